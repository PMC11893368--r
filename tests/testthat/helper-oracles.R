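# Independent oracles used by the tests; these deliberately share no code
# with the package implementation.

# --- Phase-enumeration genotype classifier -------------------------------
# Enumerates both possible phase assignments of an unphased genotype,
# derives heterodimers per haplotype (cis DQ2.5, DQ2.2, DQ8, DQ7.5) and
# across haplotypes (trans DQ2.5), then resolves the category by the
# documented precedence.

oracle_split <- function(x) {
  # "05:01" -> c(family, protein)
  strsplit(x, ":", fixed = TRUE)[[1]]
}

oracle_hap <- function(a, b) {
  af <- oracle_split(a)[1]
  dimers <- character(0)
  if (af == "05" && b == "02:01") dimers <- c(dimers, "cis")
  if (af == "02" && b == "02:02") dimers <- c(dimers, "dq22")
  if (af == "03" && b == "03:02") dimers <- c(dimers, "dq8")
  if (af == "05" && b == "03:01") dimers <- c(dimers, "dq75")
  dimers
}

oracle_classify <- function(dqa1, dqb1) {
  # dqa1, dqb1: two field strings like "05:01" each
  phasings <- list(list(c(dqa1[1], dqb1[1]), c(dqa1[2], dqb1[2])),
                   list(c(dqa1[1], dqb1[2]), c(dqa1[2], dqb1[1])))
  cis <- FALSE; cis_double <- FALSE; trans <- FALSE
  dq22 <- FALSE; dq8 <- FALSE; dq75 <- FALSE
  for (ph in phasings) {
    h1 <- oracle_hap(ph[[1]][1], ph[[1]][2])
    h2 <- oracle_hap(ph[[2]][1], ph[[2]][2])
    if ("cis" %in% h1 || "cis" %in% h2) cis <- TRUE
    if ("cis" %in% h1 && "cis" %in% h2) cis_double <- TRUE
    if (("dq75" %in% h1 && "dq22" %in% h2) ||
        ("dq22" %in% h1 && "dq75" %in% h2)) trans <- TRUE
    if ("dq22" %in% c(h1, h2)) dq22 <- TRUE
    if ("dq8" %in% c(h1, h2)) dq8 <- TRUE
    if ("dq75" %in% c(h1, h2)) dq75 <- TRUE
  }
  if (cis) trans <- FALSE
  dq25 <- cis || trans
  if (cis_double) "DQ2.5/DQ2.5"
  else if (dq25 && dq8) "DQ2.5/DQ8"
  else if (dq25) "DQ2.5/x"
  else if (dq8) "DQ8/x"
  else if (dq22) "DQ2.2/x"
  else if (dq75) "DQ7.5"
  else "Negative"
}

# A 13-allele panel of common DQ alleles (7 DQA1, 6 DQB1).
PANEL_DQA1 <- c("05:01", "05:05", "02:01", "03:01", "03:02", "01:02", "01:03")
PANEL_DQB1 <- c("02:01", "02:02", "03:01", "03:02", "06:02", "06:03")

panel_genotypes <- function() {
  pairs <- function(v) {
    idx <- expand.grid(i = seq_along(v), j = seq_along(v))
    idx <- idx[idx$i <= idx$j, ]
    lapply(seq_len(nrow(idx)), function(r) v[c(idx$i[r], idx$j[r])])
  }
  expand.grid(a = pairs(PANEL_DQA1), b = pairs(PANEL_DQB1))
}

# --- Exact binomial sign test by direct enumeration ----------------------
oracle_sign_test <- function(k, n) {
  pmf <- vapply(0:n, function(i) choose(n, i) / 2^n, 0)
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# --- Shared fixtures ------------------------------------------------------
make_record <- function(anti_tg2 = 10, ema = "not_done", iga = "normal",
                        biopsy = TRUE, marsh = "M0",
                        category = "DQ2.5/x", age = 8,
                        dwu = NA, gfd = NA, rb = NA, incidental = FALSE) {
  geno <- switch(category,
    "DQ2.5/DQ2.5" = c("DQA1*05:01", "DQA1*05:01", "DQB1*02:01", "DQB1*02:01"),
    "DQ2.5/x"     = c("DQA1*05:01", "DQA1*01:02", "DQB1*02:01", "DQB1*06:02"),
    "DQ8/x"       = c("DQA1*03:01", "DQA1*01:02", "DQB1*03:02", "DQB1*06:02"),
    "Negative"    = c("DQA1*01:02", "DQA1*01:03", "DQB1*06:02", "DQB1*06:03"),
    stop("unknown category in make_record"))
  list(id = "T001", age_years = age, anti_tg2_ua_ml = anti_tg2, ema = ema,
       iga_status = iga, anti_dgp_igg = "not_done", biopsy_done = biopsy,
       marsh = marsh, dqa1_1 = geno[1], dqa1_2 = geno[2],
       dqb1_1 = geno[3], dqb1_2 = geno[4],
       differential_workup_negative = dwu, gfd_response = gfd,
       repeat_biopsy_recovered = rb, incidental_lesion = incidental)
}
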