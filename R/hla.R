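# HLA-DQ allele parsing and celiac risk-genotype classification.
#
# Unphased DQA1/DQB1 typings are interpreted with genotype-level pattern
# matches: a DQA1*05 allele anywhere together with DQB1*02:01 anywhere is
# taken as the cis-encoded DQ2.5 heterodimer, following the strong linkage
# disequilibrium convention used by clinical HLA risk calculators.
# Alpha chains (DQA1) are matched at family level; beta chains (DQB1) at
# protein level, where the 02:01 / 02:02 distinction separates DQ2.5 from
# DQ2.2 and 03:01 / 03:02 separates DQ7.5 from DQ8.

DQ_LOCI <- c("DQA1", "DQB1")

RISK_CATEGORY_LABELS <- c("DQ2.5/DQ2.5", "DQ2.5/x", "DQ2.5/DQ8",
                          "DQ8/x", "DQ2.2/x", "DQ7.5", "Negative")

#' Risk category labels in precedence order
#'
#' The seven mutually exclusive celiac HLA risk categories, from the
#' double-dose cis DQ2.5 genotype down to `Negative` (no risk heterodimer
#' inferable).
#'
#' @return Character vector of length 7.
#' @export
risk_category_levels <- function() RISK_CATEGORY_LABELS

#' Parse an HLA-DQ allele string
#'
#' Accepts the legacy four-digit style (`"DQA1*0501"`), the colon-delimited
#' style (`"DQA1*05:01"`), family-only typings (`"DQB1*02"`), an optional
#' `"HLA-"` prefix, and a case-insensitive locus. Only the DQA1 and DQB1
#' loci are supported.
#'
#' @param text A single allele string.
#' @return An object of class `dq_allele` with fields `locus`, `family`
#'   (two digits) and `protein` (two digits, or `NA` for family-only
#'   typings).
#' @examples
#' parse_allele("HLA-DQA1*0501")
#' parse_allele("DQB1*02:01")
#' @export
parse_allele <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("allele must be a single character string")
  raw <- text
  x <- trimws(text)
  if (!nzchar(x)) stop("empty allele string")
  x <- sub("^[Hh][Ll][Aa]-", "", x)
  parts <- strsplit(x, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]))
    stop(sprintf("malformed allele '%s': expected <locus>*<fields>", raw))
  locus <- toupper(parts[1])
  if (!locus %in% DQ_LOCI)
    stop(sprintf("unknown locus '%s' in allele '%s'", parts[1], raw))
  fields <- parts[2]
  if (grepl(":", fields, fixed = TRUE)) {
    num <- strsplit(fields, ":", fixed = TRUE)[[1]]
  } else if (nchar(fields) == 2L) {
    num <- fields
  } else if (nchar(fields) == 4L) {
    num <- c(substr(fields, 1, 2), substr(fields, 3, 4))
  } else {
    stop(sprintf("malformed numeric field '%s' in allele '%s'", fields, raw))
  }
  if (length(num) > 2L)
    stop(sprintf("too many fields ('%s') in allele '%s'", fields, raw))
  if (!all(grepl("^[0-9]{2}$", num)))
    stop(sprintf("malformed numeric field '%s' in allele '%s'", fields, raw))
  structure(list(locus = locus,
                 family = num[1],
                 protein = if (length(num) == 2L) num[2] else NA_character_),
            class = "dq_allele")
}

#' @export
format.dq_allele <- function(x, ...) {
  paste0(x$locus, "*", x$family,
         if (!is.na(x$protein)) paste0(":", x$protein) else "")
}

#' @export
print.dq_allele <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.as_allele <- function(x, locus = NULL) {
  a <- if (inherits(x, "dq_allele")) x else parse_allele(x)
  if (!is.null(locus) && a$locus != locus)
    stop(sprintf("expected a %s allele, got '%s'", locus, format(a)))
  a
}

#' Construct an unphased HLA-DQ genotype
#'
#' @param dqa1 Two DQA1 alleles (strings or `dq_allele` objects);
#'   homozygosity is encoded by repetition.
#' @param dqb1 Two DQB1 alleles.
#' @return An object of class `dq_genotype`. Allele order within a locus
#'   never affects any derived result.
#' @examples
#' dq_genotype(c("DQA1*05:01", "DQA1*05:01"), c("DQB1*02:01", "DQB1*02:01"))
#' @export
dq_genotype <- function(dqa1, dqb1) {
  if (length(dqa1) != 2L || length(dqb1) != 2L)
    stop("a genotype carries exactly two alleles per locus")
  structure(list(dqa1 = lapply(dqa1, .as_allele, locus = "DQA1"),
                 dqb1 = lapply(dqb1, .as_allele, locus = "DQB1")),
            class = "dq_genotype")
}

#' @export
format.dq_genotype <- function(x, ...) {
  paste(c(vapply(x$dqa1, format, ""), vapply(x$dqb1, format, "")),
        collapse = " / ")
}

#' @export
print.dq_genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Match one allele against a (family, protein) pattern.
# Returns 2 for an exact match, 1 for an ambiguous match (family-only
# typing where the pattern demands a protein), 0 for no match.
.allele_match <- function(a, family, protein = NULL) {
  if (a$family != family) return(0L)
  if (is.null(protein)) return(2L)
  if (is.na(a$protein)) return(1L)
  if (a$protein == protein) 2L else 0L
}

# Best match over the two alleles of one chain.
.chain_match <- function(alleles, family, protein = NULL) {
  max(vapply(alleles, .allele_match, 0L, family = family, protein = protein))
}

#' Infer celiac risk heterodimers from an unphased genotype
#'
#' Reports every co-formable risk heterodimer: DQ2.5 in cis (DQA1*05 with
#' DQB1*02:01; dose `double` when both chains are homozygous for the
#' pattern), DQ2.5 in trans (DQA1*05 + DQB1*03:01 co-occurring with
#' DQA1*02 + DQB1*02:02, only when cis is absent), DQ2.2, DQ8 and DQ7.5.
#'
#' @param g A `dq_genotype`.
#' @return A data frame with columns `name` and `dose` (`"single"` or
#'   `"double"`; double only for cis DQ2.5), one row per heterodimer,
#'   with a logical attribute `ambiguous` set when a family-only typing
#'   matched a protein-level pattern.
#' @export
infer_heterodimers <- function(g) {
  stopifnot(inherits(g, "dq_genotype"))
  a05 <- .chain_match(g$dqa1, "05")
  a03 <- .chain_match(g$dqa1, "03")
  a02 <- .chain_match(g$dqa1, "02")
  b0201 <- .chain_match(g$dqb1, "02", "01")
  b0202 <- .chain_match(g$dqb1, "02", "02")
  b0301 <- .chain_match(g$dqb1, "03", "01")
  b0302 <- .chain_match(g$dqb1, "03", "02")

  name <- character(0)
  dose <- character(0)
  ambiguous <- FALSE
  add <- function(nm, sc, dbl = FALSE) {
    name <<- c(name, nm)
    dose <<- c(dose, if (dbl) "double" else "single")
    if (sc == 1L) ambiguous <<- TRUE
  }

  cis <- min(a05, b0201)
  if (cis > 0L) {
    both_a05 <- all(vapply(g$dqa1, .allele_match, 0L, family = "05") > 0L)
    b_scores <- vapply(g$dqb1, .allele_match, 0L, family = "02", protein = "01")
    add("DQ2.5_cis", cis, dbl = both_a05 && all(b_scores > 0L))
  }
  trans <- min(a05, b0301, a02, b0202)
  if (cis == 0L && trans > 0L) add("DQ2.5_trans", trans)
  dq22 <- min(a02, b0202)
  if (dq22 > 0L) add("DQ2.2", dq22)
  dq8 <- min(a03, b0302)
  if (dq8 > 0L) add("DQ8", dq8)
  dq75 <- min(a05, b0301)
  if (dq75 > 0L) add("DQ7.5", dq75)

  structure(data.frame(name = name, dose = dose, stringsAsFactors = FALSE),
            ambiguous = ambiguous)
}

#' Classify a genotype into a celiac risk category
#'
#' Applies a deterministic precedence over the inferred heterodimers:
#' `DQ2.5/DQ2.5` (double-dose cis) > `DQ2.5/DQ8` > `DQ2.5/x` > `DQ8/x` >
#' `DQ2.2/x` > `DQ7.5` > `Negative`, where `x` denotes any haplotype
#' contributing no risk heterodimer. A genotype carrying both DQ8 and
#' DQ2.2 maps to `DQ8/x` with a warning annotation; family-only typings
#' that matched ambiguously yield an `ambiguous-resolution` annotation.
#'
#' @param g A `dq_genotype`.
#' @return A single category label (see [risk_category_levels()]) with a
#'   character attribute `annotations` (possibly empty).
#' @export
classify_genotype <- function(g) {
  h <- infer_heterodimers(g)
  n <- h$name
  ann <- character(0)
  if (isTRUE(attr(h, "ambiguous"))) ann <- c(ann, "ambiguous-resolution")
  dq25 <- any(n %in% c("DQ2.5_cis", "DQ2.5_trans"))
  label <-
    if ("DQ2.5_cis" %in% n && h$dose[n == "DQ2.5_cis"] == "double") {
      "DQ2.5/DQ2.5"
    } else if (dq25 && "DQ8" %in% n) {
      "DQ2.5/DQ8"
    } else if (dq25) {
      "DQ2.5/x"
    } else if ("DQ8" %in% n) {
      if ("DQ2.2" %in% n) ann <- c(ann, "DQ8-with-DQ2.2")
      "DQ8/x"
    } else if ("DQ2.2" %in% n) {
      "DQ2.2/x"
    } else if ("DQ7.5" %in% n) {
      "DQ7.5"
    } else {
      "Negative"
    }
  structure(label, annotations = ann)
}

#' Is a risk category compatible with celiac disease?
#'
#' Every category except `Negative` carries at least one risk heterodimer
#' and is treated as HLA-compatible by the diagnostic flowcharts.
#'
#' @param category Character vector of risk category labels.
#' @return Logical vector.
#' @export
is_compatible <- function(category) {
  bad <- setdiff(unique(as.character(category)), RISK_CATEGORY_LABELS)
  if (length(bad))
    stop(sprintf("unknown risk category: %s", paste(bad, collapse = ", ")))
  as.character(category) != "Negative"
}

#' Classify the genotype columns of a cohort data frame
#'
#' Vectorised wrapper around [classify_genotype()] for cohorts with
#' `dqa1_1, dqa1_2, dqb1_1, dqb1_2` columns; distinct genotypes are
#' classified once and the labels recycled.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @return Character vector of risk category labels, one per row.
#' @export
risk_categories <- function(cohort) {
  key <- paste(cohort$dqa1_1, cohort$dqa1_2, cohort$dqb1_1, cohort$dqb1_2,
               sep = "|")
  uk <- unique(key)
  lab <- vapply(uk, function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    as.character(classify_genotype(dq_genotype(p[1:2], p[3:4])))
  }, "")
  unname(lab[match(key, uk)])
}
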