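test_that("allele strings parse across nomenclature styles and round-trip", {
  a <- parse_allele("HLA-DQA1*0501")
  expect_s3_class(a, "dq_allele")
  expect_equal(a$locus, "DQA1")
  expect_equal(a$family, "05")
  expect_equal(a$protein, "01")
  expect_equal(format(a), "DQA1*05:01")

  cases <- c("DQA1*0501", "DQA1*05:01", "hla-dqa1*05:01", "HLA-DQA1*05:01")
  for (s in cases) expect_equal(format(parse_allele(s)), "DQA1*05:01")

  fam <- parse_allele("DQB1*02")
  expect_true(is.na(fam$protein))
  expect_equal(format(fam), "DQB1*02")

  # format-then-parse is the identity
  for (s in c("DQA1*05:01", "DQB1*02", "DQB1*03:02")) {
    a <- parse_allele(s)
    expect_identical(parse_allele(format(a)), a)
  }
})

test_that("malformed allele strings raise errors naming the offending token", {
  expect_error(parse_allele("DQC1*05:01"), "unknown locus")
  expect_error(parse_allele("DQA1*05:01:01:02"), "too many fields")
  expect_error(parse_allele("DQA1*5"), "malformed")
  expect_error(parse_allele("DQA1*05:1"), "malformed")
  expect_error(parse_allele("DQA105:01"), "malformed")
  expect_error(parse_allele(""), "empty")
  expect_error(dq_genotype(c("DQA1*05:01", "DQB1*02:01"),
                           c("DQB1*02:01", "DQB1*02:01")), "expected a DQA1")
})

test_that("heterodimer inference follows the cis/trans configuration rules", {
  g <- dq_genotype(c("DQA1*05:01", "DQA1*05:01"),
                   c("DQB1*02:01", "DQB1*02:01"))
  h <- infer_heterodimers(g)
  expect_equal(h$name, "DQ2.5_cis")
  expect_equal(h$dose, "double")

  g <- dq_genotype(c("DQA1*05:01", "DQA1*02:01"),
                   c("DQB1*03:01", "DQB1*02:02"))
  h <- infer_heterodimers(g)
  expect_setequal(h$name, c("DQ2.5_trans", "DQ2.2", "DQ7.5"))
  expect_true(all(h$dose == "single"))

  g <- dq_genotype(c("DQA1*01:02", "DQA1*01:03"),
                   c("DQB1*06:02", "DQB1*06:03"))
  expect_equal(nrow(infer_heterodimers(g)), 0L)

  # trans is suppressed when the cis pattern holds
  g <- dq_genotype(c("DQA1*05:01", "DQA1*02:01"),
                   c("DQB1*02:01", "DQB1*02:02"))
  h <- infer_heterodimers(g)
  expect_true("DQ2.5_cis" %in% h$name)
  expect_false("DQ2.5_trans" %in% h$name)
})

test_that("genotype classification resolves categories by precedence", {
  cl <- function(a, b) as.character(classify_genotype(dq_genotype(a, b)))
  expect_equal(cl(c("DQA1*05:01", "DQA1*05:01"),
                  c("DQB1*02:01", "DQB1*02:01")), "DQ2.5/DQ2.5")
  expect_equal(cl(c("DQA1*03:01", "DQA1*01:02"),
                  c("DQB1*03:02", "DQB1*06:02")), "DQ8/x")
  expect_equal(cl(c("DQA1*05:05", "DQA1*01:02"),
                  c("DQB1*03:01", "DQB1*06:02")), "DQ7.5")
  expect_equal(cl(c("DQA1*05:01", "DQA1*03:01"),
                  c("DQB1*02:01", "DQB1*03:02")), "DQ2.5/DQ8")
  # trans-configured DQ2.5 also dominates
  expect_equal(cl(c("DQA1*05:01", "DQA1*02:01"),
                  c("DQB1*03:01", "DQB1*02:02")), "DQ2.5/x")

  # DQ8 + DQ2.2 is flagged, not silently collapsed
  g <- dq_genotype(c("DQA1*03:01", "DQA1*02:01"),
                   c("DQB1*03:02", "DQB1*02:02"))
  lab <- classify_genotype(g)
  expect_equal(as.character(lab), "DQ8/x")
  expect_true("DQ8-with-DQ2.2" %in% attr(lab, "annotations"))

  # family-only typing resolves by precedence with an ambiguity annotation
  g <- dq_genotype(c("DQA1*05:01", "DQA1*01:02"),
                   c("DQB1*02", "DQB1*06:02"))
  lab <- classify_genotype(g)
  expect_equal(as.character(lab), "DQ2.5/x")
  expect_true("ambiguous-resolution" %in% attr(lab, "annotations"))
})

test_that("HLA compatibility is carried by every category except Negative", {
  for (lab in risk_category_levels())
    expect_identical(is_compatible(lab), lab != "Negative")
  expect_error(is_compatible("DQ9/x"), "unknown risk category")
})

test_that("classification is invariant to allele order within each locus", {
  g <- panel_genotypes()
  set.seed(7)
  idx <- sample(nrow(g), 60)
  for (r in idx) {
    a <- paste0("DQA1*", g$a[[r]])
    b <- paste0("DQB1*", g$b[[r]])
    base <- classify_genotype(dq_genotype(a, b))
    for (ai in list(a, rev(a))) for (bi in list(b, rev(b))) {
      gt <- dq_genotype(ai, bi)
      expect_identical(as.character(classify_genotype(gt)),
                       as.character(base))
      expect_identical(infer_heterodimers(gt)$name,
                       infer_heterodimers(dq_genotype(a, b))$name)
    }
  }
})

test_that("classifier matches the phase-enumeration oracle on a 13-allele panel", {
  g <- panel_genotypes()
  mism <- 0L
  for (r in seq_len(nrow(g))) {
    a <- g$a[[r]]
    b <- g$b[[r]]
    got <- as.character(classify_genotype(
      dq_genotype(paste0("DQA1*", a), paste0("DQB1*", b))))
    want <- oracle_classify(a, b)
    if (!identical(got, want)) mism <- mism + 1L
    h <- infer_heterodimers(dq_genotype(paste0("DQA1*", a),
                                        paste0("DQB1*", b)))
    # Negative iff no heterodimer inferable; trans never alongside cis
    expect_identical(got == "Negative", nrow(h) == 0L)
    expect_false(all(c("DQ2.5_cis", "DQ2.5_trans") %in% h$name))
  }
  expect_identical(mism, 0L)
})
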