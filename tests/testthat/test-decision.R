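test_that("study-group assignment follows serology band and histology", {
  expect_equal(assign_group(make_record(anti_tg2 = 250, marsh = "M0")), "G1")
  expect_equal(assign_group(make_record(anti_tg2 = 10, marsh = "M0")), "G2")
  expect_equal(assign_group(make_record(anti_tg2 = 10, marsh = "M3a")), "G3")
  # the low band (< 3x ULN) with a lesion is still Group 3
  expect_equal(assign_group(make_record(anti_tg2 = 40, marsh = "M3a")), "G3")
  # concordant positive serology + lesion is the conventional pathway
  expect_equal(assign_group(make_record(anti_tg2 = 250, marsh = "M3c")),
               "conventional")
  expect_equal(assign_group(make_record(anti_tg2 = 100, marsh = "M2")),
               "conventional")
  # Marsh 1 counts as normal villous architecture
  expect_equal(assign_group(make_record(anti_tg2 = 40, marsh = "M1")), "G1")
  expect_equal(assign_group(make_record(biopsy = FALSE,
                                        marsh = NA_character_)), "G4")
})

test_that("Group 1 flowchart: confirm, exclude, or follow up", {
  d <- evaluate_patient(make_record(anti_tg2 = 250, ema = "positive",
                                    category = "DQ2.5/DQ2.5"))
  expect_equal(d$outcome, "ced")
  expect_true(d$hla_contributed)

  d <- evaluate_patient(make_record(anti_tg2 = 40, ema = "negative",
                                    category = "Negative"))
  expect_equal(d$outcome, "excluded")
  expect_true(d$hla_contributed)

  d <- evaluate_patient(make_record(anti_tg2 = 40, ema = "negative",
                                    category = "DQ2.5/x"))
  expect_equal(d$outcome, "follow_up")
  expect_false(d$hla_contributed)

  # branches the flowchart never specifies default to annotated follow-up
  for (rec in list(make_record(anti_tg2 = 40, ema = "positive"),
                   make_record(anti_tg2 = 250, ema = "positive",
                               category = "Negative"),
                   make_record(anti_tg2 = 100, ema = "negative"))) {
    d <- evaluate_patient(rec)
    expect_equal(d$outcome, "follow_up")
    expect_match(d$annotations, "unspecified-branch", all = FALSE)
  }
})

test_that("Groups 2 and 4 exclude on negative HLA and otherwise follow up or diagnose", {
  d <- evaluate_patient(make_record(anti_tg2 = 10, category = "Negative"))
  expect_equal(d$outcome, "excluded")
  d <- evaluate_patient(make_record(anti_tg2 = 10, category = "DQ2.5/x"))
  expect_equal(d$outcome, "follow_up")

  g4 <- function(...) make_record(biopsy = FALSE, marsh = NA_character_, ...)
  expect_equal(evaluate_patient(g4(anti_tg2 = 10,
                                   category = "Negative"))$outcome, "excluded")
  expect_equal(evaluate_patient(g4(anti_tg2 = 10,
                                   category = "DQ8/x"))$outcome, "follow_up")
  # no-biopsy pathway: >= 10x ULN + EMA+ + compatible HLA
  d <- evaluate_patient(g4(anti_tg2 = 250, ema = "positive",
                           category = "DQ2.5/DQ2.5"))
  expect_equal(d$outcome, "ced")
  expect_true(d$hla_contributed)
  # ... but not without compatible HLA
  d <- evaluate_patient(g4(anti_tg2 = 250, ema = "positive",
                           category = "Negative"))
  expect_equal(d$outcome, "follow_up")
  expect_false(d$hla_contributed)
  # EMA-positive at 1-10x ULN with compatible HLA is also diagnostic
  expect_equal(evaluate_patient(g4(anti_tg2 = 100, ema = "positive",
                                   category = "DQ2.5/x"))$outcome, "ced")
  expect_equal(evaluate_patient(g4(anti_tg2 = 40, ema = "negative",
                                   category = "DQ2.5/x"))$outcome,
               "follow_up")
})

test_that("Group 3 seronegative work-up requires the right evidence per case", {
  g3 <- function(...) make_record(anti_tg2 = 10, marsh = "M3c", ...)
  # HLA-negative lesion: excluded
  expect_equal(evaluate_patient(g3(category = "Negative"))$outcome,
               "excluded")
  # toddler with low IgA: GFD response alone confirms; not seronegative CeD
  d <- evaluate_patient(g3(age = 2, iga = "low", gfd = TRUE))
  expect_equal(d$outcome, "ced")
  expect_false(d$seronegative_ced)
  expect_match(d$annotations, "non-informative")
  # same toddler without GFD response stays pending
  expect_equal(evaluate_patient(g3(age = 2, iga = "low"))$outcome, "pending")
  # older child needs work-up + GFD + repeat-biopsy recovery
  d <- evaluate_patient(g3(age = 8, dwu = TRUE, gfd = TRUE, rb = TRUE))
  expect_equal(d$outcome, "ced")
  expect_true(d$seronegative_ced)
  expect_equal(evaluate_patient(g3(age = 8, dwu = TRUE,
                                   gfd = TRUE))$outcome, "pending")
  expect_equal(evaluate_patient(g3(age = 8, gfd = TRUE,
                                   rb = TRUE))$outcome, "pending")
})

test_that("decision engine is total, deterministic, and respects the HLA invariants", {
  cohort <- generate_cohort(default_sim_params(n = 2000, seed = 42))
  d1 <- evaluate_cohort(cohort)
  d2 <- evaluate_cohort(cohort)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), nrow(cohort))
  expect_true(all(d1$outcome %in% c("ced", "excluded", "follow_up",
                                    "pending")))
  eligible <- d1$group %in% c("G1", "G2", "G3", "G4")
  # exclusion happens only via HLA; no diagnosis without compatible HLA
  expect_true(all(d1$risk_category[d1$outcome == "excluded"] == "Negative"))
  expect_true(all(d1$risk_category[d1$outcome == "ced"] != "Negative"))
  # HLA contributed exactly when the outcome is conclusive
  expect_identical(d1$hla_contributed[eligible],
                   d1$outcome[eligible] %in% c("ced", "excluded"))
  expect_true(all(!d1$hla_contributed[!eligible]))
  expect_true(all(nzchar(d1$rationale)))
})

test_that("the terminal rule of each rationale trace replays the outcome", {
  rules <- decision_rules()
  cohort <- rbind(build_fixture(),
                  generate_cohort(default_sim_params(n = 500, seed = 9)))
  d <- evaluate_cohort(cohort)
  expect_true(all(d$rule_id %in% rules$id))
  expect_identical(d$outcome, rules$outcome[match(d$rule_id, rules$id)])
  # the trace ends with the terminal rule it names
  last <- vapply(strsplit(d$rationale, " | ", fixed = TRUE),
                 function(tr) tr[length(tr)], "")
  expect_identical(sub(":.*$", "", last), d$rule_id)
})

test_that("ineligible and malformed records pass through without aborting the run", {
  conv <- make_record(anti_tg2 = 250, marsh = "M3c")
  d <- evaluate_cohort(as.data.frame(conv, stringsAsFactors = FALSE))
  expect_equal(d$outcome, "pending")
  expect_false(d$hla_contributed)
  expect_match(d$annotations, "out-of-scope")
  expect_error(evaluate_cohort(data.frame()), "non-empty")
})
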