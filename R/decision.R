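# Study-group assignment and the four diagnostic flowcharts.
#
# Patients whose conventional work-up is inconclusive fall into four
# groups: G1 positive serology / normal histology ("potential" CeD),
# G2 negative serology / normal histology, G3 negative-or-low serology /
# celiac-type lesion, G4 no biopsy available. Each group has a rule-based
# flowchart combining the titer band, EMA, and the HLA risk category into
# an outcome (ced / excluded / follow_up / pending). HLA is counted as
# having contributed exactly when the outcome is conclusive (ced or
# excluded): under these flowcharts every exclusion is HLA-driven and
# every diagnosis requires a compatible genotype.

MARSH_LEVELS <- c("M0", "M1", "M2", "M3a", "M3b", "M3c")
MARSH_LESION <- c("M2", "M3a", "M3b", "M3c")
STUDY_GROUPS <- c("G1", "G2", "G3", "G4", "conventional", "indeterminate")
OUTCOMES <- c("ced", "excluded", "follow_up", "pending")

#' Terminal rules of the diagnostic flowcharts
#'
#' Registry of every terminal rule the decision engine can fire, with the
#' outcome it assigns. The last entry of a decision's rationale trace is
#' always one of these identifiers, and replaying it yields the decision's
#' outcome.
#'
#' @return Data frame with columns `id`, `group`, `outcome`, `text`.
#' @export
decision_rules <- function() {
  r <- rbind(
    c("G1.ced.high_ema_hla", "G1", "ced",
      "high titer, EMA positive, compatible HLA: diagnosed as CeD"),
    c("G1.excluded.hla_negative", "G1", "excluded",
      "low titer, EMA negative, no HLA risk alleles: CeD excluded"),
    c("G1.followup.hla_positive", "G1", "follow_up",
      "low titer, EMA negative, compatible HLA: follow-up on normal diet"),
    c("G1.followup.unspecified", "G1", "follow_up",
      "branch not covered by the Group 1 flowchart: follow-up"),
    c("G2.excluded.hla_negative", "G2", "excluded",
      "negative serology, normal histology, no HLA risk alleles: CeD excluded"),
    c("G2.followup.hla_positive", "G2", "follow_up",
      "negative serology, normal histology, compatible HLA: follow-up"),
    c("G3.excluded.hla_negative", "G3", "excluded",
      "seronegative lesion without HLA risk alleles: CeD excluded"),
    c("G3.ced.workup_confirmed", "G3", "ced",
      "seronegative lesion, compatible HLA, confirmatory work-up: CeD"),
    c("G3.pending.evidence", "G3", "pending",
      "seronegative lesion, compatible HLA, confirmatory evidence incomplete"),
    c("G4.excluded.hla_negative", "G4", "excluded",
      "negative serology, no biopsy, no HLA risk alleles: CeD excluded"),
    c("G4.followup.seronegative_hla", "G4", "follow_up",
      "negative serology, no biopsy, compatible HLA: follow-up"),
    c("G4.ced.no_biopsy_pathway", "G4", "ced",
      "titer >= 10x ULN, EMA positive, compatible HLA: CeD without biopsy"),
    c("G4.followup.high_titer_hla_negative", "G4", "follow_up",
      "titer >= 10x ULN, EMA positive, but no HLA risk alleles: the no-biopsy pathway requires compatible HLA; follow-up"),
    c("G4.ced.ema_hla", "G4", "ced",
      "titer 1-10x ULN, EMA positive, compatible HLA: diagnosed as CeD"),
    c("G4.followup.low_titer", "G4", "follow_up",
      "low titer, EMA negative, no biopsy: clinical and serological follow-up"),
    c("G4.followup.unspecified", "G4", "follow_up",
      "branch not covered by the Group 4 flowchart: follow-up"),
    c("scope.conventional", "conventional", "pending",
      "concordant serology and histology: conventional pathway, outside these flowcharts"),
    c("scope.indeterminate", "indeterminate", "pending",
      "record could not be assigned to a study group"))
  data.frame(id = r[, 1], group = r[, 2], outcome = r[, 3], text = r[, 4],
             stringsAsFactors = FALSE)
}

.marsh_lesion <- function(marsh) marsh %in% MARSH_LESION

#' Assign a patient to a study group
#'
#' Patients without a biopsy are G4. For biopsied patients the titer band
#' and the Marsh-Oberhuber score decide: normal histology (Marsh 0-1)
#' with a negative band is G2 and with any positive band G1; a
#' celiac-type lesion (Marsh 2-3) with a negative or low (< 3x ULN) band
#' is G3, while a lesion with an intermediate or high band is the
#' concordant `conventional` presentation, outside these flowcharts.
#'
#' @param p A patient record: a list or one-row data frame with at least
#'   `anti_tg2_ua_ml`, `biopsy_done` and (when biopsied) `marsh`.
#' @param cfg A [serology_config()].
#' @return One of `"G1" "G2" "G3" "G4" "conventional" "indeterminate"`.
#' @export
assign_group <- function(p, cfg = serology_config()) {
  if (!isTRUE(as.logical(p$biopsy_done))) return("G4")
  marsh <- as.character(p$marsh)
  if (is.na(marsh) || !marsh %in% MARSH_LEVELS) return("indeterminate")
  band <- as.character(classify_titer(p$anti_tg2_ua_ml, cfg))
  lesion <- .marsh_lesion(marsh)
  if (lesion) {
    if (band %in% c("negative", "low")) "G3" else "conventional"
  } else {
    if (band == "negative") "G2" else "G1"
  }
}

.field <- function(p, name, default = NA) {
  v <- p[[name]]
  if (is.null(v) || length(v) == 0L) default else v
}

# Confirmatory-evidence rule for HLA-compatible seronegative lesions (G3).
# Toddlers (< 3 y) whose seronegativity is explained by low/deficient IgA
# are confirmed on GFD response alone; all other cases need a negative
# differential work-up plus GFD response, and mucosal recovery at repeat
# biopsy when aged >= 3 or when the lesion was an incidental finding.
.g3_confirmed <- function(p) {
  age <- .field(p, "age_years", NA_real_)
  iga <- as.character(.field(p, "iga_status", "normal"))
  incidental <- isTRUE(as.logical(.field(p, "incidental_lesion", FALSE)))
  gfd <- isTRUE(as.logical(.field(p, "gfd_response", FALSE)))
  if (!is.na(age) && age < 3 && iga %in% c("low", "deficient") && !incidental)
    return(gfd)
  dwu <- isTRUE(as.logical(.field(p, "differential_workup_negative", FALSE)))
  rb <- isTRUE(as.logical(.field(p, "repeat_biopsy_recovered", FALSE)))
  need_rb <- (!is.na(age) && age >= 3) || incidental
  dwu && gfd && (!need_rb || rb)
}

.decision <- function(rule_id, trace, outcome, contributed,
                      seroneg = FALSE, annotations = character(0)) {
  rules <- decision_rules()
  txt <- rules$text[match(rule_id, rules$id)]
  list(outcome = outcome,
       hla_contributed = contributed,
       seronegative_ced = seroneg,
       rule_id = rule_id,
       rationale = c(trace, paste0(rule_id, ": ", txt)),
       annotations = annotations)
}

#' Evaluate one patient through the group's diagnostic flowchart
#'
#' Executes the flowchart of the patient's study group and returns the
#' outcome with a rationale trace. Branches the flowcharts never specify
#' (e.g. an intermediate band in Group 1, or EMA positivity at low titer
#' with normal histology) default to follow-up with an
#' `unspecified-branch` annotation rather than guessing a diagnosis.
#' `conventional` and `indeterminate` records pass through as `pending`
#' with a scope annotation.
#'
#' @param p A patient record (list or one-row data frame) with serology,
#'   histology, genotype columns `dqa1_1 ... dqb1_2` (or a precomputed
#'   `risk_category`), and optional follow-up evidence fields.
#' @param cfg A [serology_config()].
#' @return A list with `outcome`, `hla_contributed`, `seronegative_ced`,
#'   `rule_id`, `rationale` (ordered rule trace) and `annotations`.
#' @export
evaluate_patient <- function(p, cfg = serology_config()) {
  group <- assign_group(p, cfg)
  cat_lab <- .field(p, "risk_category", NA_character_)
  if (is.na(cat_lab))
    cat_lab <- as.character(classify_genotype(dq_genotype(
      c(p$dqa1_1, p$dqa1_2), c(p$dqb1_1, p$dqb1_2))))
  hla <- is_compatible(cat_lab)
  band <- as.character(classify_titer(p$anti_tg2_ua_ml, cfg))
  ema <- as.character(.field(p, "ema", "not_done"))
  ema_pos <- identical(ema, "positive")
  ema_neg <- identical(ema, "negative")
  trace <- c(sprintf("group: %s", group),
             sprintf("titer band: %s (%.3g UA/mL, %.3g x ULN)", band,
                     p$anti_tg2_ua_ml, uln_multiple(p$anti_tg2_ua_ml, cfg)),
             sprintf("hla: %s (%s)", if (hla) "compatible" else "negative",
                     cat_lab))
  ann <- character(0)
  rel <- serology_reliability(as.character(.field(p, "iga_status", "normal")))
  if (rel == "unreliable_iga" && band == "negative") {
    ann <- c(ann, "non-informative:negative serology under low/deficient IgA")
  }

  if (group == "conventional")
    return(.decision("scope.conventional", trace, "pending", FALSE,
                     annotations = c(ann, "out-of-scope")))
  if (group == "indeterminate")
    return(.decision("scope.indeterminate", trace, "pending", FALSE,
                     annotations = c(ann, "out-of-scope")))

  if (group == "G1") {
    if (band == "high" && ema_pos && hla)
      return(.decision("G1.ced.high_ema_hla", trace, "ced", TRUE,
                       annotations = ann))
    if (band == "low" && ema_neg && !hla)
      return(.decision("G1.excluded.hla_negative", trace, "excluded", TRUE,
                       annotations = ann))
    if (band == "low" && ema_neg && hla)
      return(.decision("G1.followup.hla_positive", trace, "follow_up", FALSE,
                       annotations = ann))
    return(.decision("G1.followup.unspecified", trace, "follow_up", FALSE,
                     annotations = c(ann, "unspecified-branch")))
  }

  if (group == "G2") {
    if (!hla)
      return(.decision("G2.excluded.hla_negative", trace, "excluded", TRUE,
                       annotations = ann))
    return(.decision("G2.followup.hla_positive", trace, "follow_up", FALSE,
                     annotations = ann))
  }

  if (group == "G3") {
    if (!hla)
      return(.decision("G3.excluded.hla_negative", trace, "excluded", TRUE,
                       annotations = ann))
    if (.g3_confirmed(p)) {
      iga <- as.character(.field(p, "iga_status", "normal"))
      seroneg <- !iga %in% c("low", "deficient")
      return(.decision("G3.ced.workup_confirmed", trace, "ced", TRUE,
                       seroneg = seroneg, annotations = ann))
    }
    return(.decision("G3.pending.evidence", trace, "pending", FALSE,
                     annotations = ann))
  }

  # G4: no biopsy available
  if (band == "negative") {
    if (!hla)
      return(.decision("G4.excluded.hla_negative", trace, "excluded", TRUE,
                       annotations = ann))
    return(.decision("G4.followup.seronegative_hla", trace, "follow_up",
                     FALSE, annotations = ann))
  }
  if (band == "high" && ema_pos) {
    if (hla)
      return(.decision("G4.ced.no_biopsy_pathway", trace, "ced", TRUE,
                       annotations = ann))
    return(.decision("G4.followup.high_titer_hla_negative", trace,
                     "follow_up", FALSE, annotations = ann))
  }
  if (band %in% c("low", "intermediate") && ema_pos && hla)
    return(.decision("G4.ced.ema_hla", trace, "ced", TRUE, annotations = ann))
  if (band == "low" && ema_neg)
    return(.decision("G4.followup.low_titer", trace, "follow_up", FALSE,
                     annotations = ann))
  .decision("G4.followup.unspecified", trace, "follow_up", FALSE,
            annotations = c(ann, "unspecified-branch"))
}

#' Evaluate a cohort
#'
#' Runs [evaluate_patient()] over every record, order-preserving.
#' Per-record validation failures are collected into the `annotations`
#' column (outcome `pending`) rather than aborting the run.
#'
#' @param cohort Cohort data frame (see [read_cohort()] for the schema).
#' @param cfg A [serology_config()].
#' @return Data frame with one row per record: `id`, `group`, `outcome`,
#'   `hla_contributed`, `seronegative_ced`, `risk_category`, `rule_id`,
#'   `rationale` (trace entries joined with `" | "`) and `annotations`.
#' @export
evaluate_cohort <- function(cohort, cfg = serology_config()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a non-empty data frame")
  cats <- if ("risk_category" %in% names(cohort)) {
    as.character(cohort$risk_category)
  } else {
    risk_categories(cohort)
  }
  n <- nrow(cohort)
  out <- data.frame(id = as.character(cohort$id),
                    group = character(n), outcome = character(n),
                    hla_contributed = logical(n), seronegative_ced = logical(n),
                    risk_category = cats, rule_id = character(n),
                    rationale = character(n), annotations = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- lapply(cohort, `[[`, i)
    p$risk_category <- cats[i]
    d <- tryCatch(evaluate_patient(p, cfg), error = function(e) {
      list(outcome = "pending", hla_contributed = FALSE,
           seronegative_ced = FALSE, rule_id = "error",
           rationale = paste0("validation error: ", conditionMessage(e)),
           annotations = "validation-error")
    })
    out$group[i] <- tryCatch(assign_group(p, cfg),
                             error = function(e) "indeterminate")
    out$outcome[i] <- d$outcome
    out$hla_contributed[i] <- d$hla_contributed
    out$seronegative_ced[i] <- d$seronegative_ced
    out$rule_id[i] <- d$rule_id
    out$rationale[i] <- paste(d$rationale, collapse = " | ")
    out$annotations[i] <- paste(d$annotations, collapse = "; ")
  }
  out
}
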