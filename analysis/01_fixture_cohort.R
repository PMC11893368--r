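#!/usr/bin/env Rscript
# Rebuild the 80-patient inconclusive-diagnosis cohort from the published
# group-level counts and write it out for the downstream steps.
#
# Finding: the reconstruction yields exactly 27 / 18 / 14 / 21 patients in
# Groups 1-4, 25 HLA-negative genotypes, and 11 high-titer records among
# the unbiopsied group, as published. The Group 1 allele column needs two
# extra DQ2.5/x carriers to reach the group size (see the cohort notes).

suppressPackageStartupMessages(library(celiacdq))
dir.create("results", showWarnings = FALSE)

cohort <- build_fixture()
write_cohort(cohort, "results/fixture.csv")

groups <- vapply(seq_len(nrow(cohort)),
                 function(i) assign_group(lapply(cohort, `[[`, i)), "")
cat("group sizes:\n")
print(table(groups))
cat("\nrisk categories:\n")
print(table(factor(risk_categories(cohort), levels = risk_category_levels())))
cat("\nhigh-titer unbiopsied records:",
    sum(!cohort$biopsy_done & cohort$anti_tg2_ua_ml >= 200), "\n")
cat("\nreconstruction notes:\n")
writeLines(paste(" -", attr(cohort, "notes")))
cat("\nwrote results/fixture.csv\n")
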