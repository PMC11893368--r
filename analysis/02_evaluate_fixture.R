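#!/usr/bin/env Rscript
# Run the four diagnostic flowcharts over the fixture cohort.
#
# Finding: HLA typing yields a conclusive decision (diagnosis or
# exclusion) for 57 of 80 patients (71.2%): 20/27 in Group 1, 7/18 in
# Group 2, 14/14 in Group 3 and 16/21 in Group 4, with 33 diagnoses,
# 24 exclusions, 23 follow-ups and 3 seronegative-CeD flags.

suppressPackageStartupMessages(library(celiacdq))

res <- run_pipeline(pipeline_config("results/fixture.csv", "results",
                                    format = c("json", "text")))
d <- res$decisions

cat("branch tallies (group x outcome):\n")
print(table(d$group, d$outcome))
cat("\n")
print(res$summary)
cat("\nseronegative CeD flags:", sum(d$seronegative_ced), "\n")
cat("\nallele distribution by group:\n")
print(res$allele_matrix)
cat("\nwrote", paste(unlist(res$paths), collapse = ", "), "\n")
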