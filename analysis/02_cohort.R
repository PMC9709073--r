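#!/usr/bin/env Rscript
# Step 2: ingest, deduplicate, and describe the target cohort.
#
# Parses the demonstration corpus, collapses case versions to the latest,
# builds the primary-suspect cohort for niraparib/Zejula, and writes the
# descriptive characteristics table (counts and percentages for sex, age
# band, indication, serious outcome, country, reporter and receipt year).

library(faersignal)

tabs <- read_faers_dir("scratch/demo_corpus")
demo <- deduplicate(tabs$demo)
log <- attr(demo, "dedup_log")
cat("Reports read:", log$n_in, "-> deduplicated cases:", log$n_out, "\n")

cohort <- build_cohort(demo, tabs$drug, c("niraparib", "zejula"))
print(cohort)

chars <- summarize_characteristics(cohort, demo, tabs$outc, tabs$indi)
write.csv(chars, "results/characteristics.csv", row.names = FALSE)

cat("\nTop characteristic rows:\n")
print(head(chars, 10), row.names = FALSE)

reduced <- exclude_consumers(cohort, demo)
cat("\nConsumer-exclusion sensitivity cohort:",
    length(reduced$target_caseids), "of", length(cohort$target_caseids),
    "target reports survive\n")
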