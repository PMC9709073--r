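#!/usr/bin/env Rscript
# Step 1: generate the demonstration corpus.
#
# A synthetic spontaneous-report corpus of 20,000 cases with a 5% stale
# case-version rate and five planted target-drug signals spanning the
# haematological, gastrointestinal and cutaneous toxicity profile expected
# of a PARP inhibitor. The FAERS-dialect files go to scratch/ (they are
# regenerated on demand); the ground-truth relative risks go to results/.

library(faersignal)

corpus_dir <- "scratch/demo_corpus"
dir.create("results", showWarnings = FALSE)

planted <- data.frame(
  drug = "NIRAPARIB",
  pt = c("Thrombocytopenia", "Anaemia", "Platelet count decreased",
         "Nausea", "Photosensitivity reaction"),
  rr = c(12, 8, 10, 3, 6))

cfg <- sim_config(n_reports = 20000L, rr = planted, duplicate_rate = 0.05,
                  seed = 20170327L)
corpus <- simulate_corpus(cfg)
write_corpus(corpus, corpus_dir)
corpus_soc_map(corpus, "scratch/demo_soc_map.csv")
write.csv(planted, "results/true_rr.csv", row.names = FALSE)

cat("Wrote", corpus_dir, "with",
    nrow(corpus$demo), "DEMO rows covering",
    corpus$ground_truth$n_cases, "cases (",
    corpus$ground_truth$n_injected_duplicates, "injected stale versions )\n")
cat("Planted signals:\n")
print(planted, row.names = FALSE)
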