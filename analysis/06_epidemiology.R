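#!/usr/bin/env Rscript
# Epidemiological layer over the attributions: CI-based dichotomization
# (75% prevalence median-split rule), risk-factor logistic regressions
# adjusted for sex, age, country and smoking, and linear regressions of
# attributed burden on country incidence (ASR).

suppressPackageStartupMessages(library(geosig))
exp_path <- "scratch/exposures.tsv"
if (!file.exists(exp_path)) stop("run analysis/05_attribute.R first")
tab <- read.delim(exp_path)
cohort <- read.csv("scratch/cohort_covariates.csv")

d <- dichotomize(tab)
cat("dichotomization rules:\n")
print(attr(d, "rule"))

idx <- match(d$sample_id, cohort$sample_id)
covs <- cohort[idx, ]
rows <- list()
for (s in setdiff(names(d), "sample_id")) {
  if (length(unique(d[[s]])) < 2) next
  r <- risk_factor_regression(d[[s]], covs$smoking == "current", covs,
                              family_size = 224L)
  rows[[s]] <- cbind(signature = s, outcome_rule =
                       unname(attr(d, "rule")[s]), r)
}
rf <- do.call(rbind, rows)
write.table(rf, "results/06_riskfactor_regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nsmoking (current vs other) logistic regressions:\n")
print(rf)

asr_rows <- list()
for (s in unique(tab$signature)) {
  sub <- tab[tab$signature == s, ]
  prev <- mean(sub$present)
  if (prev < 0.75) next   # incidence regressions only for prevalent sigs
  a <- asr_regression(sub$exposure,
                      cohort[match(sub$sample_id, cohort$sample_id), ])
  asr_rows[[s]] <- cbind(signature = s, prevalence = round(prev, 3), a)
}
ar <- do.call(rbind, asr_rows)
write.table(ar, "results/06_asr_regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nASR linear regressions (prevalent signatures):\n")
print(ar)
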