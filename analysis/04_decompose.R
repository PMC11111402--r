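#!/usr/bin/env Rscript
# Decompose the de novo consensus signatures against a reference panel:
# each extracted profile is expressed as a nonnegative combination of
# reference signatures (greedy add / backward remove, NNLS refit) or
# flagged as novel.

suppressPackageStartupMessages(library(geosig))
dn_path <- "scratch/denovo_consensus_signatures.csv"
if (!file.exists(dn_path)) stop("run analysis/03_extract_signatures.R first")
denovo <- read_signatures(dn_path, schema = "SBS96")

# reference panel: the three generating profiles plus two decoys
refs <- make_planted_signatures(
  "SBS96", shapes = c("ta_heavy", "tc_heavy", "cpg_ct", "flat", "random"),
  separation = 0.65, seed = 17)

rows <- list()
for (j in seq_len(ncol(denovo))) {
  d <- decompose(denovo[, j], refs)
  cat(sprintf("%s: %s, cosine %.4f, refs [%s]\n",
              colnames(denovo)[j], d$status, d$cosine,
              paste(sprintf("%s=%.3f", names(d$weights), d$weights),
                    collapse = ", ")))
  rows[[j]] <- data.frame(de_novo = colnames(denovo)[j],
                          reference = names(d$weights),
                          weight = round(unname(d$weights), 4),
                          cosine = round(d$cosine, 4),
                          status = d$status)
}
out <- do.call(rbind, rows)
write.table(out, "results/04_decomposition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
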