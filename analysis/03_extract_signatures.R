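#!/usr/bin/env Rscript
# De novo extraction demonstration at desk scale: 150-sample planted
# three-signature cohort, 50 NMF replicates per k over k = 1..6, consensus
# clustering with silhouette stability, stability-based selection of k.

suppressPackageStartupMessages(library(geosig))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

sigs <- make_planted_signatures(
  "SBS96", shapes = c("ta_heavy", "tc_heavy", "cpg_ct"),
  separation = 0.6, seed = 17)
set.seed(42)
V <- vapply(1:150, function(j) {
  w <- rlnorm(3, 0, 0.8)
  p <- as.numeric(sigs %*% (w / sum(w)))
  as.integer(rmultinom(1, rpois(1, 3000), p))
}, integer(96))
rownames(V) <- rownames(sigs); colnames(V) <- sprintf("s%03d", 1:150)

ex <- extract(V, k_range = 1:6, n_replicates = 50, seed = 42,
              tol = 1e-6, max_iter = 2000, cluster_restarts = 30)
print(ex)

stab <- do.call(rbind, lapply(ex$per_k, function(pk)
  data.frame(k = pk$k, mean_stability = round(pk$mean_stability, 4),
             min_stability = round(min(pk$stability), 4),
             recon_error = round(pk$recon_error, 5))))
write.table(stab, "results/03_stability_by_k.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cons <- ex$per_k[[as.character(ex$selected_k)]]$signatures
write_signatures(cons, "scratch/denovo_consensus_signatures.csv")
rec <- vapply(1:3, function(j)
  max(apply(cons, 2, cosine_similarity, b = sigs[, j])), numeric(1))
cat(sprintf("selected k = %d; planted-profile recovery cosines: %s\n",
            ex$selected_k, paste(round(rec, 4), collapse = ", ")))
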