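#' Filter samples and clusters for clonal/subclonal timing analysis
#'
#' Applies, in order, the exclusion rules used before clone-versus-subclone
#' signature comparison:
#' \enumerate{
#'   \item tumour purity at least \code{min_purity} (default 0.40);
#'   \item mutations unassigned to any cluster are dropped (handled
#'     upstream: clusters with \code{NA} ids never enter this table);
#'   \item clusters centred at CCF above \code{max_ccf} (default 1.5) are
#'     artifactual and dropped;
#'   \item clusters whose top contributing chromosome is X are dropped;
#'   \item samples need at least \code{min_mutations} (default 256) clonal
#'     and \code{min_mutations} subclonal mutations after cluster removal;
#'   \item samples with any remaining subclone centred at CCF above
#'     \code{max_subclone_ccf} (default 0.80) are dropped (poor
#'     clone/subclone separation);
#'   \item samples must retain at least one clone and one subclone.
#' }
#' Every rule is independently toggleable and excluded samples are
#' accounted to the first rule that fired.
#'
#' @param clusters data frame with columns \code{sample_id},
#'   \code{cluster_id}, \code{ccf}, \code{n_mutations}, \code{top_chrom},
#'   \code{clonal_flag} (logical: TRUE for the clone).
#' @param purity data frame with columns \code{sample_id}, \code{purity}.
#' @param min_purity,max_ccf,min_mutations,max_subclone_ccf rule
#'   thresholds; set any to \code{NULL} to disable that rule.
#' @return list with \code{retained_samples}, \code{clusters} (retained
#'   rows), \code{exclusions} (per-rule sample counts), and
#'   \code{sample_status} (data frame: sample_id, retained, reason).
#' @export
filter_timing_samples <- function(clusters, purity,
                                  min_purity = 0.40, max_ccf = 1.5,
                                  min_mutations = 256L,
                                  max_subclone_ccf = 0.80) {
  req <- c("sample_id", "cluster_id", "ccf", "n_mutations", "top_chrom",
           "clonal_flag")
  stopifnot(all(req %in% names(clusters)))
  samples <- unique(clusters$sample_id)
  reason <- setNames(rep(NA_character_, length(samples)), samples)
  excl <- c(purity = 0L, min_mutations = 0L, subclone_ccf = 0L,
            no_clone_subclone = 0L)

  if (!is.null(min_purity)) {
    pr <- purity$purity[match(samples, purity$sample_id)]
    bad <- !is.na(pr) & pr < min_purity
    reason[bad] <- "purity"
    excl["purity"] <- sum(bad)
  }
  cl <- clusters[is.na(reason[clusters$sample_id]), , drop = FALSE]
  # cluster-level artifact removal
  if (!is.null(max_ccf)) cl <- cl[cl$ccf <= max_ccf, , drop = FALSE]
  if (TRUE) cl <- cl[!(cl$top_chrom %in% c("X", "chrX")), , drop = FALSE]

  for (s in samples[is.na(reason[samples])]) {
    sub <- cl[cl$sample_id == s, , drop = FALSE]
    n_clonal <- sum(sub$n_mutations[sub$clonal_flag])
    n_subclonal <- sum(sub$n_mutations[!sub$clonal_flag])
    if (!is.null(min_mutations) &&
        (n_clonal < min_mutations || n_subclonal < min_mutations)) {
      reason[s] <- "min_mutations"
      excl["min_mutations"] <- excl["min_mutations"] + 1L
      next
    }
    if (!is.null(max_subclone_ccf) &&
        any(!sub$clonal_flag & sub$ccf > max_subclone_ccf)) {
      reason[s] <- "subclone_ccf"
      excl["subclone_ccf"] <- excl["subclone_ccf"] + 1L
      next
    }
    if (!any(sub$clonal_flag) || !any(!sub$clonal_flag)) {
      reason[s] <- "no_clone_subclone"
      excl["no_clone_subclone"] <- excl["no_clone_subclone"] + 1L
    }
  }
  retained <- samples[is.na(reason[samples])]
  status <- data.frame(sample_id = samples,
                       retained = is.na(reason),
                       reason = unname(reason), row.names = NULL)
  list(retained_samples = retained,
       clusters = cl[cl$sample_id %in% retained, , drop = FALSE],
       exclusions = excl,
       sample_status = status)
}
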