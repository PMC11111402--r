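#' Default pruning penalty per channel schema
#'
#' Simulation-derived thresholds on the L2-similarity contribution below
#' which a signature is removed from a sample's attribution: 0.008 for SBS,
#' 0.014 for DBS and 0.03 for ID catalogues.
#'
#' @param schema schema name or \code{channel_schema}.
#' @return numeric penalty.
#' @export
default_penalty <- function(schema) {
  name <- if (inherits(schema, "channel_schema")) schema$name else schema
  switch(name,
         SBS96 = 0.008, SBS288 = 0.008,
         DBS78 = 0.014, ID83 = 0.03,
         stop("default_penalty: unknown schema ", name))
}

#' Nonnegative least-squares fit of a spectrum against a signature panel
#'
#' @param spectrum nonnegative channel-count vector with positive total.
#' @param panel channels x signatures column-stochastic matrix.
#' @return list with \code{exposures} (named, nonnegative) and
#'   \code{residual} (L2 norm).
#' @export
nnls_fit <- function(spectrum, panel) {
  panel <- as.matrix(panel)
  spectrum <- as.numeric(spectrum)
  if (sum(spectrum) <= 0) stop("nnls_fit: zero spectrum")
  if (length(spectrum) != nrow(panel))
    stop("nnls_fit: spectrum/panel dimension mismatch")
  fit <- nnls_cpp(panel, spectrum)
  e <- as.numeric(fit$x)
  names(e) <- colnames(panel)
  list(exposures = e, residual = fit$resid)
}

#' L2 similarity between a spectrum and its reconstruction
#'
#' Defined as \code{1 - ||v - vhat|| / ||v||} on raw counts; equals 1 iff
#' the reconstruction is exact and 0 for a zero reconstruction.
#'
#' @param spectrum observed channel counts (nonzero).
#' @param reconstruction fitted counts, same length.
#' @return numeric similarity (can be negative for reconstructions worse
#'   than zero).
#' @export
l2_similarity <- function(spectrum, reconstruction) {
  v <- as.numeric(spectrum)
  vh <- as.numeric(reconstruction)
  if (length(v) != length(vh)) stop("l2_similarity: length mismatch")
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("l2_similarity: zero spectrum")
  1 - sqrt(sum((v - vh)^2)) / nv
}

.subset_similarity <- function(spectrum, panel, idx) {
  if (length(idx) == 0L) return(list(sim = 0, exposures = numeric(0)))
  fit <- nnls_cpp(panel[, idx, drop = FALSE], spectrum)
  recon <- panel[, idx, drop = FALSE] %*% fit$x
  list(sim = l2_similarity(spectrum, recon), exposures = as.numeric(fit$x))
}

#' Backward-elimination pruning of a signature panel for one sample
#'
#' Starting from the full panel, repeatedly refits without each currently
#' retained signature and removes the one whose absence costs the least L2
#' similarity, while that cost does not exceed \code{penalty}. Stops when
#' every remaining signature's removal would cost more than \code{penalty}
#' (at least one signature is always retained). Ties break toward the
#' earlier panel column.
#'
#' @param spectrum channel-count vector.
#' @param panel channels x signatures matrix.
#' @param penalty L2-similarity cost threshold (see [default_penalty()]).
#' @return list with \code{retained} (panel column indices),
#'   \code{exposures} (named, full panel length, zeros for pruned),
#'   \code{similarity}, and \code{trace} (data frame of removal steps).
#' @export
prune_attribution <- function(spectrum, panel, penalty) {
  panel <- as.matrix(panel)
  spectrum <- as.numeric(spectrum)
  if (sum(spectrum) <= 0) stop("prune_attribution: zero spectrum")
  retained <- seq_len(ncol(panel))
  cur <- .subset_similarity(spectrum, panel, retained)
  trace <- list()
  while (length(retained) > 1L) {
    sims <- vapply(seq_along(retained), function(i)
      .subset_similarity(spectrum, panel, retained[-i])$sim, numeric(1))
    costs <- cur$sim - sims
    drop_i <- which.min(costs)   # which.min takes the first on ties
    if (costs[drop_i] <= penalty) {
      trace[[length(trace) + 1L]] <-
        data.frame(removed = retained[drop_i], cost = costs[drop_i])
      retained <- retained[-drop_i]
      cur <- .subset_similarity(spectrum, panel, retained)
    } else break
  }
  exposures <- numeric(ncol(panel))
  exposures[retained] <- cur$exposures
  names(exposures) <- colnames(panel)
  list(retained = retained, exposures = exposures, similarity = cur$sim,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(removed = integer(0), cost = numeric(0)))
}

# rescale exposures so their sum does not exceed the spectrum total;
# the remainder is the unassigned burden
.clip_exposures <- function(exposures, total) {
  s <- sum(exposures)
  if (s > total && s > 0) exposures <- exposures * (total / s)
  exposures
}

#' Signature attribution with parametric-bootstrap confidence intervals
#'
#' The point estimate is the pruned NNLS fit on the observed spectrum. Each
#' bootstrap replicate Poisson-resamples the spectrum channel-wise and
#' reruns the full pruning + fit, so a signature pruned in a replicate
#' contributes an exposure of zero; per-signature confidence bounds are the
#' empirical \code{alpha/2} and \code{1 - alpha/2} percentiles across
#' replicates. A signature is called present when both bounds are positive.
#'
#' @param spectrum channel-count vector (positive total).
#' @param panel channels x signatures matrix.
#' @param penalty pruning penalty (default from \code{schema} via
#'   [default_penalty()] when supplied, else 0.008).
#' @param n_boot bootstrap replicates (>= 100 recommended; default 200).
#' @param alpha 1 - confidence level (default 0.05 for 95% intervals).
#' @param seed RNG seed.
#' @param sample_id optional identifier attached to the result.
#' @return object of class \code{attribution_result}: list with
#'   \code{sample_id}, \code{panel} (signature names), \code{exposures},
#'   \code{ci_low}, \code{ci_high}, \code{present}, \code{l2_similarity},
#'   \code{unassigned}, \code{total}.
#' @export
bootstrap_attribution <- function(spectrum, panel, penalty = 0.008,
                                  n_boot = 200L, alpha = 0.05,
                                  seed = NULL, sample_id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  panel <- as.matrix(panel)
  spectrum <- as.numeric(spectrum)
  total <- sum(spectrum)
  if (total <= 0) stop("bootstrap_attribution: zero spectrum")
  point <- prune_attribution(spectrum, panel, penalty)
  exposures <- .clip_exposures(point$exposures, total)
  boot <- matrix(0, n_boot, ncol(panel))
  for (b in seq_len(n_boot)) {
    sp <- stats::rpois(length(spectrum), spectrum)
    if (sum(sp) == 0) next
    pb <- prune_attribution(sp, panel, penalty)
    boot[b, ] <- .clip_exposures(pb$exposures, sum(sp))
  }
  ci <- apply(boot, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ci_low <- ci[1, ]
  ci_high <- ci[2, ]
  present <- ci_low > 0 & ci_high > 0
  names(ci_low) <- names(ci_high) <- names(present) <- colnames(panel)
  structure(list(sample_id = sample_id,
                 panel = colnames(panel),
                 exposures = exposures,
                 ci_low = ci_low, ci_high = ci_high, present = present,
                 l2_similarity = point$similarity,
                 unassigned = max(0, total - sum(exposures)),
                 total = total,
                 n_boot = n_boot, alpha = alpha),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result>", x$sample_id, " total =", x$total,
      " L2 sim =", format(x$l2_similarity, digits = 4), "\n")
  df <- data.frame(exposure = round(x$exposures, 1),
                   ci_low = round(x$ci_low, 1),
                   ci_high = round(x$ci_high, 1),
                   present = x$present)
  print(df[x$exposures > 0 | x$present, , drop = FALSE])
  invisible(x)
}

#' Attribute signature activities across a cohort
#'
#' Runs [bootstrap_attribution()] independently for every sample of a
#' catalogue and summarizes cohort-level prevalence (fraction of samples in
#' which each signature is present) and mean relative contribution.
#' Zero-count samples are skipped and logged.
#'
#' @param cat catalogue (\code{catalogue_matrix} or matrix).
#' @param panel channels x signatures matrix.
#' @param penalty pruning penalty; default taken from the catalogue schema.
#' @param n_boot,alpha bootstrap controls.
#' @param seed integer seed; per-sample seeds are derived from it.
#' @return object of class \code{cohort_attribution}: list with
#'   \code{table} (long data frame: sample_id, signature, exposure, ci_low,
#'   ci_high, present), \code{summary} (per-signature prevalence and mean
#'   relative contribution), \code{per_sample} (unassigned fraction etc.),
#'   \code{skipped}.
#' @export
attribute_cohort <- function(cat, panel, penalty = NULL, n_boot = 200L,
                             alpha = 0.05, seed = 1L) {
  counts <- .as_counts(cat)
  if (is.null(penalty)) {
    penalty <- if (inherits(cat, "catalogue_matrix"))
      default_penalty(cat$schema) else 0.008
  }
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max, ncol(counts))
  results <- vector("list", ncol(counts))
  skipped <- character(0)
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    v <- counts[, j]
    if (sum(v) == 0) {
      skipped <- c(skipped, sid)
      next
    }
    results[[j]] <- bootstrap_attribution(v, panel, penalty = penalty,
                                          n_boot = n_boot, alpha = alpha,
                                          seed = sample_seeds[j],
                                          sample_id = sid)
  }
  keep <- !vapply(results, is.null, logical(1))
  results <- results[keep]
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, signature = r$panel,
               exposure = unname(r$exposures),
               ci_low = unname(r$ci_low), ci_high = unname(r$ci_high),
               present = unname(r$present), row.names = NULL)
  }))
  per_sample <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, total = r$total,
               assigned = sum(r$exposures), unassigned = r$unassigned,
               l2_similarity = r$l2_similarity, row.names = NULL)
  }))
  sigs <- colnames(panel)
  summary <- data.frame(
    signature = sigs,
    prevalence = vapply(sigs, function(s)
      mean(tab$present[tab$signature == s]), numeric(1)),
    mean_rel_contribution = vapply(sigs, function(s) {
      sub <- tab[tab$signature == s, ]
      tot <- per_sample$total[match(sub$sample_id, per_sample$sample_id)]
      mean(sub$exposure / tot)
    }, numeric(1)),
    row.names = NULL)
  structure(list(table = tab, summary = summary, per_sample = per_sample,
                 results = results, skipped = skipped,
                 penalty = penalty, n_boot = n_boot, alpha = alpha),
            class = "cohort_attribution")
}

#' @export
print.cohort_attribution <- function(x, ...) {
  cat("<cohort_attribution>", length(x$results), "samples attributed;",
      length(x$skipped), "skipped\n")
  print(transform(x$summary,
                  prevalence = round(prevalence, 3),
                  mean_rel_contribution = round(mean_rel_contribution, 3)))
  invisible(x)
}
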