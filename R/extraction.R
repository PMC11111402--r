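# cosine similarity between the columns of A and the columns of B
.cosine_cols <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  crossprod(An, Bn)
}

# Partition pooled replicate signatures into k clusters with the constraint
# that each replicate contributes exactly one signature per cluster: iterate
# replicate-to-centroid one-to-one matching (exact assignment) and centroid
# refresh. Returns the best of `restarts` random centroid initializations.
.cluster_replicates <- function(Ws, k, restarts = 100L, max_iter = 50L) {
  n_rep <- length(Ws)
  pool <- do.call(cbind, Ws)
  best <- NULL
  for (r in seq_len(restarts)) {
    # initialize centroids from one replicate's solution (they already form
    # a valid one-per-cluster system)
    cent <- Ws[[sample.int(n_rep, 1)]]
    assign_mat <- matrix(0L, n_rep, k)
    for (it in seq_len(max_iter)) {
      newassign <- matrix(0L, n_rep, k)
      for (i in seq_len(n_rep)) {
        cost <- 1 - .cosine_cols(Ws[[i]], cent)
        newassign[i, ] <- hungarian_cpp(cost)
      }
      if (identical(newassign, assign_mat)) break
      assign_mat <- newassign
      for (j in seq_len(k)) {
        members <- vapply(seq_len(n_rep),
                          function(i) Ws[[i]][, which(assign_mat[i, ] == j)],
                          numeric(nrow(cent)))
        cm <- rowMeans(matrix(members, nrow = nrow(cent)))
        s <- sum(cm)
        cent[, j] <- if (s > 0) cm / s else cm
      }
    }
    score <- 0
    for (i in seq_len(n_rep)) {
      cs <- .cosine_cols(Ws[[i]], cent)
      score <- score + sum(cs[cbind(seq_len(k), assign_mat[i, ])])
    }
    if (is.null(best) || score > best$score) {
      # cluster label of each pooled column (replicate-major pooling)
      labels <- as.integer(t(assign_mat))
      best <- list(centroids = cent, labels = labels, score = score)
    }
  }
  best$pool <- pool
  best
}

# mean silhouette width per cluster under cosine distance; for k = 1 the
# silhouette is undefined and the mean member-to-centroid cosine is used
# instead (both lie in [-1, 1]).
.cluster_stability <- function(pool, labels, centroids) {
  k <- ncol(centroids)
  if (k == 1L) {
    return(mean(.cosine_cols(pool, centroids)))
  }
  D <- 1 - .cosine_cols(pool, pool)
  n <- ncol(pool)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(seq_len(k), labels[i]),
                    function(j) mean(D[i, labels == j]), numeric(1)))
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  vapply(seq_len(k), function(j) mean(sil[labels == j]), numeric(1))
}

#' De novo signature extraction with replicate consensus
#'
#' For each candidate number of signatures \code{k}, runs \code{n_replicates}
#' KL-NMF factorizations, each on an independently Poisson-resampled (and
#' hypermutator-renormalized) copy of the catalogue, pools the replicate
#' signatures and partitions them into \code{k} consensus clusters by
#' iterative centroid matching under cosine distance with exact one-to-one
#' replicate-to-centroid assignment. Per-signature stability is the mean
#' silhouette width of the cluster under cosine distance; the consensus
#' signature is the normalized cluster centroid. The selected \code{k} is
#' the largest scanned value whose mean stability is at least \code{s_min}
#' and whose every per-signature stability is at least \code{s_sig}.
#'
#' @param cat catalogue (\code{catalogue_matrix} or matrix).
#' @param k_range candidate signature numbers (default 1:8; the full scan
#'   used on real cohorts is 1:20).
#' @param n_replicates NMF replicates per k (>= 2).
#' @param seed integer seed controlling resampling and clustering restarts.
#' @param s_min minimum mean stability for a k to be selectable.
#' @param s_sig minimum per-signature stability.
#' @param factor_cap hypermutator cap passed to
#'   [renormalize_hypermutators()] (NULL disables).
#' @param tol,max_iter NMF stopping controls.
#' @param cluster_restarts random restarts of the consensus clustering.
#' @return object of class \code{extraction_result}: per-k list of consensus
#'   signatures, per-signature stabilities, mean stability and mean
#'   sample-wise reconstruction error; \code{selected_k}; configuration
#'   echo.
#' @export
extract <- function(cat, k_range = 1:8, n_replicates = 100L, seed = 1L,
                    s_min = 0.8, s_sig = 0.2, factor_cap = 10,
                    tol = 1e-8, max_iter = 10000L,
                    cluster_restarts = 100L) {
  V0 <- .as_counts(cat)
  if (n_replicates < 2L) stop("extract: n_replicates must be >= 2")
  if (any(k_range < 1L) || any(k_range > min(dim(V0))))
    stop("extract: k_range out of bounds")
  set.seed(seed)
  per_k <- list()
  for (k in sort(k_range)) {
    Ws <- vector("list", n_replicates)
    ok <- TRUE
    for (r in seq_len(n_replicates)) {
      Vr <- poisson_resample(V0)
      if (!is.null(factor_cap)) Vr <- renormalize_hypermutators(Vr, factor_cap)$counts
      if (all(Vr == 0)) { ok <- FALSE; break }
      sol <- nmf_kl(Vr, k, init = "nndsvd_min", tol = tol,
                    max_iter = max_iter)
      Ws[[r]] <- sol$W
    }
    if (!ok) {
      per_k[[as.character(k)]] <- list(k = k, degenerate = TRUE)
      next
    }
    cl <- .cluster_replicates(Ws, k, restarts = cluster_restarts)
    stab <- .cluster_stability(cl$pool, cl$labels, cl$centroids)
    cons <- sweep(cl$centroids, 2, colSums(cl$centroids), "/")
    rownames(cons) <- rownames(V0)
    colnames(cons) <- paste0("DN", k, LETTERS[seq_len(k)])
    # reconstruction of the original catalogue with the consensus signatures
    err <- vapply(seq_len(ncol(V0)), function(j) {
      v <- V0[, j]
      if (sum(v) == 0) return(NA_real_)
      e <- nnls_cpp(cons, v)
      e$resid / sqrt(sum(v^2))
    }, numeric(1))
    per_k[[as.character(k)]] <- list(
      k = k, degenerate = FALSE, signatures = cons,
      stability = as.numeric(stab), mean_stability = mean(stab),
      recon_error = mean(err, na.rm = TRUE))
  }
  stable <- vapply(per_k, function(x) {
    !isTRUE(x$degenerate) && x$mean_stability >= s_min &&
      all(x$stability >= s_sig)
  }, logical(1))
  selected_k <- if (any(stable)) {
    ks <- vapply(per_k[stable], `[[`, numeric(1), "k")
    errs <- vapply(per_k[stable], `[[`, numeric(1), "recon_error")
    kmax <- max(ks)
    cand <- ks == kmax
    as.integer(ks[cand][which.min(errs[cand])])
  } else {
    ms <- vapply(per_k, function(x)
      if (isTRUE(x$degenerate)) -Inf else x$mean_stability, numeric(1))
    as.integer(vapply(per_k, `[[`, numeric(1), "k")[which.max(ms)])
  }
  structure(list(per_k = per_k, selected_k = selected_k,
                 any_stable = any(stable),
                 replicates = n_replicates,
                 config = list(k_range = k_range, seed = seed,
                               s_min = s_min, s_sig = s_sig,
                               factor_cap = factor_cap, tol = tol,
                               max_iter = max_iter,
                               cluster_restarts = cluster_restarts)),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> selected k =", x$selected_k,
      "(", x$replicates, "replicates )\n")
  for (pk in x$per_k) {
    if (isTRUE(pk$degenerate)) {
      cat(sprintf("  k=%d  degenerate\n", pk$k))
    } else {
      cat(sprintf("  k=%d  mean stability %.3f  recon error %.4f\n",
                  pk$k, pk$mean_stability, pk$recon_error))
    }
  }
  invisible(x)
}
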