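#' Cosine similarity between two nonnegative profiles
#'
#' @param a,b numeric vectors of equal length, nonnegative, not all zero.
#' @return value in \[0, 1\]; 1 iff the profiles are proportional.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("cosine_similarity: length mismatch")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero vector")
  sum(a * b) / (na * nb)
}

# NNLS reconstruction of `target` from the columns `idx` of `refs`;
# returns the weights and the cosine of the reconstruction
.refit_cosine <- function(target, refs, idx) {
  if (length(idx) == 0L) return(list(weights = numeric(0), cosine = 0))
  fit <- nnls_cpp(refs[, idx, drop = FALSE], target)
  recon <- refs[, idx, drop = FALSE] %*% fit$x
  cs <- if (sum(recon^2) == 0) 0 else cosine_similarity(as.numeric(recon), target)
  list(weights = as.numeric(fit$x), cosine = cs)
}

#' Decompose a de novo signature into reference signatures
#'
#' Greedy forward selection adds, at each step, the reference signature that
#' most improves the cosine between the de novo profile and its nonnegative
#' least-squares reconstruction, while the improvement exceeds
#' \code{add_thresh}. A backward pass then removes any retained reference
#' whose removal costs less than \code{remove_thresh} cosine. Final weights
#' are refit by NNLS on the retained set. A de novo signature whose final
#' reconstruction cosine falls below \code{novelty_cosine} is flagged
#' \code{novel}.
#'
#' @param de_novo channel profile (nonnegative vector summing to ~1).
#' @param refs channels x references matrix (column-stochastic), with
#'   column names.
#' @param add_thresh minimum cosine gain to add a reference.
#' @param remove_thresh maximum cosine loss tolerated when removing.
#' @param novelty_cosine reconstruction cosine below which the signature is
#'   declared novel.
#' @return object of class \code{decomposition}: list with \code{weights}
#'   (named, nonnegative, only retained references), \code{cosine},
#'   \code{residual}, \code{status} (\code{"decomposed"} or
#'   \code{"novel"}).
#' @export
decompose <- function(de_novo, refs, add_thresh = 0.01,
                      remove_thresh = 0.01, novelty_cosine = 0.8) {
  refs <- as.matrix(refs)
  de_novo <- as.numeric(de_novo)
  if (length(de_novo) != nrow(refs))
    stop("decompose: schema mismatch between de novo profile and references")
  if (ncol(refs) == 0L) stop("decompose: empty reference set")
  nref <- ncol(refs)
  retained <- integer(0)
  cur <- 0
  repeat {
    cand <- setdiff(seq_len(nref), retained)
    if (length(cand) == 0L) break
    gains <- vapply(cand, function(j)
      .refit_cosine(de_novo, refs, c(retained, j))$cosine, numeric(1))
    best <- which.max(gains)
    if (gains[best] - cur > add_thresh) {
      retained <- c(retained, cand[best])
      cur <- gains[best]
    } else break
  }
  # backward pass
  while (length(retained) > 1L) {
    losses <- vapply(seq_along(retained), function(i)
      cur - .refit_cosine(de_novo, refs, retained[-i])$cosine, numeric(1))
    drop_i <- which.min(losses)
    if (losses[drop_i] < remove_thresh) {
      retained <- retained[-drop_i]
      cur <- .refit_cosine(de_novo, refs, retained)$cosine
    } else break
  }
  fit <- .refit_cosine(de_novo, refs, retained)
  w <- fit$weights
  names(w) <- colnames(refs)[retained]
  recon <- if (length(retained)) {
    as.numeric(refs[, retained, drop = FALSE] %*% fit$weights)
  } else rep(0, length(de_novo))
  structure(list(weights = w,
                 cosine = fit$cosine,
                 residual = sqrt(sum((de_novo - recon)^2)),
                 status = if (fit$cosine >= novelty_cosine) "decomposed"
                          else "novel"),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("<decomposition>", x$status, " cosine =",
      format(x$cosine, digits = 4), "\n")
  if (length(x$weights)) print(round(x$weights, 4))
  invisible(x)
}
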