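.as_counts <- function(cat) {
  if (inherits(cat, "catalogue_matrix")) cat$counts else as.matrix(cat)
}

#' Poisson-resample a catalogue
#'
#' Every entry is independently replaced by a Poisson draw with mean equal
#' to the observed count; zeros stay zero. This is the resampling step in
#' front of each NMF replicate and the parametric bootstrap used for
#' attribution confidence intervals.
#'
#' @param cat \code{catalogue_matrix} or nonnegative matrix.
#' @param seed optional integer seed (sets the RNG).
#' @return matrix of the same shape (or \code{catalogue_matrix} if one was
#'   supplied).
#' @export
poisson_resample <- function(cat, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- .as_counts(cat)
  if (any(m < 0)) stop("poisson_resample: matrix must be nonnegative")
  r <- matrix(stats::rpois(length(m), lambda = as.numeric(m)),
              nrow = nrow(m), dimnames = dimnames(m))
  if (inherits(cat, "catalogue_matrix")) {
    cat$counts <- r
    cat
  } else r
}

#' Cap hypermutator samples before factorization
#'
#' Columns whose total exceeds \code{factor_cap} times the median column
#' total are rescaled (and rounded) to that cap so extreme-burden samples do
#' not dominate the factorization. The applied scale factors are returned so
#' downstream attribution can be reported on the original scale.
#'
#' @param cat catalogue or matrix.
#' @param factor_cap multiple of the median column total above which a
#'   column is rescaled (> 1; default 10).
#' @return list with \code{counts} (rescaled matrix) and \code{scale}
#'   (per-sample factors, 1 for untouched samples).
#' @export
renormalize_hypermutators <- function(cat, factor_cap = 10) {
  stopifnot(factor_cap > 1)
  m <- .as_counts(cat)
  tot <- colSums(m)
  if (all(tot == 0)) stop("renormalize_hypermutators: all-zero matrix")
  med <- stats::median(tot)
  cap <- factor_cap * med
  scale <- ifelse(tot > cap, cap / tot, 1)
  out <- round(sweep(m, 2, scale, "*"))
  list(counts = out, scale = scale)
}

# Nonnegative double SVD initialization ("nndsvd_min" variant: zero or
# negative entries are replaced by the smallest positive value of V, making
# the initialization deterministic and strictly positive).
nndsvd_min_init <- function(V, k) {
  sv <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k)
  H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      x <- sv$u[, j]; y <- sv$v[, j]
      xp <- pmax(x, 0); xn <- pmax(-x, 0)
      yp <- pmax(y, 0); yn <- pmax(-y, 0)
      nxp <- sqrt(sum(xp^2)); nyp <- sqrt(sum(yp^2))
      nxn <- sqrt(sum(xn^2)); nyn <- sqrt(sum(yn^2))
      mp <- nxp * nyp; mn <- nxn * nyn
      if (mp >= mn && mp > 0) {
        W[, j] <- sqrt(sv$d[j] * mp) * xp / nxp
        H[j, ] <- sqrt(sv$d[j] * mp) * yp / nyp
      } else if (mn > 0) {
        W[, j] <- sqrt(sv$d[j] * mn) * xn / nxn
        H[j, ] <- sqrt(sv$d[j] * mn) * yn / nyn
      }
    }
  }
  minpos <- min(V[V > 0])
  W[W <= 0] <- minpos
  H[H <= 0] <- minpos
  list(W = W, H = H)
}

#' Kullback-Leibler NMF by multiplicative updates
#'
#' Factorizes a nonnegative matrix \code{V ~ W H} under the generalized
#' Kullback-Leibler divergence using multiplicative updates, initialized
#' either with nonnegative double SVD (deterministic) or at random. The
#' objective is non-increasing across iterations; iteration stops when the
#' relative objective change falls below \code{tol}. Signature columns of
#' \code{W} are normalized to sum 1 post hoc, with the scale absorbed into
#' \code{H}.
#'
#' @param V nonnegative channels x samples matrix.
#' @param k number of signatures, \code{1 <= k <= min(dim(V))}.
#' @param init \code{"nndsvd_min"} (default) or \code{"random"}.
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param seed RNG seed (used by random init).
#' @param trace keep the per-iteration objective values.
#' @return object of class \code{nmf_solution}: list with \code{W},
#'   \code{H}, \code{objective}, \code{iterations}, \code{objective_trace}
#'   (if traced), \code{seed}.
#' @export
nmf_kl <- function(V, k, init = c("nndsvd_min", "random"), tol = 1e-8,
                   max_iter = 10000L, seed = NULL, trace = FALSE) {
  init <- match.arg(init)
  V <- as.matrix(V)
  if (any(!is.finite(V))) stop("nmf_kl: V contains non-finite values")
  if (any(V < 0)) stop("nmf_kl: V must be nonnegative")
  if (k < 1 || k > min(dim(V)))
    stop("nmf_kl: k must be between 1 and min(dim(V))")
  if (!is.null(seed)) set.seed(seed)
  # zero rows cannot move under multiplicative updates; lift with a
  # negligible pseudocount
  zr <- rowSums(V) == 0
  if (any(zr)) V[zr, ] <- 1e-12
  fac <- if (init == "nndsvd_min") {
    nndsvd_min_init(V, k)
  } else {
    list(W = matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k),
         H = matrix(stats::runif(k * ncol(V), 0.1, 1), k, ncol(V)))
  }
  res <- nmf_kl_cpp(V, fac$W, fac$H, tol, as.integer(max_iter), 1e-16,
                    trace)
  W <- res$W
  H <- res$H
  cs <- colSums(W)
  cs[cs == 0] <- 1
  W <- sweep(W, 2, cs, "/")
  H <- sweep(H, 1, cs, "*")
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  structure(list(W = W, H = H, objective = res$objective,
                 iterations = res$iterations,
                 objective_trace = res$objective_trace,
                 seed = seed),
            class = "nmf_solution")
}

#' @export
print.nmf_solution <- function(x, ...) {
  cat("<nmf_solution> k =", ncol(x$W), " KL =",
      format(x$objective, digits = 6),
      " iterations =", x$iterations, "\n")
  invisible(x)
}
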