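#' Dichotomize cohort attributions into binary outcomes
#'
#' Signatures present (bootstrap CI excluding zero at both limits) in at
#' least \code{prevalence_threshold} of cases are split above/below the
#' median of attributed mutation counts across all cases; rarer signatures
#' are coded present/absent by the CI rule.
#'
#' @param attr_table long attribution table (columns \code{sample_id},
#'   \code{signature}, \code{exposure}, \code{ci_low}, \code{ci_high},
#'   \code{present}), e.g. \code{attribute_cohort(...)$table}.
#' @param prevalence_threshold prevalence above which the median split is
#'   used (default 0.75).
#' @return data frame, one row per sample, one logical column per
#'   signature; attribute \code{"rule"} records which rule was applied per
#'   signature.
#' @export
dichotomize <- function(attr_table, prevalence_threshold = 0.75) {
  sigs <- unique(attr_table$signature)
  samples <- unique(attr_table$sample_id)
  out <- data.frame(sample_id = samples)
  rule <- character(length(sigs))
  names(rule) <- sigs
  for (s in sigs) {
    sub <- attr_table[attr_table$signature == s, ]
    sub <- sub[match(samples, sub$sample_id), ]
    prev <- mean(sub$present)
    if (prev >= prevalence_threshold) {
      med <- stats::median(sub$exposure)
      out[[s]] <- sub$exposure > med
      rule[s] <- "median_split"
    } else {
      out[[s]] <- sub$present
      rule[s] <- "ci_presence"
    }
  }
  attr(out, "rule") <- rule
  out
}

# Firth-type penalized logistic regression (Jeffreys prior); used as the
# fallback when ordinary ML shows separation. Returns coefficients and
# Wald statistics from the penalized information matrix.
.firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-6) {
  # drop aliased columns so the information matrix stays invertible
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)
  beta <- rep(0, p)
  ridge <- function(I) I + diag(1e-6 * max(diag(I), 1), p)
  pen_loglik <- function(b) {
    eta <- pmin(pmax(as.numeric(Xk %*% b), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    W <- pmax(mu * (1 - mu), 1e-12)
    I <- crossprod(Xk * sqrt(W))
    sum(y * eta - log1p(exp(eta))) +
      0.5 * determinant(ridge(I), logarithm = TRUE)$modulus
  }
  ll <- pen_loglik(beta)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(as.numeric(Xk %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    W <- pmax(mu * (1 - mu), 1e-12)
    XW <- Xk * sqrt(W)
    I <- crossprod(XW)
    Iinv <- solve(ridge(I))
    h <- rowSums((XW %*% Iinv) * XW)
    U <- as.numeric(t(Xk) %*% (y - mu + h * (0.5 - mu)))
    delta <- as.numeric(Iinv %*% U)
    # step-halving keeps the penalized likelihood climbing
    step <- 1
    repeat {
      cand <- beta + step * delta
      llc <- pen_loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-6) { cand <- beta; llc <- ll; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    ll <- llc
    if (moved < tol) break
  }
  eta <- pmin(pmax(as.numeric(Xk %*% beta), -30), 30)
  mu <- 1 / (1 + exp(-eta))
  W <- pmax(mu * (1 - mu), 1e-12)
  I <- crossprod(Xk * sqrt(W))
  se_k <- sqrt(diag(solve(ridge(I))))
  coef <- rep(NA_real_, ncol(X))
  se <- rep(NA_real_, ncol(X))
  coef[keep] <- beta
  se[keep] <- se_k
  list(coef = coef, se = se)
}

#' Logistic regression of a dichotomized signature on a risk factor
#'
#' Fits \code{outcome ~ factor + sex + age_dx + country + smoking} by
#' maximum likelihood and reports the Wald estimate and raw p-value of the
#' factor term. When complete or quasi-complete separation is detected the
#' model is refit by Firth-type penalized likelihood and flagged. The
#' Bonferroni family size is recorded alongside the raw p-value.
#'
#' @param outcome logical/binary vector, one per sample.
#' @param factor risk-factor vector (numeric or factor).
#' @param cohort data frame with covariate columns \code{sex},
#'   \code{age_dx}, \code{country}, \code{smoking} (any subset present is
#'   used).
#' @param covariates character vector naming cohort columns to adjust for.
#' @param family_size Bonferroni family size recorded with the result.
#' @return data frame (class \code{test_result}) with one row per
#'   non-reference level of \code{factor}: term, estimate (log-odds),
#'   p_value, n, method, family_size.
#' @export
risk_factor_regression <- function(outcome, factor, cohort,
                                   covariates = c("sex", "age_dx",
                                                  "country", "smoking"),
                                   family_size = NA_integer_) {
  if (length(unique(stats::na.omit(outcome))) < 2L)
    stop("risk_factor_regression: outcome has fewer than 2 classes")
  if (length(unique(stats::na.omit(factor))) < 2L)
    stop("risk_factor_regression: factor is constant")
  covariates <- intersect(covariates, names(cohort))
  df <- data.frame(.y = as.integer(outcome), .f = factor,
                   cohort[covariates], check.names = FALSE)
  # drop covariates that are constant in this cohort (e.g. single country)
  for (cv in covariates)
    if (length(unique(stats::na.omit(df[[cv]]))) < 2L) df[[cv]] <- NULL
  fml <- stats::as.formula(paste(".y ~ .f",
    if (ncol(df) > 2L)
      paste("+", paste(sprintf("`%s`", setdiff(names(df), c(".y", ".f"))),
                       collapse = " + "))
    else ""))
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  sep <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  method <- "ml_logistic"
  if (sep) {
    X <- stats::model.matrix(fml, df)
    fr <- .firth_logistic(X, df$.y[as.integer(rownames(X))])
    cf <- cbind(Estimate = fr$coef, `Std. Error` = fr$se,
                `z value` = fr$coef / fr$se,
                `Pr(>|z|)` = 2 * stats::pnorm(-abs(fr$coef / fr$se)))
    rownames(cf) <- colnames(X)
    method <- "firth_logistic"
  }
  rows <- grep("^\\.f", rownames(cf))
  res <- data.frame(term = sub("^\\.f", "", rownames(cf)[rows]),
                    estimate = cf[rows, 1],
                    p_value = cf[rows, 4],
                    n = sum(stats::complete.cases(df)),
                    method = method,
                    family_size = family_size,
                    row.names = NULL)
  class(res) <- c("test_result", "data.frame")
  res
}

#' Linear regression of burden or exposure on country incidence
#'
#' Ordinary least squares of a per-sample response on the country-level
#' age-standardized incidence rate (ASR per 100,000), adjusting for sex and
#' age at diagnosis. Reports the ASR slope and its raw p-value.
#'
#' @param response numeric vector (mutation burden or signature exposure).
#' @param cohort data frame with columns \code{asr} and optionally
#'   \code{sex}, \code{age_dx}, \code{country}.
#' @return one-row \code{test_result} data frame (term \code{"asr"}).
#' @export
asr_regression <- function(response, cohort) {
  if (!"asr" %in% names(cohort)) stop("asr_regression: cohort lacks asr")
  if ("country" %in% names(cohort) &&
      length(unique(cohort$country)) < 2L)
    stop("asr_regression: single-country cohort (ASR is constant)")
  if (length(unique(cohort$asr)) < 2L)
    stop("asr_regression: ASR is constant")
  df <- data.frame(.y = response, asr = cohort$asr)
  for (cv in c("sex", "age_dx"))
    if (cv %in% names(cohort) &&
        length(unique(stats::na.omit(cohort[[cv]]))) > 1L)
      df[[cv]] <- cohort[[cv]]
  fit <- stats::lm(.y ~ ., data = df)
  cf <- summary(fit)$coefficients
  res <- data.frame(term = "asr", estimate = cf["asr", 1],
                    p_value = cf["asr", 4],
                    n = sum(stats::complete.cases(df)),
                    method = "ols", family_size = NA_integer_,
                    row.names = NULL)
  class(res) <- c("test_result", "data.frame")
  res
}

#' Test mutation-burden differences between countries
#'
#' Kruskal-Wallis rank test of per-sample burdens across countries
#' (robust to the heavy-tailed burden distributions typical of mutation
#' counts). Countries with fewer than 2 samples are excluded with a
#' warning.
#'
#' @param burden numeric per-sample burden.
#' @param country country labels.
#' @return one-row \code{test_result} data frame.
#' @export
country_burden_test <- function(burden, country) {
  country <- as.character(country)
  tab <- table(country)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("country_burden_test: excluding countries with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(country %in% small)
    burden <- burden[keep]
    country <- country[keep]
  }
  if (length(unique(country)) < 2L)
    stop("country_burden_test: need at least 2 countries")
  kt <- stats::kruskal.test(burden, factor(country))
  res <- data.frame(term = "country", estimate = unname(kt$statistic),
                    p_value = kt$p.value, n = length(burden),
                    method = "kruskal_wallis", family_size = NA_integer_,
                    row.names = NULL)
  class(res) <- c("test_result", "data.frame")
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' \code{q_i = min_{j >= i} m p_(j) / j}, capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Exact null distribution when at most 25 non-zero differences are present
#' and the absolute differences are tie-free; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{p_value}, \code{statistic} (V), \code{n_eff}
#'   (non-zero differences), \code{exact}.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  dnz <- d[d != 0]
  n_eff <- length(dnz)
  if (n_eff == 0L)
    return(list(p_value = 1, statistic = 0, n_eff = 0L, exact = TRUE))
  ties <- any(duplicated(abs(dnz)))
  exact <- n_eff <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                       correct = TRUE, alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_eff = n_eff, exact = exact)
}

#' Clonal versus subclonal signature enrichment
#'
#' For every sample, attributes the clonal and subclonal spectra separately
#' against a fixed signature panel (pruned NNLS), normalizes activities by
#' the total mutations of the clone or subclone, and compares the paired
#' relative activities per signature across samples with a two-sided
#' Wilcoxon signed-rank test; p-values are Benjamini-Hochberg adjusted
#' across signatures.
#'
#' @param clonal_cat,subclonal_cat channels x samples matrices (same sample
#'   columns) of clonal and subclonal mutation counts.
#' @param panel channels x signatures matrix.
#' @param penalty pruning penalty (default 0.008, SBS).
#' @param min_samples minimum number of paired samples required (default
#'   10).
#' @return \code{test_result} data frame, one row per tested signature:
#'   mean relative activity in clones and subclones, difference, p and q
#'   values.
#' @export
clonal_subclonal_enrichment <- function(clonal_cat, subclonal_cat, panel,
                                        penalty = 0.008,
                                        min_samples = 10L) {
  clonal_cat <- as.matrix(clonal_cat)
  subclonal_cat <- as.matrix(subclonal_cat)
  shared <- intersect(colnames(clonal_cat), colnames(subclonal_cat))
  if (length(shared) < min_samples)
    stop("clonal_subclonal_enrichment: fewer than ", min_samples,
         " paired samples")
  rel_activity <- function(v) {
    tot <- sum(v)
    if (tot == 0) return(rep(NA_real_, ncol(panel)))
    pr <- prune_attribution(v, panel, penalty)
    .clip_exposures(pr$exposures, tot) / tot
  }
  A_cl <- vapply(shared, function(s) rel_activity(clonal_cat[, s]),
                 numeric(ncol(panel)))
  A_sub <- vapply(shared, function(s) rel_activity(subclonal_cat[, s]),
                  numeric(ncol(panel)))
  rownames(A_cl) <- rownames(A_sub) <- colnames(panel)
  res <- do.call(rbind, lapply(colnames(panel), function(s) {
    xc <- A_cl[s, ]
    xs <- A_sub[s, ]
    ok <- !is.na(xc) & !is.na(xs)
    if (all(xc[ok] == 0) && all(xs[ok] == 0)) return(NULL)
    wt <- wilcoxon_signed_rank(xc[ok], xs[ok])
    data.frame(signature = s,
               mean_clonal = mean(xc[ok]), mean_subclonal = mean(xs[ok]),
               estimate = mean(xc[ok]) - mean(xs[ok]),
               p_value = wt$p_value, n = sum(ok), row.names = NULL)
  }))
  if (is.null(res) || nrow(res) == 0L)
    stop("clonal_subclonal_enrichment: no signature with activity")
  res$q_value <- bh_adjust(res$p_value)
  class(res) <- c("test_result", "data.frame")
  res
}

#' T>A enrichment of the driver-mutation spectrum in exposed cases
#'
#' Compares the proportion of T>A substitutions among driver SNVs between
#' exposed and unexposed cases with a two-sided Fisher exact test on the
#' 2x2 table (T>A vs other) x (exposed vs unexposed).
#'
#' @param class six-class labels of driver SNVs (e.g. \code{"T>A"}),
#'   or SBS-96 labels (collapsed automatically).
#' @param exposed logical exposure label per driver mutation.
#' @param target the mutation class tested for enrichment (default
#'   \code{"T>A"}).
#' @return list with \code{prop_exposed}, \code{prop_unexposed},
#'   \code{p_value}, \code{table} (the 2x2 counts), \code{odds_ratio}.
#' @export
driver_spectrum_enrichment <- function(class, exposed, target = "T>A") {
  if (any(grepl("\\[", class)))
    class <- sub("^.\\[(.>.)\\].$", "\\1", class)
  exposed <- as.logical(exposed)
  if (!any(exposed) || !any(!exposed))
    stop("driver_spectrum_enrichment: one exposure group is empty")
  is_t <- class == target
  tab <- matrix(c(sum(is_t & exposed), sum(!is_t & exposed),
                  sum(is_t & !exposed), sum(!is_t & !exposed)),
                nrow = 2,
                dimnames = list(c(target, "other"),
                                c("exposed", "unexposed")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(prop_exposed = mean(is_t[exposed]),
       prop_unexposed = mean(is_t[!exposed]),
       p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       table = tab)
}
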