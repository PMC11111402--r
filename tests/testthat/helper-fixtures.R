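# shared fixtures: small planted panels and cohorts built in code

# independent reverse complement (kept separate from the package's helper
# so classification tests do not lean on the code under test)
rc_oracle <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
         function(s) paste(rev(s), collapse = ""), "")
}

# a well-separated 5-signature SBS-96 panel used across attribution tests
test_panel <- function(seed = 11) {
  make_planted_signatures(
    "SBS96",
    shapes = c("ta_heavy", "tc_heavy", "cpg_ct", "flat", "random"),
    separation = 0.65, seed = seed)
}

# spectrum drawn from a signature mixture at a given total burden
mixture_spectrum <- function(panel, weights, total) {
  p <- as.numeric(panel %*% (weights / sum(weights)))
  as.integer(stats::rmultinom(1, total, p))
}

# small multi-country scenario (scaled-down sample sizes) for cohort tests
small_scenario <- function(divisor = 20L, seed = 20260901L) {
  cfg <- default_scenario(seed = seed)
  cfg$countries$n <- pmax(2L, cfg$countries$n %/% divisor)
  cfg
}

# grid-search NNLS oracle: residual sum of squares minimized over an
# exposure grid (resolution `step` mutations per signature)
grid_nnls_rss <- function(spectrum, panel, upper, step) {
  g <- seq(0, upper, by = step)
  E <- as.matrix(expand.grid(rep(list(g), ncol(panel))))
  G <- crossprod(panel)            # k x k
  t <- crossprod(panel, spectrum)  # k x 1
  rss <- sum(spectrum^2) - 2 * (E %*% t) + rowSums((E %*% G) * E)
  min(rss)
}

# exact two-sided signed-rank p-value by full enumeration over sign
# assignments (handles ties in |d| correctly); oracle for n <= 12
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_low <- mean(v_all <= v_obs + 1e-12)
  p_high <- mean(v_all >= v_obs - 1e-12)
  min(1, 2 * min(p_low, p_high))
}
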