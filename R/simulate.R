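#' Construct planted signature profiles
#'
#' Builds a column-stochastic panel of synthetic signatures with controlled
#' pairwise separation. Named shapes mimic processes relevant to kidney
#' cancer: \code{"ta_heavy"} concentrates mass on T>A channels (the
#' aristolochic-acid pattern), \code{"tc_heavy"} on T>C channels,
#' \code{"cpg_ct"} on C>T at CpG-like contexts (clock-like), and
#' \code{"flat"} is uniform over all channels. \code{"random"} signatures
#' concentrate most mass on a random channel subset.
#'
#' @param schema schema name or [channel_schema()] (default SBS96).
#' @param k number of signatures (>= 2) when \code{shapes} is NULL.
#' @param separation maximum allowed pairwise cosine (default 0.6).
#' @param shapes optional character vector of named shapes (overrides
#'   \code{k}).
#' @param seed RNG seed.
#' @return channels x signatures column-stochastic matrix.
#' @export
make_planted_signatures <- function(schema = "SBS96", k = 3,
                                    separation = 0.6, shapes = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(schema)) schema <- channel_schema(schema)
  channels <- schema$channels
  nch <- length(channels)
  if (is.null(shapes)) {
    if (k < 2) stop("make_planted_signatures: k must be >= 2")
    shapes <- rep("random", k)
  }
  k <- length(shapes)
  shape_profile <- function(shape) {
    w <- rep(1 / nch, nch)
    pick_class <- function(cls) {
      if (schema$name %in% c("SBS96", "SBS288"))
        grepl(paste0("\\[", cls, "\\]"), channels)
      else rep(TRUE, nch)
    }
    if (shape == "flat") {
      w
    } else if (shape == "ta_heavy") {
      idx <- which(pick_class("T>A"))
      w[] <- 0.1 / nch
      peak <- stats::rgamma(length(idx), shape = 1.5)
      w[idx] <- 0.9 * peak / sum(peak)
      w / sum(w)
    } else if (shape == "tc_heavy") {
      idx <- which(pick_class("T>C"))
      w[] <- 0.1 / nch
      peak <- stats::rgamma(length(idx), shape = 1.5)
      w[idx] <- 0.9 * peak / sum(peak)
      w / sum(w)
    } else if (shape == "cpg_ct") {
      idx <- which(pick_class("C>T") & grepl("\\]G$", channels))
      if (!length(idx)) idx <- which(pick_class("C>T"))
      w[] <- 0.15 / nch
      peak <- stats::rgamma(length(idx), shape = 2)
      w[idx] <- 0.85 * peak / sum(peak)
      w / sum(w)
    } else if (shape == "random") {
      idx <- sample.int(nch, max(4L, nch %/% 12L))
      w[] <- 0.1 / nch
      peak <- stats::rgamma(length(idx), shape = 1)
      w[idx] <- 0.9 * peak / sum(peak)
      w / sum(w)
    } else stop("make_planted_signatures: unknown shape ", shape)
  }
  for (attempt in 1:200) {
    sigs <- vapply(shapes, shape_profile, numeric(nch))
    if (k == 1L) break
    cs <- .cosine_cols(sigs, sigs)
    if (max(cs[upper.tri(cs)]) <= separation) break
    if (attempt == 200)
      stop("make_planted_signatures: requested separation infeasible")
  }
  sigs <- matrix(sigs, nrow = nch)
  rownames(sigs) <- channels
  colnames(sigs) <- make.unique(paste0("SIG_", shapes), sep = "")
  sigs
}

# --- inverse classification -------------------------------------------------
# For every channel of every schema, produce a mutation record whose
# classification is exactly that channel. Used by the simulator to emit
# record-level data whose rebuilt catalogue reproduces planted counts.

.other_base <- function(...) {
  setdiff(c("A", "C", "G", "T"), unlist(list(...)))[1]
}

.invert_sbs <- function(label) {
  f5 <- substr(label, 1, 1)
  ref <- substr(label, 3, 3)
  alt <- substr(label, 5, 5)
  f3 <- substr(label, 7, 7)
  list(ref = ref, alt = alt, context5 = f5, context3 = f3, strand = NULL)
}

.invert_sbs288 <- function(label) {
  strand <- c(T = "transcribed", U = "untranscribed",
              N = "unknown")[substr(label, 1, 1)]
  rec <- .invert_sbs(substr(label, 3, nchar(label)))
  rec$strand <- unname(strand)
  rec
}

.invert_dbs <- function(label) {
  list(ref = substr(label, 1, 2), alt = substr(label, 4, 5),
       context5 = "A", context3 = "A", strand = NULL)
}

# indel repeat units whose first and last bases differ and that are
# aperiodic, so flank construction can suppress unintended repeats
.ID_UNITS <- c("1" = "", "2" = "AC", "3" = "ACG", "4" = "ACGT",
               "5" = "ACGTT", "6" = "ACGTAC")

.invert_indel <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  Lc <- as.integer(parts[1])
  kind <- parts[2]
  sub <- parts[3]
  num <- as.integer(parts[4])
  if (Lc == 1L) {
    s <- sub              # "C" or "T"
    first <- s
    last <- s
  } else if (sub == "M" && Lc == 5L && num == 5L) {
    s <- .ID_UNITS[["6"]] # homology 5 needs length >= 6
    first <- substr(s, 1, 1)
    last <- substr(s, nchar(s), nchar(s))
  } else {
    s <- .ID_UNITS[[as.character(Lc)]]
    first <- substr(s, 1, 1)
    last <- substr(s, nchar(s), nchar(s))
  }
  L <- nchar(s)
  flank5_base <- .other_base(last, first)
  flank5 <- strrep(flank5_base, 11)
  if (sub %in% c("C", "T", "R")) {
    extra <- if (kind == "Del") num else num   # copies beyond the event
    tail_base <- .other_base(first, flank5_base)
    context3 <- paste0(strrep(s, extra), strrep(tail_base, 12))
  } else { # microhomology
    h <- num
    partial <- substr(s, 1, h)
    nxt <- substr(s, h + 1, h + 1)
    tail_base <- .other_base(nxt, first)
    context3 <- paste0(partial, strrep(tail_base, 12))
  }
  anchor <- substr(flank5, 11, 11)
  context5 <- substr(flank5, 1, 10)
  if (kind == "Del") {
    list(ref = paste0(anchor, s), alt = anchor,
         context5 = context5, context3 = context3, strand = NULL)
  } else {
    list(ref = anchor, alt = paste0(anchor, s),
         context5 = context5, context3 = context3, strand = NULL)
  }
}

#' Mutation record template for a channel label
#'
#' Inverse classification: returns ref/alt/context fields that the
#' corresponding classifier maps back to \code{label}. Contexts are minimal
#' synthetic strings; coordinates carry no genomic meaning.
#'
#' @param label channel label.
#' @param schema schema name or object.
#' @return list with \code{ref}, \code{alt}, \code{context5},
#'   \code{context3} and (for SBS288) \code{strand}.
#' @export
channel_record <- function(label, schema) {
  name <- if (inherits(schema, "channel_schema")) schema$name else schema
  switch(name,
         SBS96 = .invert_sbs(label),
         SBS288 = .invert_sbs288(label),
         DBS78 = .invert_dbs(label),
         ID83 = .invert_indel(label),
         stop("channel_record: unknown schema ", name))
}

# --- scenario ---------------------------------------------------------------

#' Default multi-country simulation scenario
#'
#' Eleven countries with cohort sizes and kidney-cancer incidence (ASR per
#' 100,000) mirroring the international study setting, and a four-signature
#' SBS panel:
#' \itemize{
#'   \item \code{SIG_flat} — flat, ubiquitous; its mean burden increases
#'     linearly with country ASR (\code{asr_intercept + asr_slope * ASR});
#'   \item \code{SIG_cpg_ct} — clock-like C>T, ubiquitous, modest burden;
#'   \item \code{SIG_ta} — T>A-heavy, concentrated in Romania (70%),
#'     Serbia (23%) and Thailand (60%), with high burdens where present;
#'   \item \code{SIG_tc} — T>C-heavy, 72% prevalence in Japan and 2%
#'     elsewhere.
#' }
#' These prevalences and burden scales are simulation inputs chosen to
#' echo the published cohort structure; they are not asserted outputs.
#'
#' @param seed seed used when drawing the signature profiles.
#' @return a \code{simulation_config} list.
#' @export
default_scenario <- function(seed = 20260901L) {
  countries <- data.frame(
    name = c("Brazil", "Canada", "Czechia", "Japan", "Lithuania",
             "Poland", "Romania", "Russia", "Serbia", "Thailand", "UK"),
    asr = c(4.5, 10.4, 14.4, 7.6, 14.5, 8.1, 7.7, 10.3, 7.4, 1.8, 10.3),
    n = c(96L, 73L, 259L, 36L, 16L, 13L, 64L, 216L, 69L, 5L, 115L))
  sigs <- make_planted_signatures(
    schema = "SBS96",
    shapes = c("flat", "cpg_ct", "ta_heavy", "tc_heavy"),
    separation = 0.65, seed = seed)
  colnames(sigs) <- c("SIG_flat", "SIG_cpg_ct", "SIG_ta", "SIG_tc")
  prevalence <- matrix(0.02, nrow = nrow(countries), ncol = 4,
                       dimnames = list(countries$name, colnames(sigs)))
  prevalence[, "SIG_flat"] <- 1
  prevalence[, "SIG_cpg_ct"] <- 1
  prevalence["Romania", "SIG_ta"] <- 0.70
  prevalence["Serbia", "SIG_ta"] <- 0.23
  prevalence["Thailand", "SIG_ta"] <- 0.60
  prevalence["Japan", "SIG_tc"] <- 0.72
  structure(list(
    countries = countries,
    signatures = sigs,
    prevalence = prevalence,
    burden = list(
      # log-normal sdlog per signature; means below
      SIG_flat = list(sdlog = 0.35, asr_intercept = 1500, asr_slope = 180),
      SIG_cpg_ct = list(sdlog = 0.4, mean = 1200),
      SIG_ta = list(sdlog = 0.7, mean = 9000),
      SIG_tc = list(sdlog = 0.5, mean = 1800)),
    covariates = list(
      p_male = 0.6,
      age_mean = 62, age_sd = 10,
      smoking = c(current = 0.25, ex = 0.25, never = 0.50),
      p_hypertension = 0.5, p_diabetes = 0.14,
      bmi_mean = 27, bmi_sd = 4.5),
    # multiplicative odds effects of current smoking on presence
    smoking_or = c(SIG_flat = 1, SIG_cpg_ct = 1, SIG_ta = 1, SIG_tc = 1),
    clone_delta = c(SIG_flat = 0, SIG_cpg_ct = 0, SIG_ta = 0.2,
                    SIG_tc = 0)),
    class = "simulation_config")
}

# mean burden of a signature for a sample of a given country
.sig_mean_burden <- function(bcfg, asr) {
  if (!is.null(bcfg$mean)) bcfg$mean
  else bcfg$asr_intercept + bcfg$asr_slope * asr
}

#' Simulate a multi-country cohort with planted ground truth
#'
#' Per sample: the signature set is drawn from country-specific prevalence
#' (optionally modulated by a planted smoking odds ratio); per-signature
#' burdens are log-normal with country-dependent means; channel counts are
#' multinomial draws from the signature profile conditional on the burden,
#' so planted exposures sum exactly to the per-sample mutation total.
#'
#' @param cfg a \code{simulation_config}, e.g. [default_scenario()].
#' @param seed RNG seed.
#' @param emit_records also materialize one mutation record per mutation
#'   via inverse classification (exact round trip through
#'   [build_catalogue()]); off by default as large cohorts need only the
#'   catalogue.
#' @param mode \code{"multinomial"} (default) draws channel counts
#'   conditional on the drawn burden, so ground-truth exposures sum to the
#'   sample total exactly; \code{"poisson"} draws each channel
#'   independently Poisson around its mean, matching the parametric model
#'   assumed by the attribution bootstrap (the recorded true exposure is
#'   then the planted mean, not a realized count).
#' @return list with \code{catalogue} (\code{catalogue_matrix}),
#'   \code{cohort} (per-sample covariates incl. country and ASR),
#'   \code{ground_truth} (list: \code{exposures} signatures x samples,
#'   \code{present}), \code{signatures} (the planted panel), and
#'   \code{records} (when requested).
#' @export
simulate_cohort <- function(cfg, seed = 1L, emit_records = FALSE,
                            mode = c("multinomial", "poisson")) {
  mode <- match.arg(mode)
  set.seed(seed)
  ctries <- cfg$countries
  sigs <- cfg$signatures
  channels <- rownames(sigs)
  signames <- colnames(sigs)
  n_total <- sum(ctries$n)
  sample_id <- sprintf("S%04d", seq_len(n_total))
  country <- rep(ctries$name, ctries$n)
  asr <- rep(ctries$asr, ctries$n)
  cv <- cfg$covariates
  sex <- sample(c("male", "female"), n_total, replace = TRUE,
                prob = c(cv$p_male, 1 - cv$p_male))
  age_dx <- pmax(18, round(stats::rnorm(n_total, cv$age_mean, cv$age_sd)))
  smoking <- sample(names(cv$smoking), n_total, replace = TRUE,
                    prob = cv$smoking)
  bmi <- round(stats::rnorm(n_total, cv$bmi_mean, cv$bmi_sd), 1)
  hypertension <- stats::runif(n_total) < cv$p_hypertension
  diabetes <- stats::runif(n_total) < cv$p_diabetes
  exposures <- matrix(0, nrow = length(signames), ncol = n_total,
                      dimnames = list(signames, sample_id))
  counts <- matrix(0L, nrow = length(channels), ncol = n_total,
                   dimnames = list(channels, sample_id))
  for (i in seq_len(n_total)) {
    prev <- cfg$prevalence[country[i], ]
    if (!is.null(cfg$smoking_or) && smoking[i] == "current") {
      or <- cfg$smoking_or[signames]
      odds <- prev / (1 - prev) * or
      prev <- ifelse(prev >= 1, 1, odds / (1 + odds))
    }
    present <- stats::runif(length(signames)) < prev
    for (s in which(present)) {
      bcfg <- cfg$burden[[signames[s]]]
      mu <- .sig_mean_burden(bcfg, asr[i])
      meanlog <- log(mu) - bcfg$sdlog^2 / 2
      burden <- max(1L, round(stats::rlnorm(1, meanlog, bcfg$sdlog)))
      exposures[s, i] <- burden
      counts[, i] <- counts[, i] + if (mode == "multinomial") {
        as.integer(stats::rmultinom(1, burden, sigs[, s]))
      } else {
        as.integer(stats::rpois(nrow(sigs), burden * sigs[, s]))
      }
    }
  }
  schema <- channel_schema(if (length(channels) == 96) "SBS96"
                           else if (length(channels) == 78) "DBS78"
                           else if (length(channels) == 83) "ID83"
                           else "SBS96")
  catalogue <- structure(list(schema = schema, sample_ids = sample_id,
                              counts = counts,
                              log = list(n_input = sum(counts),
                                         n_classified = sum(counts),
                                         n_skipped_type = 0L,
                                         n_unclassifiable = 0L)),
                         class = "catalogue_matrix")
  cohort <- data.frame(sample_id = sample_id, country = country, asr = asr,
                       sex = sex, age_dx = age_dx, smoking = smoking,
                       bmi = bmi, hypertension = hypertension,
                       diabetes = diabetes, stringsAsFactors = FALSE)
  out <- list(catalogue = catalogue, cohort = cohort,
              ground_truth = list(exposures = exposures,
                                  present = exposures > 0),
              signatures = sigs, seed = seed)
  if (emit_records) out$records <- catalogue_records(catalogue)
  out
}

#' Materialize a catalogue as individual mutation records
#'
#' Expands a counts matrix into one record per mutation using inverse
#' classification; re-running [build_catalogue()] on the result reproduces
#' the counts exactly.
#'
#' @param cat \code{catalogue_matrix}.
#' @return data frame of mutation records.
#' @export
catalogue_records <- function(cat) {
  schema <- cat$schema
  counts <- cat$counts
  tmpl <- lapply(schema$channels, channel_record, schema = schema)
  names(tmpl) <- schema$channels
  recs <- list()
  pos0 <- 0L
  for (j in seq_len(ncol(counts))) {
    nz <- which(counts[, j] > 0)
    if (!length(nz)) next
    lab <- rep(schema$channels[nz], counts[nz, j])
    t5 <- vapply(tmpl[lab], `[[`, "", "context5")
    t3 <- vapply(tmpl[lab], `[[`, "", "context3")
    rf <- vapply(tmpl[lab], `[[`, "", "ref")
    al <- vapply(tmpl[lab], `[[`, "", "alt")
    df <- data.frame(sample_id = colnames(counts)[j],
                     chrom = "1",
                     pos = pos0 + 100L * seq_along(lab),
                     ref = rf, alt = al,
                     context5 = t5, context3 = t3,
                     stringsAsFactors = FALSE, row.names = NULL)
    if (schema$name == "SBS288")
      df$strand <- vapply(tmpl[lab], `[[`, "", "strand")
    recs[[length(recs) + 1L]] <- df
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate clonal/subclonal structure over a cohort
#'
#' Each sample receives a clone (CCF near 1) and one or two subclones (CCF
#' in (0.3, 0.75]); per-sample mutations are split between clone and
#' subclones, with the clonal signature mixture shifted by the configured
#' \code{clone_delta} (added to the clonal proportion of the target
#' signature and renormalized). A configurable fraction of samples gets
#' filter-violating features — low purity, a CCF > 1.5 cluster, a
#' chrX-dominant cluster, a small clone, a subclone at CCF > 0.80 — with
#' ground-truth flags predicting exactly which samples the timing filters
#' exclude.
#'
#' @param sim output of [simulate_cohort()].
#' @param cfg the same \code{simulation_config}.
#' @param seed RNG seed.
#' @param artifact_fraction fraction of samples receiving one (randomly
#'   chosen) filter-violating feature.
#' @return list with \code{clusters} (cluster summary table),
#'   \code{purity}, \code{clonal_counts} / \code{subclonal_counts}
#'   (channels x samples matrices), and \code{flags} (data frame with
#'   \code{excluded_expected} and \code{reason}).
#' @export
simulate_clusters <- function(sim, cfg, seed = 1L,
                              artifact_fraction = 0.2) {
  set.seed(seed)
  sigs <- cfg$signatures
  signames <- colnames(sigs)
  delta <- cfg$clone_delta[signames]
  exposures <- sim$ground_truth$exposures
  samples <- colnames(exposures)
  n <- length(samples)
  artifacts <- c("purity", "ccf_high", "chrx", "small_clone",
                 "subclone_ccf")
  art <- rep(NA_character_, n)
  is_art <- stats::runif(n) < artifact_fraction
  art[is_art] <- sample(artifacts, sum(is_art), replace = TRUE)
  clusters <- list()
  purity <- data.frame(sample_id = samples,
                       purity = round(stats::runif(n, 0.45, 0.95), 2))
  clonal_counts <- matrix(0L, nrow(sigs), n,
                          dimnames = list(rownames(sigs), samples))
  subclonal_counts <- clonal_counts
  flags <- data.frame(sample_id = samples,
                      excluded_expected = FALSE,
                      reason = NA_character_)
  for (i in seq_len(n)) {
    e <- exposures[, i]
    total <- sum(e)
    mix <- if (total > 0) e / total else rep(1 / length(e), length(e))
    # clone-shifted and subclone mixtures
    mix_cl <- mix + delta * (mix > 0)
    mix_cl <- if (sum(mix_cl) > 0) mix_cl / sum(mix_cl) else mix
    mix_sub <- mix - delta * (mix > 0)
    mix_sub[mix_sub < 0] <- 0
    mix_sub <- if (sum(mix_sub) > 0) mix_sub / sum(mix_sub) else mix
    clone_frac <- stats::runif(1, 0.55, 0.75)
    n_clonal <- round(total * clone_frac)
    n_sub_total <- total - n_clonal
    if (!is.na(art[i]) && art[i] == "small_clone") n_clonal <- 100L
    ccf_clone <- round(stats::rnorm(1, 1, 0.03), 3)
    n_subclones <- sample(1:2, 1)
    ccf_subs <- round(stats::runif(n_subclones, 0.30, 0.75), 3)
    if (!is.na(art[i]) && art[i] == "subclone_ccf") ccf_subs[1] <- 0.85
    # channel spectra
    p_cl <- as.numeric(sigs %*% mix_cl)
    p_sub <- as.numeric(sigs %*% mix_sub)
    clonal_counts[, i] <- as.integer(stats::rmultinom(1, n_clonal, p_cl))
    subclonal_counts[, i] <-
      as.integer(stats::rmultinom(1, n_sub_total, p_sub))
    sub_split <- if (n_subclones == 2L) {
      a <- round(n_sub_total * stats::runif(1, 0.4, 0.6))
      c(a, n_sub_total - a)
    } else n_sub_total
    cl <- data.frame(
      sample_id = samples[i],
      cluster_id = paste0(samples[i], "_c", seq_len(1 + n_subclones)),
      ccf = c(ccf_clone, ccf_subs),
      n_mutations = c(n_clonal, sub_split),
      top_chrom = sample(as.character(1:22), 1 + n_subclones,
                         replace = TRUE),
      clonal_flag = c(TRUE, rep(FALSE, n_subclones)))
    if (!is.na(art[i])) {
      if (art[i] == "purity") purity$purity[i] <- 0.30
      if (art[i] == "ccf_high") {
        cl <- rbind(cl, data.frame(
          sample_id = samples[i],
          cluster_id = paste0(samples[i], "_art"),
          ccf = 1.6, n_mutations = 300L,
          top_chrom = "5", clonal_flag = FALSE))
      }
      if (art[i] == "chrx") {
        cl <- rbind(cl, data.frame(
          sample_id = samples[i],
          cluster_id = paste0(samples[i], "_artx"),
          ccf = 0.5, n_mutations = 300L,
          top_chrom = "X", clonal_flag = FALSE))
      }
    }
    clusters[[i]] <- cl
    expect_excl <- !is.na(art[i]) &&
      art[i] %in% c("purity", "small_clone", "subclone_ccf")
    # small cohorts can fail the 256-mutation rule without an artifact
    if (n_clonal < 256L || n_sub_total < 256L) expect_excl <- TRUE
    flags$excluded_expected[i] <- expect_excl
    flags$reason[i] <- if (expect_excl) {
      if (!is.na(art[i]) && art[i] == "purity") "purity"
      else if (!is.na(art[i]) && art[i] == "subclone_ccf" &&
               n_clonal >= 256L && n_sub_total >= 256L) "subclone_ccf"
      else "min_mutations"
    } else NA_character_
  }
  list(clusters = do.call(rbind, clusters), purity = purity,
       clonal_counts = clonal_counts,
       subclonal_counts = subclonal_counts, flags = flags)
}
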