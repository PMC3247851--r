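clip01 <- function(x) {
  pmin(pmax(x, 0), 1)
}

#' Configuration for the pooled-array experiment simulator
#'
#' Collects the knobs of the generative model in [simulate_experiment()].
#' Defaults emulate a 660-Quad-class pooled beadarray experiment: each SNP
#' assayed by 17 beads per array (typical bead counts are 16-18), array
#' error SD sqrt(3.3e-4) (the mean normalized array variance observed on
#' such arrays), construction error SD chosen so construction contributes
#' 30% of the pooling variance, and a few percent of beads pushed negative
#' by background subtraction.
#'
#' @param n_snps Number of SNPs.
#' @param n_strips Number of array strips; SNPs are assigned to strips in
#'   contiguous blocks (unique SNP groups sit on specific strips).
#' @param maf_law Either a length-2 numeric range for a uniform true-MAF
#'   distribution (default `c(0.05, 0.5)`) or a function `n -> maf vector`.
#' @param n_individuals Default pool size N (overridable per pool).
#' @param sd_construction Per-pool per-SNP construction error SD
#'   (frequency scale).
#' @param sd_array Per-array per-SNP error SD (frequency scale).
#' @param sd_bead Per-bead noise SD on the bead's allele-frequency signal.
#' @param beads_per_snp Beads assaying each SNP on one array (default 17).
#' @param intensity_scale Mean total intensity of a bead.
#' @param intensity_cv Coefficient of variation of total bead intensity.
#' @param strip_red_bias Per-strip multiplicative red-channel inflation
#'   factors (recycled over strips); `NULL` for no bias.
#' @param frac_negative_beads Fraction of beads per array forced to a
#'   negative channel value (emulating background over-subtraction).
#' @param flip_allele_coding If `TRUE` (default) the green-labelled allele
#'   is the minor or the major allele with equal probability per SNP, so
#'   the mean green-allele frequency across SNPs is near 0.5 -- the
#'   property strip normalization relies on.
#' @param seed Integer seed; identical config + seed reproduces the
#'   experiment exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 10000L, n_strips = 4L,
                       maf_law = c(0.05, 0.5), n_individuals = 300L,
                       sd_construction = sqrt(3.3e-4 * 3 / 7),
                       sd_array = sqrt(3.3e-4), sd_bead = 0.03,
                       beads_per_snp = 17L, intensity_scale = 1000,
                       intensity_cv = 0.05, strip_red_bias = NULL,
                       frac_negative_beads = 0.03,
                       flip_allele_coding = TRUE, seed = NULL) {
  stopifnot(n_snps >= 1, n_strips >= 1, n_individuals >= 1,
            sd_construction >= 0, sd_array >= 0, sd_bead >= 0,
            beads_per_snp >= 1, intensity_scale > 0,
            frac_negative_beads >= 0, frac_negative_beads < 1)
  if (is.numeric(maf_law)) {
    stopifnot(length(maf_law) == 2L, maf_law[1L] > 0, maf_law[2L] <= 0.5,
              maf_law[1L] <= maf_law[2L])
    rng <- maf_law
    maf_fun <- function(n) stats::runif(n, rng[1L], rng[2L])
  } else if (is.function(maf_law)) {
    maf_fun <- maf_law
  } else {
    stop("maf_law must be a range c(lo, hi) or a function(n)")
  }
  if (is.null(strip_red_bias)) strip_red_bias <- 1
  if (any(strip_red_bias <= 0)) stop("strip_red_bias factors must be > 0")
  structure(list(n_snps = as.integer(n_snps), n_strips = as.integer(n_strips),
                 maf_fun = maf_fun, n_individuals = as.integer(n_individuals),
                 sd_construction = sd_construction, sd_array = sd_array,
                 sd_bead = sd_bead, beads_per_snp = as.integer(beads_per_snp),
                 intensity_scale = intensity_scale, intensity_cv = intensity_cv,
                 strip_red_bias = rep_len(strip_red_bias, n_strips),
                 frac_negative_beads = frac_negative_beads,
                 flip_allele_coding = isTRUE(flip_allele_coding),
                 seed = seed),
            class = "sim_config")
}

#' Realized pool allele frequencies under binomial sampling
#'
#' Drawing N diploid individuals into a pool samples 2N chromosomes: the
#' realized frequency of each SNP is Binomial(2N, maf) / (2N), with
#' variance maf(1 - maf) / (2N) around the population value.
#'
#' @param maf Vector of population allele frequencies.
#' @param N Number of individuals in the pool.
#' @return Vector of realized pool frequencies.
#' @export
simulate_pool_frequencies <- function(maf, N) {
  stopifnot(N >= 1, all(maf >= 0 & maf <= 1))
  stats::rbinom(length(maf), 2 * N, maf) / (2 * N)
}

#' Simulate a bead-level pooled-array experiment with known ground truth
#'
#' Generative chain per SNP: a true population frequency; a realized pool
#' frequency by binomial sampling of 2N chromosomes (shared by
#' construction replicates, which are built from the same DNA samples);
#' additive Gaussian construction error per constructed pool; additive
#' Gaussian array error per array; additive Gaussian bead noise per bead.
#' Each perturbed frequency is clipped to \[0, 1\] (clip events are
#' counted; heavy clipping invalidates the additive-error reading and is
#' flagged). Bead intensities are then green = I * f and
#' red = I * (1 - f) * bias, with I a per-bead total intensity and bias
#' the strip's red-channel inflation; a configurable fraction of beads per
#' array has one channel forced negative.
#'
#' @param config A [sim_config()].
#' @param pools Data frame describing the layout: `pool_id`, `n_arrays`,
#'   optionally `replicate_of` (pool constructed from the same samples),
#'   `n_individuals` (default from config) and `batch_id`.
#' @return A list of class `pool_sim` with `beads` (bead table in the TSV
#'   dialect of [read_bead_table()]), `truth` (true/realized frequencies at
#'   every stage, injected variance components, clipping and
#'   forced-negative counts) and `pools` (metadata ready for
#'   [decompose_experiment()]).
#' @export
simulate_experiment <- function(config, pools) {
  stopifnot(inherits(config, "sim_config"))
  pools <- as.data.frame(pools)
  if (is.null(pools$pool_id) || is.null(pools$n_arrays)) {
    stop("pools must have columns pool_id and n_arrays")
  }
  pools$pool_id <- as.character(pools$pool_id)
  if (anyDuplicated(pools$pool_id)) stop("duplicated pool_id")
  if (is.null(pools$replicate_of)) pools$replicate_of <- NA_character_
  pools$replicate_of <- as.character(pools$replicate_of)
  if (is.null(pools$n_individuals)) pools$n_individuals <- config$n_individuals
  if (is.null(pools$batch_id)) pools$batch_id <- "all"
  bad <- !is.na(pools$replicate_of) & !pools$replicate_of %in% pools$pool_id
  if (any(bad)) {
    stop("replicate_of refers to unknown pool(s): ",
         paste(pools$replicate_of[bad], collapse = ", "))
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  ns <- config$n_snps
  snp_ids <- sprintf("snp%06d", seq_len(ns))
  strip_of <- ((seq_len(ns) - 1L) %/% ceiling(ns / config$n_strips)) + 1L
  strip_ids <- sprintf("strip%02d", strip_of)
  bias <- config$strip_red_bias[strip_of]

  maf <- config$maf_fun(ns)
  stopifnot(all(maf >= 0 & maf <= 1))
  green_freq <- if (config$flip_allele_coding) {
    flip <- stats::rbinom(ns, 1L, 0.5) == 1L
    ifelse(flip, 1 - maf, maf)
  } else {
    maf
  }

  n_clip <- 0L
  n_draws <- 0L
  clipped <- function(x) {
    n_clip <<- n_clip + sum(x < 0 | x > 1)
    n_draws <<- n_draws + length(x)
    clip01(x)
  }

  # realized pool frequency: shared by construction replicates
  founder_of <- ifelse(is.na(pools$replicate_of), pools$pool_id,
                       pools$replicate_of)
  founders <- unique(founder_of)
  founder_freq <- matrix(NA_real_, ns, length(founders),
                         dimnames = list(NULL, founders))
  for (fd in founders) {
    Nf <- pools$n_individuals[match(fd, pools$pool_id)]
    founder_freq[, fd] <- simulate_pool_frequencies(green_freq, Nf)
  }
  pool_freq <- matrix(NA_real_, ns, nrow(pools),
                      dimnames = list(NULL, pools$pool_id))
  for (i in seq_len(nrow(pools))) {
    pool_freq[, i] <- clipped(founder_freq[, founder_of[i]] +
                                stats::rnorm(ns, 0, config$sd_construction))
  }

  arr_pool <- rep(pools$pool_id, pools$n_arrays)
  arr_ids <- unlist(lapply(seq_len(nrow(pools)), function(i)
    paste0(pools$pool_id[i], "_a", seq_len(pools$n_arrays[i]))))
  array_freq <- matrix(NA_real_, ns, length(arr_ids),
                       dimnames = list(NULL, arr_ids))
  bead_parts <- vector("list", length(arr_ids))
  bps <- config$beads_per_snp
  n_negative_forced <- 0L
  for (a in seq_along(arr_ids)) {
    pa <- clipped(pool_freq[, arr_pool[a]] + stats::rnorm(ns, 0, config$sd_array))
    array_freq[, a] <- pa
    nb <- ns * bps
    f <- clipped(rep(pa, each = bps) + stats::rnorm(nb, 0, config$sd_bead))
    intens <- pmax(stats::rnorm(nb, config$intensity_scale,
                                config$intensity_cv * config$intensity_scale), 1)
    green <- intens * f
    red <- intens * (1 - f) * rep(bias, each = bps)
    n_neg <- as.integer(round(config$frac_negative_beads * nb))
    if (n_neg > 0L) {
      idx <- sample.int(nb, n_neg)
      pick_green <- stats::rbinom(n_neg, 1L, 0.5) == 1L
      green[idx[pick_green]] <- -(abs(green[idx[pick_green]]) + 1)
      red[idx[!pick_green]] <- -(abs(red[idx[!pick_green]]) + 1)
      n_negative_forced <- n_negative_forced + n_neg
    }
    bead_parts[[a]] <- data.frame(
      array_id = arr_ids[a], pool_id = arr_pool[a],
      strip_id = rep(strip_ids, each = bps),
      snp_id = rep(snp_ids, each = bps),
      green = green, red = red, stringsAsFactors = FALSE)
  }
  beads <- do.call(rbind, bead_parts)
  rownames(beads) <- NULL

  clip_fraction <- if (n_draws > 0L) n_clip / n_draws else 0
  truth <- list(
    maf = maf, green_freq = green_freq, founder_freq = founder_freq,
    pool_freq = pool_freq, array_freq = array_freq,
    arrays = data.frame(array_id = arr_ids, pool_id = arr_pool,
                        stringsAsFactors = FALSE),
    injected = list(
      var_construction = config$sd_construction^2,
      var_array = config$sd_array^2,
      var_bead = config$sd_bead^2,
      beads_per_snp = bps,
      # what the Type A estimator targets: array error plus the bead-
      # sampling contribution to a per-array frequency estimate
      var_array_measured = config$sd_array^2 + config$sd_bead^2 / bps),
    n_clipped = n_clip, clip_fraction = clip_fraction,
    heavy_clipping = clip_fraction > 0.01,
    n_negative_forced = n_negative_forced)
  structure(list(beads = beads, truth = truth, pools = pools,
                 config = config),
            class = "pool_sim")
}

#' @export
print.pool_sim <- function(x, ...) {
  cat(sprintf(
    "simulated pooled-array experiment: %d SNPs, %d pools, %d arrays, %d beads\n",
    x$config$n_snps, nrow(x$pools), nrow(x$truth$arrays), nrow(x$beads)))
  if (isTRUE(x$truth$heavy_clipping)) {
    cat(sprintf("  WARNING: %.1f%% of frequency draws clipped to [0,1]\n",
                100 * x$truth$clip_fraction))
  }
  invisible(x)
}

#' Parameter-recovery report for the variance pipeline
#'
#' Runs the full pipeline (simulate beads, filter, optionally normalize,
#' build frequency tables, decompose) over several seeds and compares the
#' recovered variance components with the injected ones. The injected
#' array-level value includes the bead-sampling contribution
#' sd_bead^2 / beads_per_snp, which any array-level estimator necessarily
#' absorbs.
#'
#' @param config A [sim_config()] (its `seed` is overridden per replicate).
#' @param pools Layout data frame as in [simulate_experiment()].
#' @param seeds Integer vector of seeds, one replicate per seed.
#' @param normalize Passed to [allelotype()].
#' @return A data frame with one row per component: `component`,
#'   `injected`, `mean_estimate`, `rel_error`.
#' @export
recovery_report <- function(config, pools, seeds, normalize = TRUE) {
  stopifnot(length(seeds) >= 1)
  acc <- matrix(NA_real_, length(seeds), 4,
                dimnames = list(NULL, c("var_array", "var_pooling",
                                        "var_construction",
                                        "construction_fraction")))
  for (i in seq_along(seeds)) {
    config$seed <- seeds[i]
    sim <- simulate_experiment(config, pools)
    ft <- allelotype(sim$beads, normalize = normalize)
    dec <- decompose_experiment(ft, sim$pools)
    acc[i, ] <- coef(dec)[colnames(acc)]
  }
  inj_arr <- sim$truth$injected$var_array_measured
  inj_con <- sim$truth$injected$var_construction
  injected <- c(var_array = inj_arr,
                var_pooling = inj_arr + inj_con,
                var_construction = inj_con,
                construction_fraction = if (inj_arr + inj_con > 0)
                  inj_con / (inj_arr + inj_con) else 0)
  est <- colMeans(acc)
  data.frame(component = colnames(acc), injected = as.vector(injected),
             mean_estimate = as.vector(est),
             rel_error = as.vector((est - injected) /
                                     ifelse(injected == 0, NA, injected)),
             stringsAsFactors = FALSE)
}
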