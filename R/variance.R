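#' Variance of the allele-frequency difference between two arrays
#'
#' For two frequency tables the paired difference variance is computed over
#' the intersection of their SNP sets as sum((p1_i - p2_i)^2) / (n - 2),
#' with n the intersection size. The n - 2 denominator (rather than n or
#' n - 1) follows the replicate-array estimator convention used for pooled
#' beadarray data; at array scale (n in the hundreds of thousands) the
#' difference is negligible, and for fidelity it is kept exactly.
#'
#' @param ft1,ft2 Frequency tables (data frames with `snp_id`, `freq`).
#' @return A list with `value` (the variance of the difference) and
#'   `n_snps` (SNP intersection size).
#' @seealso [array_variance_pair()], [pooling_variance_nonidentical()]
#' @export
paired_diff_variance <- function(ft1, ft2) {
  common <- intersect(ft1$snp_id, ft2$snp_id)
  n <- length(common)
  if (n <= 2L) {
    stop("insufficient SNP overlap between arrays (n = ", n,
         "); need more than 2 shared SNPs")
  }
  d <- ft1$freq[match(common, ft1$snp_id)] - ft2$freq[match(common, ft2$snp_id)]
  list(value = sum(d^2) / (n - 2), n_snps = n)
}

variance_estimate <- function(kind, value, n_snps, n_pairings,
                              raw_value = value,
                              negative_before_clamp = FALSE) {
  structure(list(kind = kind, value = value, n_snps = n_snps,
                 n_pairings = n_pairings, raw_value = raw_value,
                 negative_before_clamp = negative_before_clamp),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("variance estimate [%s]: %.6g  (%s SNPs, %d pairing%s%s)\n",
              x$kind, x$value, format(round(x$n_snps)), x$n_pairings,
              if (x$n_pairings == 1L) "" else "s",
              if (isTRUE(x$negative_before_clamp))
                sprintf(", clamped from %.3g", x$raw_value) else ""))
  if (!is.null(x$fraction_of_pooling)) {
    cat(sprintf("  fraction of pooling variance: %.1f%%\n",
                100 * x$fraction_of_pooling))
  }
  invisible(x)
}

all_unordered_pairs <- function(k) {
  if (k < 2L) return(matrix(integer(0), nrow = 2))
  utils::combn(k, 2L)
}

#' Array variance from one pair of replicate arrays (Type A)
#'
#' When two arrays allelotype the exact same DNA pool, the only source of
#' variation between them is the array, so the variance of their
#' allele-frequency difference is twice the array variance:
#' var(e_array) = var(p1 - p2) / 2.
#'
#' @param ft1,ft2 Frequency tables of two replicate arrays of one pool.
#' @return A `variance_estimate` of kind `"array"`.
#' @export
array_variance_pair <- function(ft1, ft2) {
  pdv <- paired_diff_variance(ft1, ft2)
  variance_estimate("array", pdv$value / 2, pdv$n_snps, 1L)
}

#' Array variance from all replicate arrays of one pool
#'
#' With k > 2 replicate arrays the best estimate of var(e_array) is the
#' average of all C(k, 2) possible pairings.
#'
#' @param tables List of k >= 2 frequency tables of one pool.
#' @return A `variance_estimate` of kind `"array"` with
#'   `n_pairings = choose(k, 2)`.
#' @export
array_variance_pool <- function(tables) {
  k <- length(tables)
  if (k < 2L) {
    stop("at least 2 replicate arrays are needed to estimate array variance")
  }
  pairs <- all_unordered_pairs(k)
  ests <- apply(pairs, 2L, function(ij)
    unlist(array_variance_pair(tables[[ij[1L]]], tables[[ij[2L]]])[c("value", "n_snps")]))
  variance_estimate("array", mean(ests["value", ]), mean(ests["n_snps", ]),
                    ncol(pairs))
}

#' Pooling variance from replicate pool construction (Type B)
#'
#' When two pools are constructed independently from the same DNA samples,
#' arrays of different pools differ through both array error and
#' pool-construction error: var(e_pooling-1) = var(p_a - p_b) / 2. The
#' estimate is averaged over all cross pairings (one array from each pool).
#'
#' @param tablesA,tablesB Lists of frequency tables for the two replicate
#'   pools.
#' @return A `variance_estimate` of kind `"pooling_replicate"`.
#' @export
pooling_variance_replicate <- function(tablesA, tablesB) {
  if (length(tablesA) < 1L || length(tablesB) < 1L) {
    stop("each pool needs at least one array")
  }
  vals <- numeric(0)
  ns <- numeric(0)
  for (a in tablesA) {
    for (b in tablesB) {
      pdv <- paired_diff_variance(a, b)
      vals <- c(vals, pdv$value / 2)
      ns <- c(ns, pdv$n_snps)
    }
  }
  variance_estimate("pooling_replicate", mean(vals), mean(ns), length(vals))
}

#' Binomial sampling variance of a non-identical pool comparison
#'
#' When the two pools hold different individuals, part of the observed
#' frequency difference is genuine binomial sampling of 2N chromosomes per
#' pool. The per-SNP correction is the variance of the difference of two
#' independent frequency estimates, i.e. the sum
#' p1(1-p1)/(2*Na) + p2(1-p2)/(2*Nb). A `denominator = "N"` switch computes
#' per-individual denominators instead for comparison with software using
#' that convention.
#'
#' @param p1,p2 Observed allele frequencies in the two arrays (vectorised).
#' @param Na,Nb Number of individuals contributing to each pool.
#' @param denominator `"2N"` (diploid chromosomes, default) or `"N"`.
#' @return The per-SNP sampling variance (same length as `p1`).
#' @export
binomial_pair_variance <- function(p1, p2, Na, Nb,
                                   denominator = c("2N", "N")) {
  denominator <- match.arg(denominator)
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
            Na >= 1, Nb >= 1)
  mult <- if (denominator == "2N") 2 else 1
  p1 * (1 - p1) / (mult * Na) + p2 * (1 - p2) / (mult * Nb)
}

#' Pooling variance from non-identical pools (Type C)
#'
#' Arrays of two pools holding different individuals differ through array
#' error, pool-construction error, and binomial sampling of the
#' individuals. Per cross pairing the estimate is
#' sum((p_a,i - p_b,i)^2 - V_i) / (n - 2) / 2, where V_i is the binomial
#' correction of [binomial_pair_variance()] evaluated at that pairing's
#' observed frequencies. The final value averages all cross pairings; it
#' can come out negative by chance and is then reported clamped at zero
#' with the raw value retained.
#'
#' @inheritParams pooling_variance_replicate
#' @param Na,Nb Individuals contributing to pools A and B.
#' @inheritParams binomial_pair_variance
#' @return A `variance_estimate` of kind `"pooling_nonidentical"`.
#' @export
pooling_variance_nonidentical <- function(tablesA, tablesB, Na, Nb,
                                          denominator = c("2N", "N")) {
  denominator <- match.arg(denominator)
  if (missing(Na) || missing(Nb) || is.na(Na) || is.na(Nb)) {
    stop("pool sizes Na and Nb are required for the binomial correction")
  }
  vals <- numeric(0)
  ns <- numeric(0)
  for (a in tablesA) {
    for (b in tablesB) {
      common <- intersect(a$snp_id, b$snp_id)
      n <- length(common)
      if (n <= 2L) stop("insufficient SNP overlap between arrays (n = ", n, ")")
      pa <- a$freq[match(common, a$snp_id)]
      pb <- b$freq[match(common, b$snp_id)]
      v <- binomial_pair_variance(pa, pb, Na, Nb, denominator)
      vals <- c(vals, sum((pa - pb)^2 - v) / (n - 2) / 2)
      ns <- c(ns, n)
    }
  }
  raw <- mean(vals)
  variance_estimate("pooling_nonidentical", max(0, raw), mean(ns),
                    length(vals), raw_value = raw,
                    negative_before_clamp = raw < 0)
}

#' Pool-construction variance by subtraction
#'
#' Pool-construction variance is the pooling variance (Type B or C) minus
#' the array variance (Type A); negative values are set to zero, with the
#' pre-clamp value retained for diagnostics. The fraction of pooling
#' variance attributable to construction is reported alongside.
#'
#' @param pooling A `variance_estimate` of kind `"pooling_replicate"` or
#'   `"pooling_nonidentical"`.
#' @param array A `variance_estimate` of kind `"array"`.
#' @return A `variance_estimate` of kind `"construction"` with an extra
#'   `fraction_of_pooling` component.
#' @export
construction_variance <- function(pooling, array) {
  if (!inherits(pooling, "variance_estimate") ||
      !pooling$kind %in% c("pooling_replicate", "pooling_nonidentical")) {
    stop("'pooling' must be a pooling variance estimate (Type B or C)")
  }
  if (!inherits(array, "variance_estimate") || array$kind != "array") {
    stop("'array' must be an array variance estimate (Type A)")
  }
  raw <- pooling$value - array$value
  est <- variance_estimate("construction", max(0, raw),
                           min(pooling$n_snps, array$n_snps),
                           pooling$n_pairings, raw_value = raw,
                           negative_before_clamp = raw < 0)
  est$fraction_of_pooling <-
    if (pooling$value > 0) est$value / pooling$value else 0
  est
}

replicate_group <- function(pools) {
  # pools sharing a replicate_of link (either direction) form one group
  grp <- as.character(pools$pool_id)
  names(grp) <- grp
  if (!is.null(pools$replicate_of)) {
    ro <- as.character(pools$replicate_of)
    for (i in seq_len(nrow(pools))) {
      if (!is.na(ro[i]) && ro[i] != "") grp[pools$pool_id[i]] <- grp[[ro[i]]]
    }
  }
  grp
}

#' Decompose the pooling variance of a whole experiment
#'
#' Runs the full paired-array variance decomposition over a set of
#' allelotyped pools: array variance from within-pool replicate-array
#' pairings (Type A, averaged over all pairings), pooling variance per pool
#' from replicate-pool pairings where a construction replicate exists
#' (Type B) and otherwise from cross pairings against every other pool with
#' the binomial sampling correction (Type C), and pool-construction
#' variance by subtraction, clamped at zero.
#'
#' Arrays whose mean within-pool pairwise variance exceeds a multiple of
#' the experiment-wide median are flagged as suspect (e.g. a faulty array
#' inflates every pairing it participates in); flagged arrays are reported,
#' never removed automatically.
#'
#' @param freqs Frequency table data frame covering all arrays (columns
#'   `array_id`, `pool_id`, `snp_id`, `freq`), e.g. from [allelotype()].
#' @param pools Pool metadata: data frame with `pool_id`, `n_individuals`
#'   and optionally `batch_id` and `replicate_of` (the pool this one is a
#'   construction replicate of).
#' @param group_by_batch If `TRUE`, comparisons and array-variance means
#'   are restricted within `batch_id` strata.
#' @param outlier_factor Flag arrays whose mean within-pool pairwise
#'   variance exceeds this multiple of the median (default 5).
#' @inheritParams binomial_pair_variance
#' @return An object of class `pool_varcomp`; see [print.pool_varcomp()].
#'   Components: `array` (per-scope mean/range of Type A estimates),
#'   `array_pairs` (every Type A pairing), `pools` (per-pool pooling and
#'   construction estimates with pairing counts), `outliers`, and the
#'   inputs' metadata.
#' @examples
#' cfg <- sim_config(n_snps = 400, n_strips = 1, sd_bead = 0, seed = 42)
#' layout <- data.frame(pool_id = c("case", "ctrl"), n_arrays = c(2, 2))
#' sim <- simulate_experiment(cfg, layout)
#' ft <- allelotype(sim$beads, normalize = FALSE)
#' decompose_experiment(ft, sim$pools)
#' @export
decompose_experiment <- function(freqs, pools, group_by_batch = FALSE,
                                 outlier_factor = 5,
                                 denominator = c("2N", "N")) {
  denominator <- match.arg(denominator)
  pools <- as.data.frame(pools)
  pools$pool_id <- as.character(pools$pool_id)
  if (is.null(pools$batch_id)) pools$batch_id <- "all"
  if (!group_by_batch) pools$batch_id <- "all"
  if (is.null(pools$n_individuals)) pools$n_individuals <- NA_integer_
  grp <- replicate_group(pools)

  # split frequency tables by array, remember array -> pool
  arr_pool <- unique(freqs[, c("array_id", "pool_id")])
  arr_pool$pool_id <- as.character(arr_pool$pool_id)
  unknown <- setdiff(arr_pool$pool_id, pools$pool_id)
  if (length(unknown) > 0L) {
    stop("frequency tables reference pools missing from metadata: ",
         paste(unknown, collapse = ", "))
  }
  tabs <- split(freqs[, c("snp_id", "freq")], freqs$array_id)
  tables_of <- function(pid) {
    ids <- arr_pool$array_id[arr_pool$pool_id == pid]
    tabs[ids]
  }
  k_of <- stats::setNames(tabulate(factor(arr_pool$pool_id,
                                          levels = pools$pool_id),
                                   nbins = nrow(pools)), pools$pool_id)
  if (!any(k_of >= 2L)) {
    stop("cannot estimate array variance: no pool has >= 2 replicate arrays")
  }

  # --- Type A: all within-pool pairings ----------------------------------
  ap_rows <- list()
  for (pid in pools$pool_id[k_of >= 2L]) {
    tt <- tables_of(pid)
    ids <- names(tt)
    pairs <- all_unordered_pairs(length(tt))
    for (j in seq_len(ncol(pairs))) {
      est <- array_variance_pair(tt[[pairs[1L, j]]], tt[[pairs[2L, j]]])
      ap_rows[[length(ap_rows) + 1L]] <- data.frame(
        pool_id = pid,
        batch_id = pools$batch_id[pools$pool_id == pid],
        array_1 = ids[pairs[1L, j]], array_2 = ids[pairs[2L, j]],
        value = est$value, n_snps = est$n_snps, stringsAsFactors = FALSE)
    }
  }
  array_pairs <- do.call(rbind, ap_rows)
  array_scope <- do.call(rbind, lapply(split(array_pairs, array_pairs$batch_id),
    function(d) data.frame(batch_id = d$batch_id[1L], mean = mean(d$value),
                           min = min(d$value), max = max(d$value),
                           n_pairings = nrow(d), stringsAsFactors = FALSE)))
  rownames(array_scope) <- NULL
  array_mean_for <- function(batch) {
    i <- match(batch, array_scope$batch_id)
    if (is.na(i)) stats::weighted.mean(array_scope$mean, array_scope$n_pairings)
    else array_scope$mean[i]
  }

  # --- outlier diagnostic ------------------------------------------------
  arr_means <- tapply(c(array_pairs$value, array_pairs$value),
                      c(array_pairs$array_1, array_pairs$array_2), mean)
  med <- stats::median(arr_means)
  outliers <- data.frame(array_id = names(arr_means),
                         mean_pair_variance = as.vector(arr_means),
                         flagged = as.vector(arr_means) > outlier_factor * med,
                         stringsAsFactors = FALSE)
  rownames(outliers) <- NULL

  # --- per-pool pooling + construction -----------------------------------
  pool_rows <- list()
  for (i in seq_len(nrow(pools))) {
    pid <- pools$pool_id[i]
    batch <- pools$batch_id[i]
    partners_b <- pools$pool_id[grp == grp[[pid]] & pools$pool_id != pid &
                                  pools$batch_id == batch]
    in_scope <- pools$pool_id[pools$batch_id == batch & pools$pool_id != pid &
                                grp != grp[[pid]]]
    a_mean <- array_mean_for(batch)
    if (length(partners_b) > 0L) {
      est <- pooling_variance_replicate(
        tables_of(pid), do.call(c, lapply(partners_b, tables_of)))
      type <- "B"
    } else if (length(in_scope) > 0L && k_of[[pid]] >= 1L) {
      vals <- numeric(0)
      n_pair <- 0L
      ns <- numeric(0)
      raws <- numeric(0)
      for (other in in_scope) {
        e <- pooling_variance_nonidentical(
          tables_of(pid), tables_of(other),
          Na = pools$n_individuals[i],
          Nb = pools$n_individuals[pools$pool_id == other],
          denominator = denominator)
        # accumulate at pairing granularity so the per-pool mean is the
        # unweighted mean over all cross pairings involving this pool
        raws <- c(raws, rep(e$raw_value, e$n_pairings))
        ns <- c(ns, rep(e$n_snps, e$n_pairings))
        n_pair <- n_pair + e$n_pairings
      }
      raw <- mean(raws)
      est <- variance_estimate("pooling_nonidentical", max(0, raw), mean(ns),
                               n_pair, raw_value = raw,
                               negative_before_clamp = raw < 0)
      type <- "C"
    } else {
      est <- NULL
      type <- NA_character_
    }
    if (is.null(est)) {
      pool_rows[[i]] <- data.frame(
        pool_id = pid, batch_id = batch, n_arrays = k_of[[pid]],
        pooling_type = NA_character_, var_pooling = NA_real_,
        pooling_n_pairings = NA_integer_, var_array = a_mean,
        var_construction = NA_real_, construction_fraction = NA_real_,
        construction_clamped = NA, stringsAsFactors = FALSE)
    } else {
      con <- construction_variance(est, variance_estimate(
        "array", a_mean, est$n_snps, array_scope$n_pairings[
          match(batch, array_scope$batch_id)]))
      pool_rows[[i]] <- data.frame(
        pool_id = pid, batch_id = batch, n_arrays = k_of[[pid]],
        pooling_type = type, var_pooling = est$value,
        pooling_n_pairings = est$n_pairings, var_array = a_mean,
        var_construction = con$value,
        construction_fraction = con$fraction_of_pooling,
        construction_clamped = con$negative_before_clamp,
        stringsAsFactors = FALSE)
    }
  }
  pool_report <- do.call(rbind, pool_rows)
  rownames(pool_report) <- NULL

  structure(list(array = array_scope, array_pairs = array_pairs,
                 pools = pool_report, outliers = outliers,
                 n_array_pairings = nrow(array_pairs),
                 group_by_batch = group_by_batch,
                 denominator = denominator, meta = pools),
            class = "pool_varcomp")
}

#' @describeIn decompose_experiment Compact display of the decomposition.
#' @param x,object A `pool_varcomp` object.
#' @param ... Unused.
#' @export
print.pool_varcomp <- function(x, ...) {
  cat("Pooling variance decomposition\n")
  cat(sprintf("  array variance (Type A), %d pairing%s:\n",
              x$n_array_pairings, if (x$n_array_pairings == 1L) "" else "s"))
  for (i in seq_len(nrow(x$array))) {
    cat(sprintf("    %s: mean %.3g  (range %.3g - %.3g, n = %d)\n",
                x$array$batch_id[i], x$array$mean[i], x$array$min[i],
                x$array$max[i], x$array$n_pairings[i]))
  }
  cat("  per-pool pooling / construction variance:\n")
  for (i in seq_len(nrow(x$pools))) {
    p <- x$pools[i, ]
    if (is.na(p$pooling_type)) {
      cat(sprintf("    %s (%d arrays): pooling variance unavailable\n",
                  p$pool_id, p$n_arrays))
    } else {
      cat(sprintf(
        "    %s (%d arrays, Type %s, %d pairings): pooling %.3g, construction %.3g (%.0f%%)%s\n",
        p$pool_id, p$n_arrays, p$pooling_type, p$pooling_n_pairings,
        p$var_pooling, p$var_construction, 100 * p$construction_fraction,
        if (isTRUE(p$construction_clamped)) " [clamped]" else ""))
    }
  }
  if (any(x$outliers$flagged)) {
    cat("  suspect arrays:",
        paste(x$outliers$array_id[x$outliers$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn decompose_experiment Per-pool summary table as a data frame.
#' @export
summary.pool_varcomp <- function(object, ...) {
  object$pools
}

#' @describeIn decompose_experiment Named vector of the headline components:
#'   mean array variance, mean pooling variance, mean construction variance
#'   and mean construction fraction across pools with an estimate.
#' @export
coef.pool_varcomp <- function(object, ...) {
  p <- object$pools[!is.na(object$pools$var_pooling), , drop = FALSE]
  c(var_array = stats::weighted.mean(object$array$mean,
                                     object$array$n_pairings),
    var_pooling = mean(p$var_pooling),
    var_construction = mean(p$var_construction),
    construction_fraction = mean(p$construction_fraction))
}

#' Write a variance decomposition report as TSV
#'
#' @param x A `pool_varcomp` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_varcomp_report <- function(x, path) {
  stopifnot(inherits(x, "pool_varcomp"))
  utils::write.table(x$pools, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
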