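#' Default average minor allele frequencies by Illumina array class
#'
#' Average MAF across SNPs with HapMap CEU (release 27) data: 0.21 for the
#' 1M-Single and 1M-Duo arrays and 0.29 for the 660-Quad array. Used as
#' planner defaults; any value in (0, 0.5] can be supplied instead.
#'
#' @format Named numeric vector.
#' @export
default_array_maf <- c("1M-Single" = 0.21, "1M-Duo" = 0.21, "660-Quad" = 0.29)

#' Binomial sampling variance of a pool's true allele frequency
#'
#' The true frequency of an allele among the N diploid individuals drawn
#' into a pool varies around the population frequency p with variance
#' Vs = p(1 - p) / (2N) (2N sampled chromosomes).
#'
#' @param p Allele frequency in (0, 1).
#' @param N Number of individuals contributing to the pool.
#' @return The sampling variance Vs.
#' @export
sampling_variance <- function(p, N) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly between 0 and 1")
  if (any(N < 1)) stop("N must be >= 1")
  p * (1 - p) / (2 * N)
}

#' Relative sample size of a pool allelotyped with k replicate arrays
#'
#' RSS = Vs / (Vs + var(e_pooling) / k): the fraction of the total variance
#' of a pooled frequency estimate explained by genuine binomial sampling,
#' with k replicate arrays reducing the pooling variance by 1/k.
#'
#' @param Vs Binomial sampling variance, see [sampling_variance()].
#' @param var_pooling Pooling variance (array + construction components).
#' @param k Number of replicate arrays (integer >= 1).
#' @return RSS in (0, 1].
#' @export
relative_sample_size <- function(Vs, var_pooling, k) {
  if (any(k < 1) || any(k != floor(k))) stop("k must be a positive integer")
  if (any(var_pooling < 0)) stop("var_pooling must be >= 0")
  Vs / (Vs + var_pooling / k)
}

#' Effective sample size
#'
#' N* = RSS * N, rounded to the nearest integer: the number of individually
#' genotyped samples giving precision equivalent to the pool.
#'
#' @param rss Relative sample size in (0, 1].
#' @param N Pool size in individuals.
#' @return Integer effective sample size.
#' @export
effective_sample_size <- function(rss, N) {
  if (any(rss <= 0 | rss > 1)) stop("rss must lie in (0, 1]")
  # round half up, independent of the IEEE round-to-even convention
  as.integer(floor(rss * N + 0.5))
}

#' Total pooling variance from its specification
#'
#' Either an explicit construction variance is added to the array variance,
#' or an array:construction ratio is supplied; the ratio is read as shares
#' of the TOTAL pooling variance, so ratio a:c gives
#' var_pooling = var_array * (a + c) / a (e.g. 7:3 means construction is
#' 30% of pooling variance, var_pooling = var_array / 0.7).
#'
#' @param var_array Array variance (frequency^2 units).
#' @param var_construction Explicit construction variance, or `NULL`.
#' @param ratio Array:construction ratio, either a length-2 numeric vector
#'   or a string like `"7:3"`; or `NULL`.
#' @return The total pooling variance.
#' @export
resolve_pooling_variance <- function(var_array, var_construction = NULL,
                                     ratio = NULL) {
  if (var_array < 0) stop("var_array must be >= 0")
  if (is.null(var_construction) == is.null(ratio)) {
    stop("specify exactly one of var_construction or ratio")
  }
  if (!is.null(var_construction)) {
    if (var_construction < 0) stop("var_construction must be >= 0")
    return(var_array + var_construction)
  }
  if (is.character(ratio)) {
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1L]])
  }
  if (length(ratio) != 2L || anyNA(ratio) || any(ratio < 0) || ratio[1L] <= 0) {
    stop("ratio must be two non-negative numbers a:c with a > 0")
  }
  var_array * sum(ratio) / ratio[1L]
}

#' Plan replicate arrays for a DNA pool
#'
#' Builds the planning table of relative and effective sample size over a
#' range of replicate-array counts for one DNA pool, given the pooling
#' variance components, the average minor allele frequency on the array,
#' and the pool size. By convention the 1/k replicate-array reduction is
#' applied to the entire pooling variance (construction component
#' included); `reduce = "array-only"` restricts it to the array component
#' for sensitivity analysis.
#'
#' @param n_individuals Pool size N.
#' @param maf Average minor allele frequency p in (0, 0.5].
#' @inheritParams resolve_pooling_variance
#' @param k_max Largest replicate-array count tabulated (default 24).
#' @param reduce `"pooling"` (default) or `"array-only"`.
#' @param ess_step_threshold Diminishing-returns marker: the smallest k at
#'   which adding one more array increases N* by less than this many
#'   individuals (default 1).
#' @return An object of class `pooling_plan`: the table (`k`, `rss`,
#'   `ess`), the resolved parameters, and `k_diminishing`.
#' @examples
#' plan <- pooling_plan(n_individuals = 300, maf = 0.29,
#'                      var_array = 3.3e-4, ratio = "7:3")
#' plan
#' @export
pooling_plan <- function(n_individuals, maf, var_array,
                         var_construction = NULL, ratio = NULL,
                         k_max = 24L, reduce = c("pooling", "array-only"),
                         ess_step_threshold = 1) {
  reduce <- match.arg(reduce)
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (k_max < 1) stop("k_max must be >= 1")
  var_pooling <- resolve_pooling_variance(var_array, var_construction, ratio)
  vc <- var_pooling - var_array
  Vs <- sampling_variance(maf, n_individuals)
  k <- seq_len(k_max)
  veff <- if (reduce == "pooling") var_pooling / k else var_array / k + vc
  rss <- Vs / (Vs + veff)
  ess <- effective_sample_size(rss, n_individuals)
  tab <- data.frame(k = k, rss = rss, ess = ess)
  step <- diff(ess)
  k_dim <- if (length(step) > 0L && any(step < ess_step_threshold)) {
    k[which(step < ess_step_threshold)[1L] + 1L]
  } else {
    NA_integer_
  }
  structure(list(table = tab, n_individuals = n_individuals, maf = maf,
                 var_array = var_array, var_pooling = var_pooling,
                 Vs = Vs, reduce = reduce, k_diminishing = k_dim),
            class = "pooling_plan")
}

#' @describeIn pooling_plan Print the planning table.
#' @param x A `pooling_plan`.
#' @param ... Unused.
#' @export
print.pooling_plan <- function(x, ...) {
  cat(sprintf(
    "Pooling plan: N = %d, mean MAF = %.2f, var(array) = %.3g, var(pooling) = %.3g\n",
    x$n_individuals, x$maf, x$var_array, x$var_pooling))
  tab <- x$table
  cat(sprintf("  %3s  %5s  %5s\n", "k", "RSS", "N*"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %3d  %5.2f  %5d\n", tab$k[i], tab$rss[i], tab$ess[i]))
  }
  if (!is.na(x$k_diminishing)) {
    cat(sprintf("  diminishing returns beyond k = %d (marginal N* gain < 1)\n",
                x$k_diminishing - 1L))
  }
  invisible(x)
}

#' @describeIn pooling_plan The planning table as a data frame.
#' @param row.names,optional Passed through; unused.
#' @export
as.data.frame.pooling_plan <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  x$table
}

#' @describeIn pooling_plan RSS versus replicate arrays.
#' @param y Unused.
#' @export
plot.pooling_plan <- function(x, y, ...) {
  graphics::plot(x$table$k, x$table$rss, type = "b", pch = 16,
                 xlab = "replicate arrays (k)",
                 ylab = "relative sample size", ylim = c(0, 1), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Minimal replicate arrays achieving a target relative sample size
#'
#' Solves RSS(k) >= target for the smallest integer k, by the closed form
#' k = ceiling(var_pooling * target / (Vs * (1 - target))) cross-checked
#' against a linear scan.
#'
#' @param plan A `pooling_plan` object.
#' @param target_rss Target RSS in (0, 1).
#' @return The minimal integer k.
#' @export
arrays_for_target_rss <- function(plan, target_rss) {
  stopifnot(inherits(plan, "pooling_plan"))
  if (target_rss >= 1) stop("target RSS of 1 is unreachable with finite arrays")
  if (target_rss <= 0) stop("target_rss must lie in (0, 1)")
  if (plan$reduce != "pooling") {
    stop("closed form assumes the 1/k reduction applies to the full pooling variance")
  }
  if (plan$var_pooling == 0) return(1L)
  k <- ceiling(plan$var_pooling * target_rss / (plan$Vs * (1 - target_rss)))
  k <- max(1L, as.integer(k))
  # guard the closed form against floating-point edge cases
  while (relative_sample_size(plan$Vs, plan$var_pooling, k) < target_rss) {
    k <- k + 1L
  }
  while (k > 1L &&
         relative_sample_size(plan$Vs, plan$var_pooling, k - 1L) >= target_rss) {
    k <- k - 1L
  }
  k
}

#' Optimal allocation of arrays between two pools
#'
#' Distributes a fixed total number of arrays between two pools so as to
#' minimise the estimation-variance contribution to the case-control
#' frequency difference, var_poolingA / kA + var_poolingB / kB. All splits
#' are scanned; ties are broken toward the more balanced split. With equal
#' pooling variances the optimum is the (near-)equal split, regardless of
#' pool sizes.
#'
#' @param total_arrays Total number of arrays T >= 2.
#' @param var_pooling_a,var_pooling_b Pooling variance of each pool.
#' @return Integer vector `c(kA, kB)` summing to `total_arrays`.
#' @export
optimal_allocation <- function(total_arrays, var_pooling_a, var_pooling_b) {
  if (total_arrays < 2) stop("total_arrays must be >= 2")
  ka <- seq_len(total_arrays - 1L)
  obj <- var_pooling_a / ka + var_pooling_b / (total_arrays - ka)
  best <- which(obj <= min(obj) + 1e-15)
  if (length(best) > 1L) {
    imb <- abs(2L * ka[best] - total_arrays)
    best <- best[order(imb, ka[best])][1L]
  }
  c(kA = ka[best], kB = total_arrays - ka[best])
}

#' Cost of a pooling experiment relative to individual genotyping
#'
#' @param n_pools Number of pools.
#' @param arrays_per_pool Replicate arrays per pool.
#' @param array_price Price of one array.
#' @param n_individuals Individuals that would be genotyped individually.
#' @return A list with `pooling_cost`, `individual_cost` and `percent`
#'   (pooling cost as a percentage of individual genotyping cost).
#' @examples
#' cost_summary(2, 12, 250, 4000)  # $6000, 0.6% of $1,000,000
#' @export
cost_summary <- function(n_pools, arrays_per_pool, array_price,
                         n_individuals) {
  stopifnot(n_pools > 0, arrays_per_pool > 0, array_price > 0,
            n_individuals > 0)
  pooling <- n_pools * arrays_per_pool * array_price
  individual <- n_individuals * array_price
  list(pooling_cost = pooling, individual_cost = individual,
       percent = 100 * pooling / individual)
}
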