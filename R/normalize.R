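#' Mean allele frequency of a strip at a given red-channel scale
#'
#' Beadarrays are manufactured in strips, and the relative intensity of the
#' red and green channels can differ substantially between strips and
#' arrays. Normalization rescales the red channel so that each strip's mean
#' allele-frequency estimate is 0.5. This helper evaluates that mean at a
#' candidate scale.
#'
#' By default the mean is taken over per-SNP frequency estimates (each SNP
#' with at least four beads contributes once, consistent with the SNP
#' exclusion rule applied downstream); `level = "bead"` averages raw
#' per-bead ratios instead, which weights SNPs by bead count.
#'
#' @param strip_beads Filtered bead observations of one strip.
#' @param red_scale Positive red-channel factor.
#' @param level `"snp"` (default) or `"bead"`.
#' @return The mean frequency, a number in \[0, 1\].
#' @export
strip_mean_frequency <- function(strip_beads, red_scale = 1,
                                 level = c("snp", "bead")) {
  level <- match.arg(level)
  if (!is.numeric(red_scale) || length(red_scale) != 1L || red_scale <= 0) {
    stop("red_scale must be a single positive number")
  }
  if (level == "bead") {
    return(mean(strip_beads$green /
                  (strip_beads$green + red_scale * strip_beads$red)))
  }
  tab <- per_snp_frequencies(strip_beads$snp_id, strip_beads$green,
                             strip_beads$red, red_scale)
  tab <- tab[tab$n_beads >= 4L, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("degenerate strip: no SNP with >= 4 bead observations")
  }
  mean(tab$freq)
}

#' Solve the red-channel scale that balances a strip
#'
#' Finds the multiplicative red-channel factor c such that the strip's mean
#' allele-frequency estimate equals 0.5. Because every per-bead ratio
#' G/(G + cR) is non-increasing in c (strictly decreasing wherever both
#' channels are positive), the mean is monotone in c and the root is
#' unique; it is located by bisection on log(c) over c in \[1e-6, 1e6\].
#'
#' @inheritParams strip_mean_frequency
#' @param tol Convergence tolerance on |mean - 0.5| (default 1e-9).
#' @param max_iter Bisection iteration cap (default 200).
#' @return A list of class `strip_scale`: `red_scale`, `achieved_mean`,
#'   `iterations`.
#' @examples
#' b <- data.frame(snp_id = rep("s1", 4), green = rep(100, 4), red = rep(200, 4))
#' solve_red_scale(b)$red_scale  # red is twice green, so c = 0.5
#' @export
solve_red_scale <- function(strip_beads, level = c("snp", "bead"),
                            tol = 1e-9, max_iter = 200L) {
  level <- match.arg(level)
  # precompute the grouping once; the bisection only re-evaluates ratios
  f <- factor(strip_beads$snp_id)
  n <- as.vector(rowsum(rep(1, nrow(strip_beads)), f))
  if (level == "snp" && !any(n >= 4L)) {
    stop("degenerate strip: no SNP with >= 4 bead observations")
  }
  g <- strip_beads$green
  r <- strip_beads$red
  mean_at <- function(c) {
    ratio <- g / (g + c * r)
    if (level == "bead") return(mean(ratio))
    freq <- as.vector(rowsum(ratio, f)) / n
    mean(freq[n >= 4L])
  }
  lo <- 1e-6
  hi <- 1e6
  m_lo <- mean_at(lo)
  m_hi <- mean_at(hi)
  # mean is decreasing in c: need mean(lo) >= 0.5 >= mean(hi)
  if (m_lo < 0.5 - tol || m_hi > 0.5 + tol) {
    stop("non-normalizable strip: mean frequency cannot reach 0.5 ",
         "(range [", signif(m_hi, 6), ", ", signif(m_lo, 6),
         "] over red_scale in [1e-6, 1e6])")
  }
  iter <- 0L
  c_mid <- 1
  m_mid <- mean_at(c_mid)
  while (abs(m_mid - 0.5) > tol && iter < max_iter) {
    iter <- iter + 1L
    c_mid <- sqrt(lo * hi)
    m_mid <- mean_at(c_mid)
    if (m_mid > 0.5) lo <- c_mid else hi <- c_mid
  }
  structure(list(red_scale = c_mid, achieved_mean = m_mid, iterations = iter),
            class = "strip_scale")
}

#' @export
print.strip_scale <- function(x, ...) {
  cat(sprintf("strip scale: red_scale = %.6g (mean %.9f, %d iterations)\n",
              x$red_scale, x$achieved_mean, x$iterations))
  invisible(x)
}

#' Normalize one array strip by strip
#'
#' Solves [solve_red_scale()] for every strip of an array, so that
#' frequency tables built with the returned scales have per-strip mean
#' allele frequency 0.5.
#'
#' @param array_beads Filtered bead observations of a single array.
#' @inheritParams solve_red_scale
#' @return A data frame with one row per strip: `array_id`, `strip_id`,
#'   `red_scale`, `achieved_mean`, `iterations`.
#' @export
normalize_array <- function(array_beads, level = c("snp", "bead"),
                            tol = 1e-9, max_iter = 200L) {
  level <- match.arg(level)
  aid <- unique(array_beads$array_id)
  if (length(aid) != 1L) {
    stop("normalize_array() expects beads of a single array")
  }
  strips <- unique(as.character(array_beads$strip_id))
  rows <- lapply(strips, function(s) {
    b <- array_beads[array_beads$strip_id == s, , drop = FALSE]
    sc <- tryCatch(solve_red_scale(b, level = level, tol = tol,
                                   max_iter = max_iter),
                   error = function(e) {
                     stop("array ", aid, ", strip ", s, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
    data.frame(array_id = aid, strip_id = s, red_scale = sc$red_scale,
               achieved_mean = sc$achieved_mean, iterations = sc$iterations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
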