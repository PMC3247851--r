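#' Read a bead-level intensity table
#'
#' Reads a tab-separated bead-level table as exported for pooled-array
#' allelotyping. The dialect has one header row and the six columns
#' `array_id`, `pool_id`, `strip_id`, `snp_id`, `green`, `red`; the two
#' intensity columns are decimal floats and may be negative (local
#' background subtraction during image processing can push raw bead
#' intensities below zero).
#'
#' No filtering is applied: the returned data frame has one row per bead
#' observation in file order. Use [filter_beads()] before estimating
#' allele frequencies.
#'
#' @param path Path to a bead TSV file.
#' @return A data frame with columns `array_id`, `pool_id`, `strip_id`,
#'   `snp_id` (character) and `green`, `red` (numeric).
#' @seealso [write_bead_table()], [filter_beads()], [allelotype()]
#' @export
read_bead_table <- function(path) {
  if (!file.exists(path)) {
    stop("bead table not found: ", path)
  }
  cols <- c("array_id", "pool_id", "strip_id", "snp_id", "green", "red")
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != length(cols))
  if (length(bad) > 0L) {
    stop("malformed bead table '", path, "': line ", bad[1L], " has ",
         nf[bad[1L]], " fields, expected ", length(cols))
  }
  raw <- utils::read.delim(path, colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE)
  if (!identical(names(raw), cols)) {
    stop("malformed bead table '", path, "': header must be ",
         paste(cols, collapse = "\t"))
  }
  for (ch in c("green", "red")) {
    val <- suppressWarnings(as.numeric(raw[[ch]]))
    bad <- which(is.na(val) & !is.na(raw[[ch]]))
    if (length(bad) > 0L) {
      # +1: line numbers in the file are offset by the header row
      stop("malformed bead table '", path, "': non-numeric ", ch,
           " intensity '", raw[[ch]][bad[1L]], "' at line ", bad[1L] + 1L)
    }
    raw[[ch]] <- val
  }
  rownames(raw) <- NULL
  raw
}

#' Write a bead-level intensity table
#'
#' @param beads A bead data frame as returned by [read_bead_table()] or
#'   [simulate_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bead_table <- function(beads, path) {
  stopifnot(all(c("array_id", "pool_id", "strip_id", "snp_id",
                  "green", "red") %in% names(beads)))
  utils::write.table(
    beads[, c("array_id", "pool_id", "strip_id", "snp_id", "green", "red")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter bead observations
#'
#' Applies the standard bead-level quality rules for pooled beadarray data:
#' beads with a negative intensity in the red channel, the green channel, or
#' both are removed, and beads with zero intensity in both channels are
#' considered failed and also removed. The negative rule is applied first,
#' so a bead with one negative channel and the other at zero counts as
#' negative, not failed.
#'
#' @param beads A bead data frame (columns `green`, `red` at minimum).
#' @return A list with components `kept` (the surviving rows, original
#'   order preserved) and `report` (a `filter_report`: counts of dropped
#'   negative and failed beads; the SNP-level fields are `NA` at this stage
#'   and are filled in by [build_frequency_table()]).
#' @export
filter_beads <- function(beads) {
  neg <- beads$green < 0 | beads$red < 0
  failed <- !neg & beads$green == 0 & beads$red == 0
  kept <- beads[!neg & !failed, , drop = FALSE]
  rownames(kept) <- NULL
  report <- filter_report(n_dropped_negative = sum(neg),
                          n_dropped_failed = sum(failed))
  list(kept = kept, report = report)
}

filter_report <- function(n_dropped_negative = 0L, n_dropped_failed = 0L,
                          n_snps_excluded_low_beads = NA_integer_,
                          n_snps_kept = NA_integer_) {
  structure(list(n_dropped_negative = as.integer(n_dropped_negative),
                 n_dropped_failed = as.integer(n_dropped_failed),
                 n_snps_excluded_low_beads = as.integer(n_snps_excluded_low_beads),
                 n_snps_kept = as.integer(n_snps_kept)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Bead/SNP filter report\n")
  cat("  beads dropped (negative intensity):", x$n_dropped_negative, "\n")
  cat("  beads dropped (failed, both zero): ", x$n_dropped_failed, "\n")
  if (!is.na(x$n_snps_kept)) {
    cat("  SNPs excluded (<4 beads):          ", x$n_snps_excluded_low_beads, "\n")
    cat("  SNPs kept:                         ", x$n_snps_kept, "\n")
  }
  invisible(x)
}

#' Estimate the allele frequency of one SNP from its beads
#'
#' The pooled allele-frequency estimate for a SNP is the unweighted mean,
#' over the n beads assaying it, of the per-bead intensity ratio
#' G/(G + s*R), where G and R are the green and red channel intensities and
#' s is an optional red-channel scale factor (from strip normalization,
#' see [solve_red_scale()]). SNPs assayed by fewer than four beads give a
#' poorly estimated frequency and are excluded, signalled by `NA`.
#'
#' @param beads Filtered bead observations of a single SNP.
#' @param red_scale Positive multiplicative factor applied to the red
#'   channel; default 1 (raw data).
#' @return The estimated frequency in \[0, 1\], or `NA_real_` when fewer
#'   than four beads remain (excluded marker).
#' @examples
#' b <- data.frame(green = c(100, 300, 200, 150), red = c(300, 100, 200, 50))
#' snp_allele_frequency(b)  # mean of 0.25, 0.75, 0.5, 0.75 = 0.5625
#' @export
snp_allele_frequency <- function(beads, red_scale = 1) {
  if (!is.numeric(red_scale) || length(red_scale) != 1L || red_scale <= 0) {
    stop("red_scale must be a single positive number")
  }
  if (nrow(beads) < 4L) {
    return(NA_real_)
  }
  mean(beads$green / (beads$green + red_scale * beads$red))
}

# Vectorised per-SNP frequency workhorse shared by the table builder and
# strip normalization: returns mean bead ratio and bead count per SNP.
per_snp_frequencies <- function(snp, green, red, red_scale = 1) {
  f <- factor(snp)
  ratio <- green / (green + red_scale * red)
  n <- as.vector(rowsum(rep(1, length(ratio)), f))
  freq <- as.vector(rowsum(ratio, f)) / n
  data.frame(snp_id = levels(f), freq = freq, n_beads = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Build a per-SNP frequency table for one array
#'
#' Computes the allele-frequency estimate of every SNP on one array
#' ([snp_allele_frequency()] applied per SNP), applying per-strip
#' red-channel scale factors. SNPs with fewer than four beads are excluded
#' from the table (rather than carried as missing values), so that
#' downstream paired-array comparisons operate on the intersection of SNP
#' sets.
#'
#' @param array_beads Filtered bead observations of a single array.
#' @param scales Either `NULL` (all scales 1, raw mode), or a data frame
#'   with columns `strip_id` and `red_scale` as returned by
#'   [normalize_array()]. Every strip present in the beads must be covered.
#' @return A data frame with columns `array_id`, `pool_id`, `snp_id`,
#'   `freq`, `n_beads`, carrying a `filter_report` in
#'   `attr(, "filter_report")`.
#' @export
build_frequency_table <- function(array_beads, scales = NULL) {
  if (nrow(array_beads) == 0L) {
    stop("no bead observations supplied")
  }
  aid <- unique(array_beads$array_id)
  if (length(aid) != 1L) {
    stop("build_frequency_table() expects beads of a single array, got: ",
         paste(aid, collapse = ", "))
  }
  strips <- unique(as.character(array_beads$strip_id))
  if (is.null(scales)) {
    scale_map <- stats::setNames(rep(1, length(strips)), strips)
  } else {
    scale_map <- stats::setNames(scales$red_scale, as.character(scales$strip_id))
    missing <- setdiff(strips, names(scale_map))
    if (length(missing) > 0L) {
      stop("no red_scale provided for strip(s): ", paste(missing, collapse = ", "))
    }
  }
  parts <- lapply(strips, function(s) {
    b <- array_beads[array_beads$strip_id == s, , drop = FALSE]
    per_snp_frequencies(b$snp_id, b$green, b$red, scale_map[[s]])
  })
  tab <- do.call(rbind, parts)
  low <- tab$n_beads < 4L
  out <- tab[!low, , drop = FALSE]
  out <- data.frame(array_id = aid,
                    pool_id = as.character(array_beads$pool_id[1L]),
                    snp_id = out$snp_id, freq = out$freq,
                    n_beads = out$n_beads, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "filter_report") <- filter_report(
    n_snps_excluded_low_beads = sum(low), n_snps_kept = sum(!low))
  out
}

#' Allelotype a bead-level experiment
#'
#' End-to-end pipeline from raw bead observations to per-array SNP
#' allele-frequency tables: bead filtering ([filter_beads()]), optional
#' strip-by-strip normalization of the red channel ([normalize_array()]),
#' and per-SNP frequency estimation with the `<4 beads` exclusion
#' ([build_frequency_table()]).
#'
#' @param beads A bead data frame covering one or more arrays.
#' @param normalize Logical; solve per-strip red-channel scales so each
#'   strip's mean SNP allele frequency is 0.5 (default), or use raw
#'   intensities (all scales 1).
#' @param level Passed to [solve_red_scale()]: average per-SNP frequencies
#'   (`"snp"`, default) or per-bead ratios (`"bead"`) when targeting the
#'   strip mean.
#' @return A data frame with one row per kept SNP per array (columns
#'   `array_id`, `pool_id`, `snp_id`, `freq`, `n_beads`), with attributes
#'   `filter_report` (aggregate counts) and `scales` (per-array, per-strip
#'   `StripScale` rows when `normalize = TRUE`).
#' @examples
#' cfg <- sim_config(n_snps = 50, n_strips = 1, sd_bead = 0, seed = 1)
#' sim <- simulate_experiment(cfg, data.frame(pool_id = "p1", n_arrays = 2))
#' ft <- allelotype(sim$beads)
#' head(ft)
#' @export
allelotype <- function(beads, normalize = TRUE, level = c("snp", "bead")) {
  level <- match.arg(level)
  fl <- filter_beads(beads)
  kept <- fl$kept
  if (nrow(kept) == 0L) stop("no beads survive filtering")
  arrays <- unique(kept$array_id)
  tabs <- vector("list", length(arrays))
  scl <- vector("list", length(arrays))
  n_low <- 0L
  n_kept <- 0L
  for (i in seq_along(arrays)) {
    ab <- kept[kept$array_id == arrays[i], , drop = FALSE]
    scales <- if (normalize) normalize_array(ab, level = level) else NULL
    tabs[[i]] <- build_frequency_table(ab, scales)
    scl[[i]] <- scales
    rep_i <- attr(tabs[[i]], "filter_report")
    n_low <- n_low + rep_i$n_snps_excluded_low_beads
    n_kept <- n_kept + rep_i$n_snps_kept
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "filter_report") <- filter_report(
    n_dropped_negative = fl$report$n_dropped_negative,
    n_dropped_failed = fl$report$n_dropped_failed,
    n_snps_excluded_low_beads = n_low, n_snps_kept = n_kept)
  if (normalize) attr(out, "scales") <- do.call(rbind, scl)
  out
}

#' Read / write per-SNP frequency tables
#'
#' Frequency tables are exchanged as TSV with columns
#' `array_id`, `snp_id`, `freq`, `n_beads` (plus `pool_id` when present).
#'
#' @param path File path.
#' @return `read_frequency_table()` returns the table as a data frame.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.delim(path, quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  need <- c("array_id", "snp_id", "freq", "n_beads")
  if (!all(need %in% names(tab))) {
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' @param freqs Frequency table data frame.
#' @rdname read_frequency_table
#' @export
write_frequency_table <- function(freqs, path) {
  utils::write.table(freqs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
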