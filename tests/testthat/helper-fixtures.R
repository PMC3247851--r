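# In-code fixtures shared across the suite.

# quick bead table: one row per (green, red) pair, all on one SNP/strip/array
make_beads <- function(green, red, snp_id = "snp1", strip_id = "strip1",
                       array_id = "a1", pool_id = "p1") {
  data.frame(array_id = array_id, pool_id = pool_id, strip_id = strip_id,
             snp_id = snp_id, green = green, red = red,
             stringsAsFactors = FALSE)
}

# beads realising given per-SNP green-allele fractions exactly
# (n beads per SNP, total intensity `intensity`, red inflated by `bias`)
beads_with_freqs <- function(freqs, n_beads = 4L, bias = 1,
                             intensity = 1000, ...) {
  do.call(rbind, lapply(seq_along(freqs), function(i) {
    f <- freqs[i]
    make_beads(green = rep(intensity * f, n_beads),
               red = rep(intensity * (1 - f) * bias, n_beads),
               snp_id = sprintf("snp%03d", i), ...)
  }))
}

# random frequency table over a shared SNP panel
rand_ft <- function(n_snps, array_id = "a1", snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%03d", seq_len(n_snps))
  data.frame(array_id = array_id, snp_id = snp_ids,
             freq = stats::runif(length(snp_ids)),
             n_beads = 17L, stringsAsFactors = FALSE)
}

# frequency tables for an arbitrary pool layout (for combinatorics checks):
# `arrays_per_pool` is a named integer vector pool_id -> k
layout_freqs <- function(arrays_per_pool, n_snps = 5L, seed = 1L) {
  set.seed(seed)
  snp_ids <- sprintf("snp%03d", seq_len(n_snps))
  rows <- list()
  for (pid in names(arrays_per_pool)) {
    for (j in seq_len(arrays_per_pool[[pid]])) {
      aid <- paste0(pid, "_a", j)
      ft <- rand_ft(n_snps, array_id = aid, snp_ids = snp_ids)
      ft$pool_id <- pid
      rows[[length(rows) + 1L]] <- ft
    }
  }
  do.call(rbind, rows)
}

layout_pools <- function(arrays_per_pool, n_individuals = 100L) {
  data.frame(pool_id = names(arrays_per_pool),
             n_individuals = n_individuals, stringsAsFactors = FALSE)
}
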