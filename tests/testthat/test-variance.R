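# first-principles recomputations used as oracles: explicit loops over
# SNPs and pairings, independent of the package's vectorised paths
oracle_pdv <- function(ft1, ft2) {
  common <- intersect(ft1$snp_id, ft2$snp_id)
  s <- 0
  for (id in common) {
    s <- s + (ft1$freq[ft1$snp_id == id] - ft2$freq[ft2$snp_id == id])^2
  }
  s / (length(common) - 2)
}

oracle_array_pool <- function(tables) {
  k <- length(tables)
  vals <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      vals <- c(vals, oracle_pdv(tables[[i]], tables[[j]]) / 2)
    }
  }
  mean(vals)
}

oracle_pooling_c <- function(tablesA, tablesB, Na, Nb) {
  vals <- c()
  for (a in tablesA) {
    for (b in tablesB) {
      common <- intersect(a$snp_id, b$snp_id)
      s <- 0
      for (id in common) {
        p1 <- a$freq[a$snp_id == id]
        p2 <- b$freq[b$snp_id == id]
        v <- p1 * (1 - p1) / (2 * Na) + p2 * (1 - p2) / (2 * Nb)
        s <- s + (p1 - p2)^2 - v
      }
      vals <- c(vals, s / (length(common) - 2) / 2)
    }
  }
  mean(vals)
}

test_that("paired difference variance uses the n-2 denominator on the SNP intersection", {
  set.seed(1)
  ft <- rand_ft(6)
  expect_equal(paired_diff_variance(ft, ft)$value, 0)

  # 4 shared SNPs, all differences 0.01: sum d^2 / (n-2) = 4e-4 / 2
  f1 <- rand_ft(4)
  f2 <- f1
  f2$freq <- f1$freq + 0.01
  res <- paired_diff_variance(f1, f2)
  expect_equal(res$value, 2e-4)
  expect_equal(res$n_snps, 4L)

  # intersection, not union: disjoint extras are ignored
  f3 <- rbind(f1, rand_ft(3, snp_ids = c("x1", "x2", "x3")))
  expect_equal(paired_diff_variance(f3, f2)$value, 2e-4)

  expect_error(paired_diff_variance(rand_ft(2), rand_ft(2)), "overlap")
})

test_that("paired difference variance is unbiased up to the n/(n-2) factor", {
  set.seed(2)
  n <- 100
  sigma <- 0.02
  est <- replicate(400, {
    f1 <- rand_ft(n)
    f2 <- f1
    f2$freq <- f1$freq + stats::rnorm(n, 0, sigma)
    paired_diff_variance(f1, f2)$value
  })
  expect_equal(mean(est), sigma^2 * n / (n - 2), tolerance = 0.05)
})

test_that("Type A array variance is half the paired difference variance, averaged over pairings", {
  set.seed(3)
  f1 <- rand_ft(4)
  f2 <- f1
  f2$freq <- f1$freq + 0.01
  expect_equal(array_variance_pair(f1, f2)$value, 1e-4)
  expect_equal(array_variance_pair(f1, f1)$value, 0)

  tables <- lapply(1:4, function(i) {
    f <- rand_ft(8)
    f$freq <- stats::runif(8)
    f
  })
  est <- array_variance_pool(tables)
  expect_equal(est$n_pairings, choose(4, 2))
  expect_equal(est$value, oracle_array_pool(tables), tolerance = 1e-12)
  expect_error(array_variance_pool(tables[1]), "replicate")
})

test_that("pairwise estimators are symmetric in their arguments", {
  set.seed(5)
  f1 <- rand_ft(10)
  f2 <- rand_ft(10)
  expect_equal(array_variance_pair(f1, f2)$value,
               array_variance_pair(f2, f1)$value)
  expect_equal(pooling_variance_replicate(list(f1), list(f2))$value,
               pooling_variance_replicate(list(f2), list(f1))$value)
  expect_equal(pooling_variance_nonidentical(list(f1), list(f2), 50, 80)$value,
               pooling_variance_nonidentical(list(f2), list(f1), 80, 50)$value)
})

test_that("Type B pooling variance averages all cross pairings", {
  set.seed(6)
  tablesA <- list(rand_ft(8), rand_ft(8))
  # identical replicate pool: zero pooling variance
  expect_equal(pooling_variance_replicate(tablesA, tablesA[1])$value,
               mean(c(0, oracle_pdv(tablesA[[2]], tablesA[[1]]) / 2)))
  est <- pooling_variance_replicate(tablesA, list(rand_ft(8), rand_ft(8)))
  expect_equal(est$n_pairings, 4L)
})

test_that("binomial sampling correction uses summed 2N-denominator variances", {
  expect_equal(binomial_pair_variance(0.5, 0.5, 100, 100), 2.5e-3)
  expect_equal(binomial_pair_variance(0, 0, 10, 10), 0)
  expect_lt(binomial_pair_variance(0.5, 0.5, 1e12, 1e12), 1e-12)
  # per-individual convention available as a switch
  expect_equal(binomial_pair_variance(0.5, 0.5, 100, 100, denominator = "N"),
               5e-3)
})

test_that("Type C pooling variance subtracts the binomial correction and clamps", {
  set.seed(7)
  f1 <- rand_ft(10)
  # identical tables with huge pools: estimate ~ 0 after clamping
  est0 <- pooling_variance_nonidentical(list(f1), list(f1), 1e9, 1e9)
  expect_equal(est0$value, 0, tolerance = 1e-10)

  # identical tables with small pools: negative before clamping, flagged
  est_neg <- pooling_variance_nonidentical(list(f1), list(f1), 50, 50)
  expect_equal(est_neg$value, 0)
  expect_true(est_neg$negative_before_clamp)
  expect_lt(est_neg$raw_value, 0)

  # matches the brute-force oracle
  tablesA <- list(rand_ft(9), rand_ft(9))
  tablesB <- list(rand_ft(9), rand_ft(9), rand_ft(9))
  est <- pooling_variance_nonidentical(tablesA, tablesB, 74, 446)
  expect_equal(est$n_pairings, 6L)
  expect_equal(max(0, oracle_pooling_c(tablesA, tablesB, 74, 446)),
               est$value, tolerance = 1e-12)

  expect_error(pooling_variance_nonidentical(tablesA, tablesB, NA, 10),
               "pool sizes")
})

test_that("construction variance subtracts array from pooling and clamps at zero", {
  mk <- function(kind, value) {
    est <- array_variance_pair(rand_ft(5), rand_ft(5))
    est$kind <- kind
    est$value <- value
    est
  }
  con <- construction_variance(mk("pooling_replicate", 4.0e-4),
                               mk("array", 3.3e-4))
  expect_equal(con$value, 0.7e-4)
  expect_equal(con$fraction_of_pooling, 0.175)
  expect_false(con$negative_before_clamp)

  con2 <- construction_variance(mk("pooling_nonidentical", 2e-4),
                                mk("array", 3e-4))
  expect_equal(con2$value, 0)
  expect_true(con2$negative_before_clamp)
  expect_equal(con2$raw_value, -1e-4)

  expect_error(construction_variance(mk("array", 1), mk("array", 1)),
               "pooling")
  expect_error(construction_variance(mk("pooling_replicate", 1),
                                     mk("construction", 1)), "array")
})

test_that("decompose_experiment reports per-pool components and pairing counts", {
  set.seed(8)
  # 12 pools x 2 arrays: 12 Type A estimates with mean and range
  freqs <- layout_freqs(stats::setNames(rep(2L, 12), paste0("pool", 1:12)),
                        n_snps = 6)
  dec <- decompose_experiment(freqs, layout_pools(
    stats::setNames(rep(2L, 12), paste0("pool", 1:12))))
  expect_equal(dec$n_array_pairings, 12L)
  expect_gte(dec$array$mean, dec$array$min)
  expect_lte(dec$array$mean, dec$array$max)

  # single pool with 2 arrays: array variance only, pooling unavailable
  freqs1 <- layout_freqs(c(solo = 2L), n_snps = 6)
  dec1 <- decompose_experiment(freqs1, layout_pools(c(solo = 2L)))
  expect_equal(dec1$n_array_pairings, 1L)
  expect_true(is.na(dec1$pools$pooling_type))
  expect_true(is.na(dec1$pools$var_pooling))

  # no pool with replicate arrays: explicit error
  freqs_single <- layout_freqs(c(a = 1L, b = 1L), n_snps = 6)
  expect_error(decompose_experiment(freqs_single,
                                    layout_pools(c(a = 1L, b = 1L))),
               "replicate arrays")
})

test_that("replicate pools are compared with Type B and excluded from Type C", {
  set.seed(9)
  layout <- c(p1 = 2L, p1rep = 2L, p2 = 2L)
  freqs <- layout_freqs(layout, n_snps = 8)
  pools <- layout_pools(layout)
  pools$replicate_of <- c(NA, "p1", NA)
  dec <- decompose_experiment(freqs, pools)
  expect_equal(dec$pools$pooling_type, c("B", "B", "C"))
  # p2's Type C runs against all 4 arrays of the other pools: 2 x 4 pairings
  expect_equal(dec$pools$pooling_n_pairings[3], 8L)
  # Type B for p1: its 2 arrays against p1rep's 2 arrays
  expect_equal(dec$pools$pooling_n_pairings[1], 4L)
})

test_that("an aberrant array is flagged by the outlier diagnostic", {
  set.seed(10)
  # four pools of three replicate arrays at per-array error SD 0.01; one
  # faulty array at 13x the variance inflates every pairing it joins, while
  # the experiment-wide median stays at the clean level
  n <- 200
  pools <- paste0("p", 1:4)
  snp_ids <- sprintf("snp%03d", seq_len(n))
  rows <- list()
  for (pid in pools) {
    base <- stats::runif(n)
    for (j in 1:3) {
      noise_sd <- if (pid == "p1" && j == 1) 0.036 else 0.01
      rows[[length(rows) + 1L]] <- data.frame(
        array_id = paste0(pid, "_a", j), pool_id = pid, snp_id = snp_ids,
        freq = pmin(pmax(base + stats::rnorm(n, 0, noise_sd), 0), 1),
        n_beads = 17L, stringsAsFactors = FALSE)
    }
  }
  freqs <- do.call(rbind, rows)
  dec <- decompose_experiment(freqs,
                              layout_pools(stats::setNames(rep(3L, 4), pools)))
  expect_true(dec$outliers$flagged[dec$outliers$array_id == "p1_a1"])
  expect_false(any(dec$outliers$flagged[dec$outliers$array_id != "p1_a1"]))
})
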