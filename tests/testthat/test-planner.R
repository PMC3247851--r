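test_that("binomial sampling variance follows p(1-p)/2N", {
  expect_equal(sampling_variance(0.29, 300), 0.29 * 0.71 / 600)
  expect_equal(sampling_variance(0.5, 1), 0.125)
  expect_lt(sampling_variance(0.3, 1e12), 1e-12)
  expect_error(sampling_variance(0, 100), "strictly between")
  expect_error(sampling_variance(1, 100), "strictly between")
})

test_that("relative and effective sample size follow the 1/k reduction", {
  Vs <- sampling_variance(0.29, 300)
  vp <- 3.3e-4 / 0.7
  expect_equal(relative_sample_size(Vs, 0, 5), 1)
  expect_equal(round(relative_sample_size(Vs, vp, 6), 2), 0.81)
  expect_equal(round(relative_sample_size(Vs, vp, 24), 2), 0.95)
  expect_error(relative_sample_size(Vs, vp, 0), "positive integer")

  # nearest-integer rounding: 283.76 -> 284 (floor would give 283)
  expect_equal(effective_sample_size(relative_sample_size(Vs, vp, 24), 300),
               284L)
  expect_equal(effective_sample_size(0.5, 301), 151L)  # half rounds up
  expect_error(effective_sample_size(0, 300), "\\(0, 1\\]")
})

test_that("pooling variance resolves from explicit or ratio specification", {
  expect_equal(resolve_pooling_variance(3.3e-4, ratio = "7:3"),
               3.3e-4 / 0.7)
  expect_equal(resolve_pooling_variance(3.3e-4, ratio = c(7, 3)),
               4.714286e-4, tolerance = 1e-6)
  expect_equal(resolve_pooling_variance(3.3e-4, var_construction = 0), 3.3e-4)
  expect_equal(resolve_pooling_variance(2e-4, ratio = "1:1"), 4e-4)
  expect_error(resolve_pooling_variance(3.3e-4), "exactly one")
  expect_error(resolve_pooling_variance(3.3e-4, var_construction = 1,
                                        ratio = "7:3"), "exactly one")
  expect_error(resolve_pooling_variance(3.3e-4, ratio = "0:3"), "a > 0")
})

test_that("planning tables are ordered, strictly increasing in RSS and bounded by N", {
  plan <- pooling_plan(300, 0.29, 3.3e-4, ratio = "7:3", k_max = 30)
  tab <- as.data.frame(plan)
  expect_equal(tab$k, 1:30)
  expect_true(all(diff(tab$rss) > 0))
  # concavity: marginal RSS gains shrink
  expect_true(all(diff(diff(tab$rss)) < 0))
  expect_true(all(tab$ess <= 300))
  expect_true(!is.na(plan$k_diminishing))

  expect_equal(nrow(as.data.frame(pooling_plan(300, 0.29, 3.3e-4,
                                               var_construction = 0,
                                               k_max = 1))), 1L)
  zero <- pooling_plan(300, 0.29, 0, var_construction = 0, k_max = 5)
  expect_true(all(as.data.frame(zero)$rss == 1))
  expect_true(all(as.data.frame(zero)$ess == 300L))
  expect_error(pooling_plan(300, 0.6, 3.3e-4, ratio = "7:3"), "maf")
})

test_that("RSS tends to 1 and N* to N as replicate arrays grow", {
  Vs <- sampling_variance(0.29, 300)
  vp <- 3.3e-4 / 0.7
  expect_equal(relative_sample_size(Vs, vp, 1e9), 1, tolerance = 1e-5)
  expect_equal(effective_sample_size(relative_sample_size(Vs, vp, 1e9), 300),
               300L)
  # monotone sensitivity: more pooling variance, lower RSS at fixed k
  expect_gt(relative_sample_size(Vs, vp, 6),
            relative_sample_size(Vs, 2 * vp, 6))
})

test_that("minimal arrays for a target RSS: closed form agrees with a scan", {
  plan_case <- pooling_plan(300, 0.29, 3.3e-4, ratio = "7:3")
  expect_equal(arrays_for_target_rss(plan_case, 0.8), 6L)
  expect_equal(arrays_for_target_rss(plan_case, 0.0001), 1L)
  plan_ctrl <- pooling_plan(1000, 0.29, 3.3e-4, ratio = "7:3")
  expect_equal(arrays_for_target_rss(plan_ctrl, 0.8), 19L)
  expect_error(arrays_for_target_rss(plan_case, 1), "unreachable")

  # parameter grid: closed form vs linear scan
  for (va in c(1e-4, 3.3e-4, 1e-3)) {
    for (maf in c(0.1, 0.29, 0.5)) {
      for (N in c(74, 300, 446)) {
        plan <- pooling_plan(N, maf, va, ratio = "7:3")
        for (target in c(0.5, 0.8, 0.9, 0.99)) {
          k_cf <- arrays_for_target_rss(plan, target)
          k_scan <- which(relative_sample_size(plan$Vs, plan$var_pooling,
                                               1:10000) >= target)[1]
          expect_equal(k_cf, as.integer(k_scan))
        }
      }
    }
  }
})

test_that("array allocation between pools minimises the summed estimation variance", {
  expect_equal(unname(optimal_allocation(12, 4.7e-4, 4.7e-4)), c(6L, 6L))
  expect_equal(unname(optimal_allocation(13, 4.7e-4, 4.7e-4)), c(6L, 7L))
  expect_equal(unname(optimal_allocation(6, 4e-4, 1e-4)), c(4L, 2L))
  expect_error(optimal_allocation(1, 1e-4, 1e-4), ">= 2")

  # brute-force oracle over random variance pairs
  set.seed(12)
  for (i in 1:20) {
    va <- stats::runif(1, 1e-5, 1e-3)
    vb <- stats::runif(1, 1e-5, 1e-3)
    T <- sample(2:40, 1)
    alloc <- optimal_allocation(T, va, vb)
    obj <- function(ka) va / ka + vb / (T - ka)
    best <- min(vapply(seq_len(T - 1), obj, numeric(1)))
    expect_equal(obj(alloc[["kA"]]), best, tolerance = 1e-12)
    expect_equal(sum(alloc), T)
  }

  # equal pooling variances: the (near-)equal split is always optimal
  for (T in 2:30) {
    alloc <- optimal_allocation(T, 3e-4, 3e-4)
    expect_lte(abs(alloc[["kA"]] - alloc[["kB"]]), 1L)
  }
})

test_that("pooling costs scale as pools x arrays x price", {
  cs <- cost_summary(2, 12, 250, 4000)
  expect_equal(cs$pooling_cost, 6000)
  expect_equal(cs$individual_cost, 1e6)
  expect_equal(cs$percent, 0.6)
  expect_equal(cost_summary(1, 1, 99, 10)$pooling_cost, 99)
  expect_equal(cost_summary(2, 5, 100, 10)$percent, 100)
})
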