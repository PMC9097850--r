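null_design <- function(seed = NULL) {
  simulation_design(baseline = c(Ywhaz = 22, Ppia = 19, Gapdh = 18,
                                 Hprt1 = 24, Actb = 17, B2m = 20.5),
                    noise_sd = 0.3, loading_sd = 0.3, seed = seed)
}

test_that("the null generator keeps the type-I error rate at alpha", {
  alpha <- 0.05
  n_sims <- 170  # 170 x 6 genes = 1020 gene-level tests
  rejections <- 0L
  total <- 0L
  for (seed in seq_len(n_sims)) {
    d <- null_design()
    d$regions <- "HIP"
    m <- simulate_ct(d, seed = 5000 + seed)
    scr <- variation_screen(m, "HIP", alpha = alpha)
    rejections <- rejections + sum(!scr$stable)
    total <- total + nrow(scr)
  }
  rate <- rejections / total
  band <- 2 * sqrt(alpha * (1 - alpha) / total)
  expect_lt(abs(rate - alpha), band)
})

test_that("an injected late Actb induction is detected as unstable", {
  hits <- 0L
  for (seed in 1:20) {
    m <- simulate_ct(tmcao_preset(), seed = 300 + seed)
    scr <- variation_screen(m, "CX")
    if (!scr$stable[scr$gene == "Actb"]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("screen preconditions and outputs are sound", {
  d <- null_design()
  d$regions <- "CX"
  d$time_points <- "12h"
  m <- simulate_ct(d, seed = 1)
  # keep only SHAM -> a single group
  keep <- m$samples$condition == "SHAM"
  m1 <- ct_matrix(m$ct[keep, ], m$samples$condition[keep],
                  m$samples$time_point[keep], m$samples$region[keep])
  expect_error(variation_screen(m1, "CX"), "at least 2 groups")

  scr <- variation_screen(m, "CX")
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  gs <- attr(scr, "group_stats")
  expect_equal(nrow(gs), 6 * 2)  # 6 genes x (SHAM, tMCAO) at one time point
  expect_true(all(is.finite(gs$mean)))
})

test_that("Welch and classical screens agree on strong effects", {
  m <- simulate_ct(tmcao_preset(), seed = 77)
  scr1 <- variation_screen(m, "DS")
  scr2 <- variation_screen(m, "DS", welch = TRUE)
  expect_equal(scr1$stable[scr1$gene == "B2m"], scr2$stable[scr2$gene == "B2m"])
  expect_false(scr1$stable[scr1$gene == "B2m"])
})

test_that("fold change recovers an injected shift exactly in the noiseless limit", {
  d <- simulation_design(baseline = c(A = 20, B = 22, C = 24, target = 21),
                         noise_sd = 0, loading_sd = 0,
                         effects = data.frame(gene = "target",
                                              condition = "tMCAO",
                                              time_point = "3d", region = "CX",
                                              shift = -log2(5)),
                         regions = "CX")
  m <- simulate_ct(d, seed = 1)
  fc <- fold_change(m, "target", "CX", normalizer = c("A", "B", "C"))
  expect_equal(fc$fold[fc$time_point == "3d"], 5, tolerance = 1e-9)
  expect_equal(fc$fold[fc$time_point == "12h"], 1, tolerance = 1e-9)
})

test_that("fold change is invariant to per-sample loading shifts", {
  m <- simulate_ct(tmcao_preset(), seed = 4)
  fc1 <- fold_change(m, "Actb", "CX", normalizer = c("Ppia", "Hprt1", "Ywhaz"))
  m$ct <- m$ct + rnorm(nrow(m$ct), 0, 2)  # arbitrary per-sample constants
  fc2 <- fold_change(m, "Actb", "CX", normalizer = c("Ppia", "Hprt1", "Ywhaz"))
  expect_equal(fc1$fold, fc2$fold, tolerance = 1e-9)
})

test_that("the preset recovers the reported Actb induction range", {
  # With n = 8 per group the log2 fold estimate has SE ~ 0.24 cycles, so
  # single-study estimates land inside the one-quarter-cycle-wide 4-6-fold
  # window only ~3 times in 4; the mean across studies recovers the
  # injected 5-fold induction tightly.
  folds <- vapply(1:40, function(seed) {
    m <- simulate_ct(tmcao_preset(), seed = 900 + seed)
    fc <- fold_change(m, "Actb", "CX", normalizer = c("Ppia", "Hprt1", "Ywhaz"))
    fc$fold[fc$time_point == "3d"]
  }, 0)
  expect_gte(sum(folds >= 4 & folds <= 6), 24L)
  expect_equal(mean(log2(folds)), log2(5), tolerance = 0.08)
})

test_that("a gene cannot normalize itself", {
  m <- simulate_ct(tmcao_preset(), seed = 2)
  expect_error(fold_change(m, "Actb", "CX", c("Actb", "Ppia")), "normalizer")
})
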