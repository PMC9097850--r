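test_that("geometric mean of ranks matches hand-checked published cells", {
  expect_equal(round_half_up(geometric_mean_rank(c(4, 3, 3, 3))), 3.22)
  expect_equal(round_half_up(geometric_mean_rank(c(1, 1, 1, 1))), 1.00)
  expect_equal(round_half_up(geometric_mean_rank(c(5, 4, 5, 5))), 4.73)
  expect_error(geometric_mean_rank(numeric(0)), "empty")
  expect_error(geometric_mean_rank(c(0, 2)), ">= 1")
})

test_that("round_half_up rounds .005 upward, unlike base round", {
  expect_equal(round_half_up(2.005), 2.01)
  expect_equal(round_half_up(3.4641016), 3.46)
  expect_equal(round_half_up(-2.005), -2.01)
})

fake_result <- function(method, genes, scores, ...) {
  stability_tab <- data.frame(gene = genes, score = scores, ...,
                              stringsAsFactors = FALSE)
  rgstab:::stability_result(method, stability_tab)
}

test_that("rank assignment follows each method's convention", {
  genes <- c("A", "B", "C", "D")
  res <- list(
    fake_result("delta_ct", genes, c(0.4, 0.2, 0.6, 0.3)),
    fake_result("normfinder", genes, c(0.3, 0.1, 0.2, 0.4)),
    fake_result("bestkeeper", genes, c(0.5, 0.6, 1.4, 0.7),
                r = c(0.9, 0.95, 0.99, 0.2), excluded = c(FALSE, FALSE, TRUE, FALSE))
  )
  rt <- ranks_from_scores(res)
  expect_equal(rt$delta_ct, c(3L, 1L, 4L, 2L))
  expect_equal(rt$normfinder, c(3L, 1L, 2L, 4L))
  # BestKeeper: r descending among non-excluded (B, A, D), excluded C last
  expect_equal(rt$bestkeeper, c(2L, 1L, 4L, 3L))
})

test_that("ties are broken by delta-Ct score and reported", {
  genes <- c("A", "B", "C")
  res <- list(fake_result("delta_ct", genes, c(0.2, 0.1, 0.3)),
              fake_result("normfinder", genes, c(0.5, 0.5, 0.5)))
  expect_message(rt <- ranks_from_scores(res), "tie in normfinder")
  expect_equal(rt$normfinder, c(2L, 1L, 3L))  # by delta-Ct score
  expect_setequal(rt$normfinder, 1:3)
})

test_that("two genes always rank {1, 2} in every method", {
  b <- rand_block(n = 8, g = 2, seed = 6, sd = 0.4)
  res <- list(delta_ct_stability(b), bestkeeper(b))
  rt <- ranks_from_scores(res)
  expect_setequal(rt$delta_ct, 1:2)
  expect_setequal(rt$bestkeeper, 1:2)
})

test_that("comprehensive ranking equals the brute-force geometric mean", {
  set.seed(17)
  for (i in 1:10) {
    g <- sample(3:8, 1)
    rt <- data.frame(gene = paste0("G", 1:g),
                     delta_ct = sample(g), bestkeeper = sample(g),
                     normfinder = sample(g), genorm = sample(g))
    class(rt) <- c("rank_table", "data.frame")
    cr <- suppressMessages(comprehensive_ranking(rt))
    manual <- apply(rt[, -1], 1, function(r) prod(r)^(1 / 4))
    expect_equal(sort(cr$geomean), sort(manual), tolerance = 1e-12)
    expect_true(all(cr$geomean >= 1 & cr$geomean <= g))
    expect_false(is.unsorted(cr$geomean))
    # invariant to method column order
    rt2 <- rt[, c("gene", "genorm", "delta_ct", "bestkeeper", "normfinder")]
    class(rt2) <- c("rank_table", "data.frame")
    cr2 <- suppressMessages(comprehensive_ranking(rt2))
    expect_equal(cr2$geomean, cr$geomean)
    expect_equal(cr2$gene, cr$gene)
  }
})

test_that("unanimous methods reproduce the single-method order", {
  rt <- data.frame(gene = c("A", "B", "C"), delta_ct = c(2L, 1L, 3L),
                   bestkeeper = c(2L, 1L, 3L), normfinder = c(2L, 1L, 3L),
                   genorm = c(2L, 1L, 3L))
  class(rt) <- c("rank_table", "data.frame")
  cr <- comprehensive_ranking(rt)
  expect_equal(cr$gene, c("B", "A", "C"))
  expect_equal(cr$geomean, c(1, 2, 3))
})

test_that("a non-permutation rank column is rejected", {
  rt <- data.frame(gene = c("A", "B", "C"), delta_ct = c(1L, 1L, 3L))
  class(rt) <- c("rank_table", "data.frame")
  expect_error(comprehensive_ranking(rt), "not a permutation")
})

test_that("study-level aggregation reduces to the block for a single block", {
  rt <- data.frame(gene = c("A", "B", "C"), delta_ct = c(2L, 1L, 3L),
                   genorm = c(3L, 1L, 2L))
  class(rt) <- c("rank_table", "data.frame")
  cr <- comprehensive_ranking(rt)
  sl <- study_level_ranking(list(cr))
  expect_equal(sl$gene, cr$gene)
  expect_equal(sl$geomean, as.numeric(cr$rank))
})

test_that("study-level aggregation rejects inconsistent gene sets", {
  rt1 <- data.frame(gene = c("A", "B"), delta_ct = c(1L, 2L))
  rt2 <- data.frame(gene = c("A", "C"), delta_ct = c(1L, 2L))
  class(rt1) <- class(rt2) <- c("rank_table", "data.frame")
  expect_error(study_level_ranking(list(comprehensive_ranking(rt1),
                                        comprehensive_ranking(rt2))),
               "missing")
})
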