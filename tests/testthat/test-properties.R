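# Invariance and monotonicity properties of the stability metrics.

shift_gene <- function(b, gene, delta) {
  b$ct[, gene] <- b$ct[, gene] + delta
  b
}

test_that("per-gene constant shifts leave every stability score unchanged", {
  for (seed in 1:5) {
    b <- rand_block(n = 12, g = 5, seed = seed, sd = 0.5)
    b2 <- shift_gene(b, "G2", 3.7)
    expect_equal(delta_ct_stability(b2)$table$score,
                 delta_ct_stability(b)$table$score, tolerance = 1e-12)
    q1 <- to_relative_quantities(b)
    q2 <- to_relative_quantities(b2)
    expect_equal(genorm_m(q2), genorm_m(q1), tolerance = 1e-12)
    r1 <- genorm_rank(q1)
    expect_equal(genorm_pairwise_v(q2, r1$ranking)$v,
                 genorm_pairwise_v(q1, r1$ranking)$v, tolerance = 1e-12)
    expect_equal(suppressWarnings(normfinder_s(b2))$table$score,
                 suppressWarnings(normfinder_s(b))$table$score,
                 tolerance = 1e-12)
    bk1 <- bestkeeper(b)
    bk2 <- bestkeeper(b2)
    expect_equal(bk2$table$score, bk1$table$score, tolerance = 1e-12)
    # CV is NOT shift invariant (its denominator moves), and neither is r
    # exactly: the index is a geometric (not arithmetic) mean of Ct, so a
    # per-gene shift reweights it slightly. Assert r moves only modestly.
    expect_lt(max(abs(bk2$table$r - bk1$table$r)), 0.2)
  }
})

test_that("per-sample loading shifts cancel everywhere except BestKeeper SD", {
  for (seed in 1:5) {
    b <- rand_block(n = 12, g = 5, seed = seed, sd = 0.5)
    b2 <- b
    set.seed(seed + 100)
    b2$ct <- b2$ct + rnorm(12, 0, 1.5)  # strong per-sample loading effect
    expect_equal(delta_ct_stability(b2)$table$score,
                 delta_ct_stability(b)$table$score, tolerance = 1e-12)
    expect_equal(genorm_m(to_relative_quantities(b2)),
                 genorm_m(to_relative_quantities(b)), tolerance = 1e-12)
    r <- genorm_rank(to_relative_quantities(b))$ranking
    expect_equal(genorm_pairwise_v(to_relative_quantities(b2), r)$v,
                 genorm_pairwise_v(to_relative_quantities(b), r)$v,
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(normfinder_s(b2))$table$score,
                 suppressWarnings(normfinder_s(b))$table$score,
                 tolerance = 1e-12)
    # SDs all inflate (compare with a high cutoff so no gene is excluded)
    expect_true(all(bestkeeper(b2, sd_exclusion_cutoff = 10)$table$score >
                      bestkeeper(b, sd_exclusion_cutoff = 10)$table$score))
  }
})

test_that("inflating one gene's noise raises its delta-Ct score and M", {
  n_seeds <- 200
  dct_up <- m_up <- logical(n_seeds)
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    base <- rnorm(8, 20, 0.3)
    mk <- function(sd_target) {
      noise <- rnorm(8, 0, sd_target)
      cbind(A = base + rnorm(8, 0, 0.2), B = base + rnorm(8, 0, 0.2),
            C = base + rnorm(8, 0, 0.2), target = base + noise)
    }
    set.seed(seed + 1000)
    ct_lo <- mk(0.2)
    set.seed(seed + 1000)
    ct_hi <- mk(0.6)  # same noise draws, scaled: paired comparison
    s_lo <- delta_ct_stability(make_block(ct_lo))$table
    s_hi <- delta_ct_stability(make_block(ct_hi))$table
    dct_up[seed] <- s_hi$score[s_hi$gene == "target"] >
      s_lo$score[s_lo$gene == "target"]
    m_lo <- genorm_m(to_relative_quantities(make_block(ct_lo)))
    m_hi <- genorm_m(to_relative_quantities(make_block(ct_hi)))
    m_up[seed] <- m_hi[["target"]] > m_lo[["target"]]
  }
  # one-sided sign test against p = 0.5
  expect_lt(binom.test(sum(dct_up), n_seeds, alternative = "greater")$p.value,
            1e-6)
  expect_lt(binom.test(sum(m_up), n_seeds, alternative = "greater")$p.value,
            1e-6)
})

test_that("run_full_analysis is deterministic and self-consistent", {
  m <- simulate_ct(tmcao_preset(), seed = 8)
  res1 <- suppressMessages(suppressWarnings(run_full_analysis(m)))
  res2 <- suppressMessages(suppressWarnings(run_full_analysis(m)))
  expect_equal(comprehensive_table(res1), comprehensive_table(res2))
  expect_length(res1$blocks, 12L)
  # every reported geomean is reproducible from the reported per-method ranks
  ct_tab <- comprehensive_table(res1)
  manual <- apply(ct_tab[c("delta_ct", "bestkeeper", "normfinder", "genorm")],
                  1, function(r) prod(r)^(1 / 4))
  expect_equal(ct_tab$geomean, manual, tolerance = 1e-12)
})

test_that("restricting the input restricts the blocks", {
  m <- simulate_ct(tmcao_preset(), seed = 8)
  keep <- m$samples$region == "CX"
  m_cx <- ct_matrix(m$ct[keep, ], m$samples$condition[keep],
                    m$samples$time_point[keep], m$samples$region[keep])
  res <- suppressMessages(suppressWarnings(run_full_analysis(m_cx)))
  expect_length(res$blocks, 4L)
  expect_true(all(grepl("^CX_", names(res$blocks))))
})

test_that("a block failing preconditions is skipped with a reason", {
  m <- simulate_ct(tmcao_preset(), seed = 8)
  # wreck one block: leave only 2 complete samples in HIP 7d
  idx <- which(m$samples$region == "HIP" & m$samples$time_point == "7d")
  m$ct[idx[-(1:2)], "Gapdh"] <- NA
  res <- suppressMessages(suppressWarnings(run_full_analysis(m)))
  expect_length(res$blocks, 11L)
  expect_named(res$skipped, "HIP_7d")
})
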