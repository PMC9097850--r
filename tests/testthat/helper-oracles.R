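# Naive, loop-based reimplementations of every metric, written directly from
# the definitions. They deliberately share no code with the package and serve
# as independent oracles.

oracle_delta_ct <- function(ct) {
  genes <- colnames(ct)
  score <- numeric(length(genes))
  for (j in seq_along(genes)) {
    sds <- c()
    for (k in seq_along(genes)) {
      if (k == j) next
      diffs <- ct[, j] - ct[, k]
      sds <- c(sds, sd(diffs))
    }
    score[j] <- mean(sds)
  }
  setNames(score, genes)
}

oracle_genorm_m <- function(ct, efficiency = 2) {
  genes <- colnames(ct)
  q <- ct
  for (j in seq_along(genes)) q[, j] <- efficiency^(min(ct[, j]) - ct[, j])
  m <- numeric(length(genes))
  for (j in seq_along(genes)) {
    vs <- c()
    for (k in seq_along(genes)) {
      if (k == j) next
      vs <- c(vs, sd(log2(q[, j] / q[, k])))
    }
    m[j] <- mean(vs)
  }
  setNames(m, genes)
}

oracle_pairwise_v <- function(ct, ranking, efficiency = 2) {
  q <- ct
  for (j in seq_len(ncol(ct))) q[, j] <- efficiency^(min(ct[, j]) - ct[, j])
  q <- q[, ranking]
  g <- ncol(q)
  nf <- function(n) apply(q[, 1:n, drop = FALSE], 1, function(x) prod(x)^(1 / n))
  v <- numeric(g - 2)
  for (n in 2:(g - 1)) v[n - 1] <- sd(log2(nf(n) / nf(n + 1)))
  v
}

oracle_bestkeeper <- function(ct, cutoff = 1) {
  genes <- colnames(ct)
  sds <- cvs <- rs <- numeric(length(genes))
  for (j in seq_along(genes)) {
    sds[j] <- sd(ct[, j])
    cvs[j] <- 100 * sds[j] / mean(ct[, j])
  }
  excl <- sds > cutoff
  idx <- apply(ct[, !excl, drop = FALSE], 1, function(x) prod(x)^(1 / sum(!excl)))
  for (j in seq_along(genes)) rs[j] <- cor(ct[, j], idx)
  list(sd = setNames(sds, genes), cv = setNames(cvs, genes),
       r = setNames(rs, genes), excluded = setNames(excl, genes), index = idx)
}

oracle_normfinder <- function(ct, groups, efficiency = 2) {
  genes <- colnames(ct)
  k <- length(genes)
  y <- -ct * log2(efficiency)
  for (i in seq_len(nrow(y))) y[i, ] <- y[i, ] - mean(y[i, ])
  gl <- sort(unique(groups))
  G <- length(gl)
  d <- s2 <- matrix(0, G, k)
  ng <- numeric(G)
  for (gi in seq_len(G)) {
    zg <- y[groups == gl[gi], , drop = FALSE]
    ng[gi] <- nrow(zg)
    m <- numeric(k)
    for (j in seq_len(k)) m[j] <- sum((zg[, j] - mean(zg[, j]))^2) / (ng[gi] - 1)
    for (j in seq_len(k)) {
      s2[gi, j] <- max(k / (k - 2) * (m[j] - sum(m) / (k * (k - 1))), 0)
    }
    for (j in seq_len(k)) d[gi, j] <- mean(zg[, j])
  }
  for (j in seq_len(k)) d[, j] <- d[, j] - mean(d[, j])
  sv <- s2
  for (gi in seq_len(G)) sv[gi, ] <- s2[gi, ] / ng[gi]
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(sv))
  S <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(G)) {
      dsh <- if (gamma2 + sv[gi, j] > 0) {
        d[gi, j] * gamma2 / (gamma2 + sv[gi, j])
      } else 0
      acc <- acc + abs(dsh) + sqrt(sv[gi, j])
    }
    S[j] <- acc / G
  }
  setNames(S, genes)
}

oracle_normfinder_ungrouped <- function(ct, efficiency = 2) {
  genes <- colnames(ct)
  k <- length(genes)
  y <- -ct * log2(efficiency)
  for (i in seq_len(nrow(y))) y[i, ] <- y[i, ] - mean(y[i, ])
  m <- numeric(k)
  for (j in seq_len(k)) m[j] <- var(y[, j])
  S <- numeric(k)
  for (j in seq_len(k)) {
    S[j] <- sqrt(max(k / (k - 2) * (m[j] - sum(m) / (k * (k - 1))), 0))
  }
  setNames(S, genes)
}
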