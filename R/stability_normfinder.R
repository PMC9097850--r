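#' NormFinder stability value S
#'
#' Model-based decomposition of log-scale expression into a sample loading
#' effect, a gene effect, an intergroup (e.g. SHAM vs tMCAO) expression
#' difference and intragroup technical/biological noise. Working on
#' `y = log2` relative quantities, each sample is first centered across
#' genes, which removes the loading effect. For gene i in group g the model
#' then estimates
#'
#' * the intergroup difference `d_ig`: the gene's mean centered value in
#'   group g minus its unweighted mean across groups (so the `d_ig` sum to
#'   zero over genes within a group and over groups within a gene), and
#' * the intragroup variance `sigma2_ig`, estimated unbiasedly from the
#'   within-group two-way residuals with the correction that removes the
#'   variance shared through sample centering (the estimate
#'   `k/(k-2) * (m_ig - sum_l m_lg / (k (k-1)))`, with `m_ig` the raw
#'   residual mean square and k the number of genes); negative estimates
#'   are floored at 0 with a warning.
#'
#' The intergroup differences are shrunken towards zero in proportion to
#' their sampling noise, `d~_ig = d_ig * gamma2 / (gamma2 + sigma2_ig/n_g)`,
#' where `gamma2` is the method-of-moments estimate of the true intergroup
#' variance (floored at 0). The stability value of gene i is
#'
#' `S_i = mean_g ( |d~_ig| + sqrt(sigma2_ig / n_g) )`,
#'
#' the shrunken systematic error plus the standard error of the group mean:
#' lowest S = most stable. With `use_groups = FALSE` the grouping is
#' ignored and `S_i` is the corrected standard deviation of the gene's
#' centered values.
#'
#' @param b A complete-data `ct_block` with at least 3 genes; with
#'   `use_groups = TRUE`, at least 2 groups of at least 2 samples each
#'   (grouping from `attr(b, "group_labels")`, by default the condition).
#' @param use_groups Use the group structure (default `TRUE`).
#' @param efficiency Amplification factor for the log transform (default 2).
#' @return A [stability_result] with method `"normfinder"`; the table also
#'   reports the mean absolute shrunken intergroup difference
#'   (`intergroup`) and the mean group-mean standard error (`intragroup_se`)
#'   per gene (zero / the SD in ungrouped mode).
#' @references Andersen, Jensen & Orntoft (2004), Cancer Res 64:5245-5250.
#' @export
normfinder_s <- function(b, use_groups = TRUE, efficiency = 2) {
  stopifnot(inherits(b, "ct_block"))
  ct <- block_ct(b)
  check_block_size(ct, min_genes = 3L, min_samples = 3L)
  genes <- colnames(ct)
  k <- length(genes)
  # log2 quantities up to per-gene constants, which the model removes
  y <- -ct * log2(expand_efficiency(efficiency, genes))[col(ct)]
  z <- y - rowMeans(y)  # sample centering removes the loading effect

  if (!use_groups) {
    m <- apply(z, 2, function(col) stats::var(col))
    s2 <- corrected_variance(m, k)
    tab <- data.frame(gene = genes, score = sqrt(s2),
                      intergroup = 0, intragroup_se = sqrt(s2),
                      stringsAsFactors = FALSE)
    return(stability_result("normfinder", tab))
  }

  groups <- attr(b, "group_labels")
  if (is.null(groups)) groups <- b$samples$condition
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("NormFinder grouped mode needs at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 samples (got: ",
         paste(sprintf("%s n=%d", names(sizes), sizes), collapse = ", "), ")",
         call. = FALSE)
  }
  G <- nlevels(groups)
  group_mean <- t(vapply(levels(groups), function(g) {
    colMeans(z[groups == g, , drop = FALSE])
  }, numeric(k)))                      # G x k
  d <- sweep(group_mean, 2, colMeans(group_mean))  # intergroup differences
  sigma2 <- t(vapply(levels(groups), function(g) {
    zg <- z[groups == g, , drop = FALSE]
    resid <- sweep(zg, 2, colMeans(zg))
    m <- colSums(resid^2) / (nrow(zg) - 1L)
    corrected_variance(m, k)
  }, numeric(k)))                      # G x k
  n_g <- as.numeric(sizes[levels(groups)])
  samp_var <- sigma2 / n_g             # sampling variance of each d_ig
  gamma2 <- sum(d^2) / ((k - 1L) * (G - 1L)) - mean(samp_var)
  if (gamma2 < 0) gamma2 <- 0
  d_shrunk <- d * gamma2 / (gamma2 + samp_var)
  d_shrunk[!is.finite(d_shrunk)] <- 0  # gamma2 and samp_var both 0
  s_per_group <- abs(d_shrunk) + sqrt(samp_var)
  tab <- data.frame(gene = genes,
                    score = colMeans(s_per_group),
                    intergroup = colMeans(abs(d_shrunk)),
                    intragroup_se = colMeans(sqrt(samp_var)),
                    stringsAsFactors = FALSE)
  stability_result("normfinder", tab)
}

# Unbiased intragroup variance given raw residual mean squares m (per gene)
# after sample centering across k genes; floors negative estimates at 0.
corrected_variance <- function(m, k) {
  if (k < 3L) stop("variance correction requires at least 3 genes", call. = FALSE)
  s2 <- k / (k - 2) * (m - sum(m) / (k * (k - 1)))
  if (any(s2 < 0)) {
    warning("negative intragroup variance estimate floored at 0 for: ",
            paste(names(m)[s2 < 0], collapse = ", "), call. = FALSE)
    s2[s2 < 0] <- 0
  }
  s2
}
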