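#' BestKeeper descriptive stability analysis
#'
#' Works directly on raw Ct values. Per gene it reports the sample standard
#' deviation `SD (+/- Ct)`, the coefficient of variation `CV (%Ct)`
#' (100 * SD / mean Ct), and the Pearson correlation `r` (with two-sided
#' p-value) between the gene's Ct and the BestKeeper index — the per-sample
#' geometric mean of the Ct values of all non-excluded genes. Genes with
#' `SD > sd_exclusion_cutoff` (default 1 cycle, i.e. about a two-fold
#' expression range) are flagged unstable and excluded from the index, but
#' their correlation with the index is still reported.
#'
#' Ranking convention (see [ranks_from_scores()]): non-excluded genes by r
#' descending, then excluded genes by r descending.
#'
#' @param b A complete-data `ct_block` with at least 2 genes and 3 samples.
#' @param sd_exclusion_cutoff SD threshold in cycles above which a gene is
#'   excluded from the index. Default 1.0.
#' @return A [stability_result] with method `"bestkeeper"`; `score` is the
#'   raw-Ct SD and the table carries `cv`, `r`, `p` and `excluded`. The
#'   per-sample index is attached as attribute `"index"`.
#' @references Pfaffl et al. (2004), Biotechnol Lett 26:509-515.
#' @export
bestkeeper <- function(b, sd_exclusion_cutoff = 1) {
  stopifnot(inherits(b, "ct_block"))
  ct <- block_ct(b)
  check_block_size(ct)
  genes <- colnames(ct)
  sds <- apply(ct, 2, stats::sd)
  cvs <- 100 * sds / colMeans(ct)
  excluded <- sds > sd_exclusion_cutoff
  if (all(excluded)) {
    stop("all genes exceed the SD exclusion cutoff (", sd_exclusion_cutoff,
         "); no BestKeeper index can be formed", call. = FALSE)
  }
  index <- exp(rowMeans(log(ct[, !excluded, drop = FALSE])))
  r <- p <- rep(NA_real_, length(genes))
  for (j in seq_along(genes)) {
    if (sds[j] == 0) {
      warning("gene ", genes[j],
              " has constant Ct; correlation with the index is undefined",
              call. = FALSE)
      next
    }
    if (stats::sd(index) == 0) next
    test <- stats::cor.test(ct[, j], index)
    r[j] <- unname(test$estimate)
    p[j] <- test$p.value
  }
  tab <- data.frame(gene = genes, score = unname(sds), cv = unname(cvs),
                    r = r, p = p, excluded = unname(excluded),
                    stringsAsFactors = FALSE)
  res <- stability_result("bestkeeper", tab, excluded = genes[excluded])
  attr(res, "index") <- index
  res
}
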