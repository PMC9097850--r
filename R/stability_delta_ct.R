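#' Comparative delta-Ct stability
#'
#' For each candidate gene, forms its pairwise Ct difference against every
#' other candidate and scores the gene by the mean of the sample standard
#' deviations of those differences (the "average SD", in cycles). A gene
#' whose Ct tracks the others up to a constant offset scores 0; noisy or
#' regulated genes score high.
#'
#' All standard deviations in this package use the unbiased n-1 denominator.
#'
#' @param b A complete-data `ct_block` with at least 2 genes and 3 samples.
#' @return A [stability_result] with method `"delta_ct"`; `score` is the
#'   average SD in cycles.
#' @references The comparative delta-Ct approach of Silver et al. (2006),
#'   BMC Mol Biol 7:33.
#' @export
delta_ct_stability <- function(b) {
  stopifnot(inherits(b, "ct_block"))
  ct <- block_ct(b)
  check_block_size(ct)
  genes <- colnames(ct)
  g <- length(genes)
  score <- vapply(seq_len(g), function(j) {
    others <- setdiff(seq_len(g), j)
    mean(vapply(others, function(k) stats::sd(ct[, j] - ct[, k]), 0))
  }, 0)
  stability_result("delta_ct", data.frame(gene = genes, score = score,
                                          stringsAsFactors = FALSE))
}

# Average pairwise-difference SD on an arbitrary (log-quantity) matrix.
# Used for geNorm tie-breaks; identical ordering to delta_ct_stability on
# the Ct scale when the efficiency is shared across genes.
pairwise_sd_score <- function(y) {
  g <- ncol(y)
  vapply(seq_len(g), function(j) {
    others <- setdiff(seq_len(g), j)
    mean(vapply(others, function(k) stats::sd(y[, j] - y[, k]), 0))
  }, 0)
}
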