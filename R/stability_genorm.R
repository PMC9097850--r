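#' geNorm expression stability M
#'
#' For genes j and k, the pairwise variation `V_jk` is the standard
#' deviation over samples of `log2(q_j / q_k)`. The stability value of gene
#' j is the arithmetic mean of its pairwise variations against every other
#' gene in `subset`: `M_j = mean_{k != j} V_jk`. Lower M means more stable;
#' by convention genes with M above 1.0 are regarded as unstable.
#'
#' When the amplification factor is 2 for all genes, `log2(q_j/q_k)` equals
#' the negated Ct difference, so full-panel M coincides with the comparative
#' delta-Ct score.
#'
#' @param q An `rq_matrix` from [to_relative_quantities()].
#' @param subset Genes over which to compute M (default: all genes in `q`);
#'   at least 2.
#' @return Named numeric vector of M values for the genes in `subset`.
#' @references Vandesompele et al. (2002), Genome Biol 3:research0034.
#' @export
genorm_m <- function(q, subset = NULL) {
  stopifnot(inherits(q, "rq_matrix"))
  genes <- colnames(q$q)
  if (is.null(subset)) subset <- genes
  if (!all(subset %in% genes)) {
    stop("subset contains unknown gene(s): ",
         paste(setdiff(subset, genes), collapse = ", "), call. = FALSE)
  }
  if (length(subset) < 2L) stop("geNorm M needs at least 2 genes", call. = FALSE)
  y <- log2(q$q[, subset, drop = FALSE])
  if (any(!is.finite(y))) stop("non-finite log-quantity encountered", call. = FALSE)
  g <- ncol(y)
  m <- vapply(seq_len(g), function(j) {
    others <- setdiff(seq_len(g), j)
    mean(vapply(others, function(k) stats::sd(y[, j] - y[, k]), 0))
  }, 0)
  names(m) <- subset
  m
}

#' geNorm iterative stability ranking
#'
#' Repeatedly removes the gene with the highest M from the panel,
#' recomputing M over the remaining genes, until two genes remain. The
#' stability ranking is the reverse exclusion order; the final two genes
#' cannot be separated by the algorithm (their M values are identical by
#' construction) and are flagged as a tied pair. For reporting, the tied
#' pair is assigned distinct rank positions 1 and 2, ordered by their
#' average pairwise-difference SD (the delta-Ct criterion computed on log2
#' quantities); aggregated rankings require distinct integer positions.
#'
#' Ties at an exclusion step (two genes sharing the maximal M) are broken by
#' excluding the gene with the larger log-quantity SD, and the decision is
#' reported via `message()`.
#'
#' @param q An `rq_matrix` with at least 3 genes.
#' @return A list with `ranking` (genes, most stable first),
#'   `m_at_exclusion` (named; for the tied pair, their shared final M),
#'   `m_full` (M on the complete panel), `tied_pair` (character(2)), and
#'   `stability` — a [stability_result] with method `"genorm"`, whose score
#'   is `m_at_exclusion` and whose explicit ordering is the ranking.
#' @export
genorm_rank <- function(q) {
  stopifnot(inherits(q, "rq_matrix"))
  genes <- colnames(q$q)
  if (length(genes) < 3L) stop("geNorm ranking needs at least 3 genes", call. = FALSE)
  y <- log2(q$q)
  m_full <- genorm_m(q)
  remaining <- genes
  excluded <- character(0)
  m_at_exclusion <- stats::setNames(numeric(length(genes)), genes)
  while (length(remaining) > 2L) {
    m <- genorm_m(q, subset = remaining)
    worst <- which(m == max(m))
    if (length(worst) > 1L) {
      sds <- vapply(remaining[worst], function(g) stats::sd(y[, g]), 0)
      pick <- worst[which.max(sds)]
      message("geNorm exclusion tie between ",
              paste(remaining[worst], collapse = ", "),
              "; excluding ", remaining[pick],
              " (larger log-quantity SD)")
    } else {
      pick <- worst
    }
    gene_out <- remaining[pick]
    m_at_exclusion[gene_out] <- m[pick]
    excluded <- c(excluded, gene_out)
    remaining <- setdiff(remaining, gene_out)
  }
  m_final <- genorm_m(q, subset = remaining)
  m_at_exclusion[remaining] <- m_final
  # order within the tied pair by the pairwise-SD (delta-Ct) criterion
  pair_score <- pairwise_sd_score(y)[match(remaining, genes)]
  pair <- remaining[order(pair_score, remaining)]
  ranking <- c(pair, rev(excluded))
  tab <- data.frame(gene = genes,
                    score = unname(m_at_exclusion[genes]),
                    m_full = unname(m_full[genes]),
                    exclusion_step = vapply(genes, function(g) {
                      i <- match(g, excluded)
                      if (is.na(i)) 0L else i
                    }, 0L),
                    tied_top_pair = genes %in% pair,
                    stringsAsFactors = FALSE)
  list(ranking = ranking,
       m_at_exclusion = m_at_exclusion[ranking],
       m_full = m_full,
       tied_pair = pair,
       stability = stability_result("genorm", tab, ordering = ranking))
}

#' geNorm pairwise variation V(n/n+1)
#'
#' Builds normalization factors `NF_n` as the geometric mean of the
#' relative quantities of the top n genes of the stability ranking and
#' computes `V_{n/n+1} = SD_i(log2(NF_n(i) / NF_{n+1}(i)))` for
#' n = 2..G-1. A low V means the (n+1)-th gene adds nothing; the
#' recommended number of reference genes is the smallest n with
#' `V < cutoff` (conventionally 0.15). When no V falls below the cutoff the
#' profile is flagged and more genes than the panel offers may be needed.
#'
#' @param q An `rq_matrix` with at least 3 genes.
#' @param ranking Stability ordering (most stable first); defaults to
#'   `genorm_rank(q)$ranking`.
#' @param cutoff V threshold below which adding another gene is considered
#'   unnecessary. Default 0.15.
#' @return An object of class `pairwise_variation`: list with `v` (named
#'   `V2/3`, `V3/4`, ...), `recommended_n` (`NA` when flagged),
#'   `none_below_cutoff` and `cutoff`.
#' @export
genorm_pairwise_v <- function(q, ranking = NULL, cutoff = 0.15) {
  stopifnot(inherits(q, "rq_matrix"))
  genes <- colnames(q$q)
  if (length(genes) < 3L) stop("pairwise variation needs at least 3 genes", call. = FALSE)
  if (is.null(ranking)) ranking <- genorm_rank(q)$ranking
  if (!setequal(ranking, genes)) {
    stop("`ranking` must be a permutation of the genes in `q`", call. = FALSE)
  }
  y <- log2(q$q[, ranking, drop = FALSE])
  g <- length(genes)
  nf_log <- vapply(2:g, function(n) rowMeans(y[, seq_len(n), drop = FALSE]),
                   numeric(nrow(y)))
  v <- vapply(seq_len(g - 2L), function(i) stats::sd(nf_log[, i] - nf_log[, i + 1L]), 0)
  names(v) <- paste0("V", 2:(g - 1L), "/", 3:g)
  below <- which(v < cutoff)
  structure(list(v = v,
                 recommended_n = if (length(below) > 0) unname(below[1]) + 1L else NA_integer_,
                 none_below_cutoff = length(below) == 0L,
                 cutoff = cutoff,
                 ranking = ranking),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("<pairwise_variation>\n")
  print(round(x$v, 4))
  if (x$none_below_cutoff) {
    cat(sprintf("no V below cutoff %.2f: more reference genes than the panel offers may be needed\n",
                x$cutoff))
  } else {
    cat(sprintf("recommended number of reference genes: %d (cutoff %.2f)\n",
                x$recommended_n, x$cutoff))
  }
  invisible(x)
}
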