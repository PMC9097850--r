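#' Integer rank positions from per-method stability results
#'
#' Converts a set of [stability_result] objects for one analysis block into
#' integer rank positions 1..G per method (1 = most stable). Delta-Ct,
#' NormFinder and score-only geNorm results are ranked by score ascending;
#' a geNorm result carrying an explicit iterative ordering uses it (with the
#' tied top pair at positions 1 and 2); BestKeeper is ranked by r descending
#' among non-excluded genes, with excluded genes last, themselves ordered by
#' r descending.
#'
#' Ranks are always a permutation of 1..G — fractional tied ranks are never
#' produced, because geometric-mean aggregation of the published kind
#' requires distinct integer positions. Ties are broken by the delta-Ct
#' score where one is available in `results`, then alphabetically, and are
#' reported via `message()`.
#'
#' @param results List of [stability_result] objects over the same gene set,
#'   at most one per method.
#' @return A `rank_table`: data frame with `gene` and one integer rank
#'   column per method.
#' @export
ranks_from_scores <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  if (!all(vapply(results, inherits, TRUE, "stability_result"))) {
    stop("`results` must be a list of stability_result objects", call. = FALSE)
  }
  methods <- vapply(results, function(r) r$method, "")
  if (anyDuplicated(methods)) stop("duplicate method in `results`", call. = FALSE)
  names(results) <- methods
  genes <- sort(results[[1]]$table$gene)
  for (r in results) {
    if (!setequal(r$table$gene, genes)) {
      stop("stability results cover different gene sets", call. = FALSE)
    }
  }
  dct <- results[["delta_ct"]]
  tie_break <- if (!is.null(dct)) {
    stats::setNames(dct$table$score, dct$table$gene)[genes]
  } else {
    stats::setNames(rep(0, length(genes)), genes)
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (m in methods) {
    out[[m]] <- method_ranks(results[[m]], genes, tie_break)
  }
  class(out) <- c("rank_table", "data.frame")
  out
}

method_ranks <- function(res, genes, tie_break) {
  tab <- res$table[match(genes, res$table$gene), ]
  if (!is.null(res$ordering)) {
    ordering <- res$ordering
  } else if (res$method == "bestkeeper") {
    key <- -tab$r
    key[is.na(key)] <- Inf  # undefined correlation ranks last in its tier
    ordering <- genes[order(tab$excluded, key, tie_break, genes)]
    report_ties(interaction(tab$excluded, tab$r, drop = TRUE), res$method, genes)
  } else {
    ordering <- genes[order(tab$score, tie_break, genes)]
    report_ties(tab$score, res$method, genes)
  }
  match(genes, ordering)
}

report_ties <- function(key, method, genes) {
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    message("tie in ", method, " ranking among ",
            paste(genes[dup], collapse = ", "),
            "; broken by delta-Ct score, then alphabetically")
  }
}

#' Geometric mean of rank positions
#'
#' @param ranks Numeric vector of rank positions, all >= 1.
#' @return The geometric mean `(prod(ranks))^(1/length(ranks))` at full
#'   precision. Display rounding is half-up to 2 decimals (see
#'   [round_half_up()]).
#' @export
geometric_mean_rank <- function(ranks) {
  if (length(ranks) == 0L) stop("empty rank vector", call. = FALSE)
  if (any(!is.finite(ranks)) || any(ranks < 1)) {
    stop("ranks must be finite and >= 1", call. = FALSE)
  }
  exp(mean(log(ranks)))
}

#' Round half away from zero
#'
#' Decimal display rounding in which .005 rounds up, matching how the
#' published comprehensive geomeans are typeset (base R's `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Comprehensive (geometric-mean) ranking of one block
#'
#' Aggregates a block's per-method integer ranks into the RefFinder-style
#' comprehensive ranking: per gene, the geometric mean of its rank
#' positions across methods, ordered ascending. Geomean ties are broken by
#' the delta-Ct rank column when present, then alphabetically, and
#' reported.
#'
#' @param rt A `rank_table` from [ranks_from_scores()].
#' @return A `comprehensive_ranking`: data frame with `gene`, `geomean`
#'   (full precision), `geomean_2dp` (display), `rank` (final position),
#'   ordered most stable first, with the per-method ranks retained.
#' @export
comprehensive_ranking <- function(rt) {
  stopifnot(inherits(rt, "rank_table") || is.data.frame(rt))
  method_cols <- setdiff(names(rt), "gene")
  if (length(method_cols) == 0L) stop("rank table has no method columns", call. = FALSE)
  rk <- as.matrix(rt[method_cols])
  check_permutations(rk, method_cols)
  gm <- apply(rk, 1, geometric_mean_rank)
  tie2 <- if ("delta_ct" %in% method_cols) rt[["delta_ct"]] else rep(0, nrow(rt))
  report_ties(gm, "comprehensive", rt$gene)
  ord <- order(gm, tie2, rt$gene)
  out <- data.frame(gene = rt$gene[ord],
                    geomean = gm[ord],
                    geomean_2dp = round_half_up(gm[ord], 2),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out <- cbind(out, rt[ord, method_cols, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("comprehensive_ranking", "data.frame")
  out
}

check_permutations <- function(rk, method_cols) {
  for (j in seq_len(ncol(rk))) {
    if (!setequal(rk[, j], seq_len(nrow(rk)))) {
      stop("rank column ", sQuote(method_cols[j]),
           " is not a permutation of 1..", nrow(rk), call. = FALSE)
    }
  }
  invisible(rk)
}

#' Study-level ranking across blocks
#'
#' Aggregates per-block comprehensive rankings (or rank tables reduced to a
#' single method) into one ordered gene list: per gene, the geometric mean
#' of its final rank positions across all blocks. Every gene must appear in
#' every block. Ties are broken by the mean per-block geomean, then
#' alphabetically.
#'
#' @param per_block List of `comprehensive_ranking` objects (one per
#'   region x time-point block).
#' @return Data frame with `gene`, `geomean` (across blocks), `rank`,
#'   ordered most stable first.
#' @export
study_level_ranking <- function(per_block) {
  stopifnot(is.list(per_block), length(per_block) >= 1L)
  if (!all(vapply(per_block, inherits, TRUE, "comprehensive_ranking"))) {
    stop("`per_block` must be a list of comprehensive_ranking objects", call. = FALSE)
  }
  genes <- sort(per_block[[1]]$gene)
  ranks <- vapply(per_block, function(b) {
    i <- match(genes, b$gene)
    if (anyNA(i)) {
      stop("gene(s) missing from a block: ",
           paste(genes[is.na(i)], collapse = ", "), call. = FALSE)
    }
    b$rank[i]
  }, numeric(length(genes)))
  ranks <- matrix(ranks, nrow = length(genes))
  gms <- vapply(per_block, function(b) b$geomean[match(genes, b$gene)],
                numeric(length(genes)))
  gms <- matrix(gms, nrow = length(genes))
  gm <- apply(ranks, 1, geometric_mean_rank)
  ord <- order(gm, rowMeans(gms), genes)
  data.frame(gene = genes[ord], geomean = gm[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
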