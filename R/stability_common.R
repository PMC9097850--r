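#' Stability result container
#'
#' Every stability algorithm returns a `stability_result`: a per-gene score
#' where lower always means more stable, plus method-specific auxiliary
#' statistics. BestKeeper additionally reports the Pearson correlation `r`
#' of each gene with its index, which is ranked descending (see
#' [ranks_from_scores()]).
#'
#' @param method One of `"delta_ct"`, `"genorm"`, `"normfinder"`,
#'   `"bestkeeper"`.
#' @param table Data frame with at least `gene` and `score`.
#' @param excluded Character vector of genes excluded by the method
#'   (BestKeeper's SD rule).
#' @param ordering Optional explicit stability ordering (most stable first);
#'   used by geNorm, whose ranking comes from iterative exclusion rather
#'   than from sorting a single score.
#' @return An object of class `stability_result`.
#' @keywords internal
stability_result <- function(method, table, excluded = character(),
                             ordering = NULL) {
  stopifnot(is.data.frame(table), all(c("gene", "score") %in% names(table)))
  structure(list(method = method, table = table, excluded = excluded,
                 ordering = ordering),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result: %s>\n", x$method))
  tab <- x$table[order(x$table$score), ]
  print(tab, row.names = FALSE, digits = 4)
  if (length(x$excluded) > 0) {
    cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a block to relative quantities
#'
#' Transforms Ct values to unitless relative quantities
#' `q = E^(Ct_min - Ct)`, gene by gene, where `E` is the per-cycle
#' amplification factor (2 at 100% efficiency) and `Ct_min` the lowest Ct of
#' that gene in the block. The most abundant sample of each gene therefore
#' has `q = 1` and all quantities lie in (0, 1]. This is the standard
#' preprocessing for geNorm-style analyses.
#'
#' @param b A complete-data `ct_block` (see [drop_missing()]).
#' @param efficiency Amplification factor per cycle, either a single number
#'   or a named per-gene vector; must be > 1. Default 2.
#' @return An object of class `rq_matrix` with elements `q` (samples x
#'   genes), `efficiency` (per-gene vector), `samples`, and the block's
#'   group labels and id carried over as attributes.
#' @export
to_relative_quantities <- function(b, efficiency = 2) {
  stopifnot(inherits(b, "ct_block"))
  ct <- block_ct(b)
  check_block_size(ct, min_genes = 1L, min_samples = 1L)
  eff <- expand_efficiency(efficiency, colnames(ct))
  q <- vapply(seq_len(ncol(ct)), function(j) {
    eff[j] ^ (min(ct[, j]) - ct[, j])
  }, numeric(nrow(ct)))
  dimnames(q) <- dimnames(ct)
  structure(list(q = q, efficiency = eff, samples = b$samples),
            class = "rq_matrix",
            group_labels = attr(b, "group_labels"),
            block_id = attr(b, "block_id"))
}

expand_efficiency <- function(efficiency, genes) {
  if (!is.numeric(efficiency) || any(efficiency <= 1)) {
    stop("`efficiency` must be numeric and > 1", call. = FALSE)
  }
  if (length(efficiency) == 1L) {
    eff <- rep(efficiency, length(genes))
  } else {
    if (is.null(names(efficiency)) || !all(genes %in% names(efficiency))) {
      stop("per-gene `efficiency` must be named and cover every gene",
           call. = FALSE)
    }
    eff <- unname(efficiency[genes])
  }
  names(eff) <- genes
  eff
}
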