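#' Analyze one region x time-point block with all four methods
#'
#' Runs comparative delta-Ct, geNorm (M, iterative ranking, pairwise
#' variation V), NormFinder and BestKeeper on one block, converts the four
#' results into integer ranks and aggregates them into the comprehensive
#' ranking.
#'
#' @param block A `ct_block`.
#' @param efficiency Amplification factor (scalar or per-gene named
#'   vector). Default 2.
#' @param sd_exclusion_cutoff BestKeeper SD exclusion threshold (cycles).
#'   Default 1.
#' @param v_cutoff Pairwise-variation threshold. Default 0.15.
#' @param use_groups NormFinder grouped mode. Default `TRUE`.
#' @param missing_policy Passed to [drop_missing()].
#' @return A list of class `block_analysis`: `block_id`, `results` (the
#'   four [stability_result]s), `genorm` (full [genorm_rank()] output),
#'   `pairwise_v`, `rank_table`, `comprehensive`.
#' @export
analyze_block <- function(block, efficiency = 2, sd_exclusion_cutoff = 1,
                          v_cutoff = 0.15, use_groups = TRUE,
                          missing_policy = "drop_sample") {
  stopifnot(inherits(block, "ct_block"))
  block <- drop_missing(block, policy = missing_policy)
  q <- to_relative_quantities(block, efficiency = efficiency)
  gn <- genorm_rank(q)
  results <- list(
    delta_ct = delta_ct_stability(block),
    bestkeeper = bestkeeper(block, sd_exclusion_cutoff = sd_exclusion_cutoff),
    normfinder = normfinder_s(block, use_groups = use_groups,
                              efficiency = efficiency),
    genorm = gn$stability
  )
  rt <- ranks_from_scores(results)
  structure(list(block_id = attr(block, "block_id"),
                 results = results,
                 genorm = gn,
                 pairwise_v = genorm_pairwise_v(q, ranking = gn$ranking,
                                                cutoff = v_cutoff),
                 rank_table = rt,
                 comprehensive = comprehensive_ranking(rt)),
            class = "block_analysis")
}

#' Full spatiotemporal stability analysis
#'
#' Slices a study into its region x time-point blocks, analyzes each with
#' [analyze_block()], and aggregates the per-block comprehensive rankings
#' into the study-level ordering. Blocks whose preconditions fail (too few
#' samples after missing-data handling, a group of size 1, ...) are
#' skipped with the reason recorded.
#'
#' @param m A `ct_matrix`.
#' @param composition Block composition: `"pooled"` (SHAM + tMCAO,
#'   default) or `"tmcao_only"`.
#' @inheritParams analyze_block
#' @return A list of class `study_analysis`: `blocks` (named list of
#'   `block_analysis`, names like `"CX_12h"`), `study` (study-level
#'   ranking), `skipped` (named character vector of reasons).
#' @export
run_full_analysis <- function(m, composition = c("pooled", "tmcao_only"),
                              efficiency = 2, sd_exclusion_cutoff = 1,
                              v_cutoff = 0.15, use_groups = TRUE,
                              missing_policy = "drop_sample") {
  stopifnot(inherits(m, "ct_matrix"))
  composition <- match.arg(composition)
  if (composition == "tmcao_only" && use_groups) {
    use_groups <- FALSE  # a single-condition block has no grouping
  }
  combos <- unique(m$samples[c("region", "time_point")])
  combos <- combos[order(match(combos$region, rg_regions),
                         match(combos$time_point, rg_time_points)), ]
  blocks <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(combos))) {
    id <- paste(combos$region[i], combos$time_point[i], sep = "_")
    res <- tryCatch(
      analyze_block(slice_block(m, combos$region[i], combos$time_point[i],
                                composition = composition),
                    efficiency = efficiency,
                    sd_exclusion_cutoff = sd_exclusion_cutoff,
                    v_cutoff = v_cutoff, use_groups = use_groups,
                    missing_policy = missing_policy),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message("skipping block ", id, ": ", res)
      skipped[id] <- res
    } else {
      blocks[[id]] <- res
    }
  }
  if (length(blocks) == 0L) stop("no analyzable blocks", call. = FALSE)
  study <- study_level_ranking(lapply(blocks, function(b) b$comprehensive))
  structure(list(blocks = blocks, study = study, skipped = skipped),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("<study_analysis> %d blocks analyzed", length(x$blocks)))
  if (length(x$skipped) > 0) cat(sprintf(", %d skipped", length(x$skipped)))
  cat("\nstudy-level ranking:\n")
  print(x$study, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy per-gene stability table of a study analysis
#'
#' One row per block x method x gene with the method score, the integer
#' rank, and the method-specific auxiliary statistics (BestKeeper `sd`,
#' `cv`, `r`, `p`, `excluded`; geNorm `m_full`, `exclusion_step`).
#'
#' @param x A `study_analysis` from [run_full_analysis()].
#' @return Data frame.
#' @export
stability_table <- function(x) {
  stopifnot(inherits(x, "study_analysis"))
  rows <- lapply(names(x$blocks), function(id) {
    b <- x$blocks[[id]]
    do.call(rbind, lapply(b$results, function(res) {
      tab <- res$table
      base <- data.frame(region = unname(b$block_id["region"]),
                         time_point = unname(b$block_id["time_point"]),
                         method = res$method, gene = tab$gene,
                         score = tab$score,
                         rank = b$rank_table[[res$method]][match(tab$gene, b$rank_table$gene)],
                         stringsAsFactors = FALSE)
      for (col in c("cv", "r", "p", "excluded", "m_full", "exclusion_step")) {
        base[[col]] <- if (col %in% names(tab)) tab[[col]] else NA
      }
      base
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tidy comprehensive-ranking table of a study analysis
#'
#' @param x A `study_analysis`.
#' @return Data frame with one row per block x gene: the per-method ranks,
#'   the geomean (full precision and 2 d.p. display) and the final rank.
#' @export
comprehensive_table <- function(x) {
  stopifnot(inherits(x, "study_analysis"))
  out <- do.call(rbind, lapply(names(x$blocks), function(id) {
    b <- x$blocks[[id]]
    cbind(data.frame(region = unname(b$block_id["region"]),
                     time_point = unname(b$block_id["time_point"]),
                     stringsAsFactors = FALSE),
          as.data.frame(b$comprehensive))
  }))
  rownames(out) <- NULL
  out
}

#' Tidy pairwise-variation table of a study analysis
#'
#' @param x A `study_analysis`.
#' @return Data frame with one row per block x V step, plus the
#'   recommended number of reference genes (`NA` when no V falls below the
#'   cutoff).
#' @export
pairwise_v_table <- function(x) {
  stopifnot(inherits(x, "study_analysis"))
  out <- do.call(rbind, lapply(names(x$blocks), function(id) {
    b <- x$blocks[[id]]
    pv <- b$pairwise_v
    data.frame(region = unname(b$block_id["region"]),
               time_point = unname(b$block_id["time_point"]),
               step = names(pv$v), v = unname(pv$v),
               recommended_n = pv$recommended_n,
               none_below_cutoff = pv$none_below_cutoff,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
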