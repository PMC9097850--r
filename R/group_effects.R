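#' Per-gene variance screen across condition x time groups
#'
#' Screens each candidate gene, within one brain region, for expression
#' variation across the condition x time-point groups (8 groups under the
#' full design) with a one-way analysis of variance; a gene is declared
#' "stable" when its p-value is at or above `alpha`. The screen only feeds
#' a stable/unstable label, so no post-hoc testing is performed; a Welch
#' correction is available for unequal group variances.
#'
#' The response scale is configurable because published screens of this
#' kind rarely state it: `"centered"` (default) tests per-sample centered
#' log2 quantities (loading-corrected relative expression), `"delta_ct"`
#' tests Ct minus the per-sample gene mean (the same quantity on the Ct
#' scale, opposite sign), and `"ct"` tests raw Ct.
#'
#' @param m A `ct_matrix` (samples with missing Ct are dropped with a
#'   message).
#' @param region Region label to screen.
#' @param alpha Significance level for the stable/unstable call. Default
#'   0.05.
#' @param response `"centered"`, `"delta_ct"` or `"ct"`.
#' @param welch Use Welch's ANOVA (`stats::oneway.test` with
#'   `var.equal = FALSE`). Default `FALSE`.
#' @param efficiency Amplification factor for the log2 transform.
#' @return Data frame with one row per gene: `gene`, `region`, `statistic`
#'   (F), `df1`, `df2`, `p_value`, `stable`. Per-group mean and SD of
#'   centered log2 relative expression are attached as attribute
#'   `"group_stats"`.
#' @export
variation_screen <- function(m, region, alpha = 0.05,
                             response = c("centered", "delta_ct", "ct"),
                             welch = FALSE, efficiency = 2) {
  stopifnot(inherits(m, "ct_matrix"))
  response <- match.arg(response)
  check_tokens(region, rg_regions, "region")
  keep <- m$samples$region == region & rowSums(is.na(m$ct)) == 0L
  dropped <- sum(m$samples$region == region) - sum(keep)
  if (dropped > 0) message("variation_screen: dropping ", dropped,
                           " sample(s) with missing Ct")
  if (!any(keep)) stop("no samples in region ", region, call. = FALSE)
  ct <- m$ct[keep, , drop = FALSE]
  meta <- m$samples[keep, ]
  grp <- factor(paste(meta$condition, meta$time_point, sep = "_"))
  if (nlevels(grp) < 2L) stop("variance screen needs at least 2 groups", call. = FALSE)
  if (any(table(grp) < 2L)) {
    stop("every condition x time group needs at least 2 samples", call. = FALSE)
  }
  genes <- colnames(ct)
  eff <- expand_efficiency(efficiency, genes)
  centered <- sweep(-ct * log2(eff)[col(ct)], 1, rowMeans(-ct * log2(eff)[col(ct)]))
  y <- switch(response,
              centered = centered,
              delta_ct = ct - rowMeans(ct),
              ct = ct)
  res <- lapply(seq_along(genes), function(j) {
    if (welch) {
      tst <- stats::oneway.test(y[, j] ~ grp, var.equal = FALSE)
      data.frame(statistic = unname(tst$statistic),
                 df1 = unname(tst$parameter[1]), df2 = unname(tst$parameter[2]),
                 p_value = tst$p.value)
    } else {
      fit <- stats::aov(y[, j] ~ grp)
      s <- summary(fit)[[1]]
      data.frame(statistic = s[["F value"]][1],
                 df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                 p_value = s[["Pr(>F)"]][1])
    }
  })
  out <- cbind(data.frame(gene = genes, region = region,
                          stringsAsFactors = FALSE),
               do.call(rbind, res))
  out$stable <- out$p_value >= alpha
  gs <- expand.grid(gene = genes, group = levels(grp),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gs$mean <- mapply(function(g, gr) mean(centered[grp == gr, g]), gs$gene, gs$group)
  gs$sd <- mapply(function(g, gr) stats::sd(centered[grp == gr, g]), gs$gene, gs$group)
  attr(out, "group_stats") <- gs
  out
}

#' Fold change of one gene versus time-matched SHAM
#'
#' Quantifies a gene relative to a normalizer set with the 2^-ddCt
#' convention: per sample, `dCt = Ct_gene - mean(Ct_normalizers)`; per time
#' point, `fold = 2^-(mean dCt_tMCAO - mean dCt_SHAM)`. A fold above 1
#' means higher expression after occlusion than in the time-matched SHAM
#' group. Being a within-sample contrast, the estimate is invariant to
#' per-sample loading shifts.
#'
#' @param m A `ct_matrix`.
#' @param gene Target gene symbol.
#' @param region Region label.
#' @param normalizer Non-empty character vector of reference genes; must
#'   not contain `gene`.
#' @return Data frame with `time_point`, `n_SHAM`, `n_tMCAO`, `log2_fold`,
#'   `fold`.
#' @export
fold_change <- function(m, gene, region, normalizer) {
  stopifnot(inherits(m, "ct_matrix"))
  check_tokens(region, rg_regions, "region")
  if (length(normalizer) == 0L) stop("`normalizer` must be non-empty", call. = FALSE)
  if (gene %in% normalizer) stop("`gene` must not be in its own normalizer set", call. = FALSE)
  missing_g <- setdiff(c(gene, normalizer), ct_genes(m))
  if (length(missing_g) > 0L) {
    stop("unknown gene(s): ", paste(missing_g, collapse = ", "), call. = FALSE)
  }
  keep <- m$samples$region == region & rowSums(is.na(m$ct[, c(gene, normalizer), drop = FALSE])) == 0L
  if (!any(keep)) stop("no usable samples in region ", region, call. = FALSE)
  ct <- m$ct[keep, , drop = FALSE]
  meta <- m$samples[keep, ]
  dct <- ct[, gene] - rowMeans(ct[, normalizer, drop = FALSE])
  tps <- intersect(rg_time_points, unique(meta$time_point))
  rows <- lapply(tps, function(tp) {
    sham <- dct[meta$time_point == tp & meta$condition == "SHAM"]
    tmcao <- dct[meta$time_point == tp & meta$condition == "tMCAO"]
    if (length(sham) == 0L || length(tmcao) == 0L) return(NULL)
    lf <- -(mean(tmcao) - mean(sham))
    data.frame(time_point = tp, n_SHAM = length(sham), n_tMCAO = length(tmcao),
               log2_fold = lf, fold = 2^lf, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
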