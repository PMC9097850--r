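#' @title Ct matrix data model
#' @name ct_matrix
#' @description
#' A `ct_matrix` holds one quantification-cycle (Ct/Cq) value per sample and
#' gene, together with the per-sample design metadata of the tMCAO study
#' layout: experimental condition (`SHAM`/`tMCAO`), post-reperfusion time
#' point (`12h`/`24h`/`3d`/`7d`) and brain region (`CX` frontal cortex,
#' `HIP` hippocampus, `DS` dorsal striatum). Technical replicates are assumed
#' to have been collapsed upstream: one Ct per sample x gene.
#'
#' Metadata vocabularies are closed and case-sensitive so that a mistyped
#' label can never silently merge or split groups; `aliases` maps
#' nonstandard tokens onto the canonical ones.
NULL

#' Canonical design vocabularies
#'
#' Allowed labels for condition, time point and region. These are the closed
#' vocabularies enforced by [ct_matrix()] and [read_ct_table()].
#'
#' @format Character vectors.
#' @export
rg_conditions <- c("SHAM", "tMCAO")

#' @rdname rg_conditions
#' @export
rg_time_points <- c("12h", "24h", "3d", "7d")

#' @rdname rg_conditions
#' @export
rg_regions <- c("CX", "HIP", "DS")

check_tokens <- function(x, allowed, what) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s token(s): %s (allowed: %s)", what,
                 paste(sQuote(bad), collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Construct a validated Ct matrix
#'
#' @param ct Numeric matrix, samples in rows, genes in columns; column names
#'   are gene symbols. Values are quantification cycles (typically 15-35);
#'   `NA` marks a missing measurement. Finite values must be positive.
#' @param condition,time_point,region Per-sample labels, recycled never;
#'   must come from the closed vocabularies ([rg_conditions],
#'   [rg_time_points], [rg_regions]).
#' @param sample_ids Unique sample identifiers; defaults to the row names
#'   of `ct`.
#'
#' @return An object of class `ct_matrix`: a list with elements `ct`
#'   (numeric matrix, row names = sample ids) and `samples` (data frame with
#'   `sample_id`, `condition`, `time_point`, `region`).
#' @seealso [read_ct_table()], [slice_block()], [simulate_ct()]
#' @export
ct_matrix <- function(ct, condition, time_point, region,
                      sample_ids = rownames(ct)) {
  ct <- as.matrix(ct)
  if (!is.numeric(ct)) stop("`ct` must be numeric", call. = FALSE)
  if (is.null(colnames(ct))) stop("`ct` must carry gene symbols as column names", call. = FALSE)
  if (is.null(sample_ids)) stop("sample ids are required (row names or `sample_ids`)", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  n <- nrow(ct)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(ct))) stop("duplicate gene symbols", call. = FALSE)
  if (length(sample_ids) != n || length(condition) != n ||
      length(time_point) != n || length(region) != n) {
    stop("metadata length does not match number of samples", call. = FALSE)
  }
  check_tokens(condition, rg_conditions, "condition")
  check_tokens(time_point, rg_time_points, "time_point")
  check_tokens(region, rg_regions, "region")
  bad <- which(!is.na(ct) & (!is.finite(ct) | ct <= 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("Ct values must be finite and > 0 or NA (first offender: sample %s, gene %s)",
                 sample_ids[bad[1, 1]], colnames(ct)[bad[1, 2]]), call. = FALSE)
  }
  rownames(ct) <- sample_ids
  structure(list(
    ct = ct,
    samples = data.frame(sample_id = sample_ids,
                         condition = as.character(condition),
                         time_point = as.character(time_point),
                         region = as.character(region),
                         stringsAsFactors = FALSE)
  ), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d samples x %d genes\n", nrow(x$ct), ncol(x$ct)))
  cat("  genes:", paste(colnames(x$ct), collapse = ", "), "\n")
  tab <- table(x$samples$region, x$samples$time_point)
  cat("  samples per region x time point:\n")
  print(tab)
  nm <- sum(is.na(x$ct))
  if (nm > 0) cat("  missing Ct values:", nm, "\n")
  invisible(x)
}

#' Gene symbols of a Ct matrix
#' @param x A `ct_matrix`.
#' @return Character vector of gene symbols.
#' @export
ct_genes <- function(x) colnames(x$ct)

meta_cols <- c("sample_id", "condition", "time_point", "region")

#' Read a wide Ct table
#'
#' Reads a UTF-8 CSV/TSV file with one row per sample, the metadata columns
#' `sample_id`, `condition`, `time_point`, `region`, and one numeric Ct
#' column per candidate gene. Empty cells and the token `NA` are parsed as
#' missing, never as zero.
#'
#' @param path Path to the file.
#' @param gene_columns Gene columns to keep; default: every non-metadata
#'   column.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.tab` -> tab, otherwise comma).
#' @param aliases Optional named character vector mapping nonstandard
#'   metadata tokens to canonical ones, e.g. `c(sham = "SHAM")`.
#' @return A validated [ct_matrix()].
#' @export
read_ct_table <- function(path, gene_columns = NULL, sep = NULL, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          fileEncoding = "UTF-8")
  missing_meta <- setdiff(meta_cols, names(df))
  if (length(missing_meta) > 0L) {
    stop("missing required column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(gene_columns)) gene_columns <- setdiff(names(df), meta_cols)
  missing_genes <- setdiff(gene_columns, names(df))
  if (length(missing_genes) > 0L) {
    stop("gene column(s) not in file: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  }
  if (length(gene_columns) == 0L) stop("no gene columns found", call. = FALSE)
  for (col in c("condition", "time_point", "region")) {
    df[[col]] <- apply_aliases(df[[col]], aliases)
  }
  ct <- matrix(NA_real_, nrow = nrow(df), ncol = length(gene_columns),
               dimnames = list(df$sample_id, gene_columns))
  for (j in seq_along(gene_columns)) {
    raw <- df[[gene_columns[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric Ct value %s in row %d, column %s",
                   sQuote(raw[bad[1]]), bad[1], gene_columns[j]), call. = FALSE)
    }
    ct[, j] <- val
  }
  ct_matrix(ct, df$condition, df$time_point, df$region, sample_ids = df$sample_id)
}

apply_aliases <- function(x, aliases) {
  if (is.null(aliases)) return(x)
  hit <- x %in% names(aliases)
  x[hit] <- unname(aliases[x[hit]])
  x
}

#' Read a long-format Ct table and pivot it wide
#'
#' Accepts the long layout (`sample_id`, `condition`, `time_point`,
#' `region`, `gene`, `ct`) and pivots it to the wide form used by
#' [ct_matrix()]. Metadata must be consistent within a sample; a duplicated
#' (sample, gene) pair is an error.
#'
#' @inheritParams read_ct_table
#' @return A validated [ct_matrix()].
#' @export
read_ct_long <- function(path, sep = NULL, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          fileEncoding = "UTF-8")
  need <- c(meta_cols, "gene", "ct")
  missing_meta <- setdiff(need, names(df))
  if (length(missing_meta) > 0L) {
    stop("missing required column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[c("sample_id", "gene")])) {
    stop("duplicated (sample_id, gene) pair in long table", call. = FALSE)
  }
  for (col in c("condition", "time_point", "region")) {
    df[[col]] <- apply_aliases(df[[col]], aliases)
  }
  meta <- unique(df[meta_cols])
  if (anyDuplicated(meta$sample_id)) {
    stop("inconsistent metadata within a sample_id", call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(df$ct))
  bad <- which(!is.na(df$ct) & is.na(val))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric Ct value %s in row %d", sQuote(df$ct[bad[1]]), bad[1]),
         call. = FALSE)
  }
  genes <- unique(df$gene)
  ct <- matrix(NA_real_, nrow = nrow(meta), ncol = length(genes),
               dimnames = list(meta$sample_id, genes))
  ct[cbind(match(df$sample_id, meta$sample_id), match(df$gene, genes))] <- val
  ct_matrix(ct, meta$condition, meta$time_point, meta$region,
            sample_ids = meta$sample_id)
}

#' Write a Ct matrix to a wide CSV/TSV file
#'
#' Round-trips with [read_ct_table()] up to floating-point formatting.
#'
#' @param x A `ct_matrix`.
#' @param path Output path; extension `.tsv`/`.tab` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- cbind(x$samples, as.data.frame(x$ct, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract one region x time-point analysis block
#'
#' Every stability metric operates on one block at a time, mirroring the
#' study's per-block rankings (e.g. cerebral cortex at 12 h). By default a
#' block pools SHAM and tMCAO samples (16 samples under the study design);
#' `composition = "tmcao_only"` restricts to the occluded animals.
#'
#' @param x A `ct_matrix`.
#' @param region,time_point Labels selecting the block.
#' @param composition `"pooled"` (default) or `"tmcao_only"`.
#' @return A `ct_block` (also a `ct_matrix`) whose samples all share the
#'   requested region and time point; the per-sample grouping used by
#'   NormFinder defaults to condition and is stored in
#'   `attr(, "group_labels")`.
#' @export
slice_block <- function(x, region, time_point,
                        composition = c("pooled", "tmcao_only")) {
  stopifnot(inherits(x, "ct_matrix"))
  composition <- match.arg(composition)
  check_tokens(region, rg_regions, "region")
  check_tokens(time_point, rg_time_points, "time_point")
  keep <- x$samples$region == region & x$samples$time_point == time_point
  if (composition == "tmcao_only") keep <- keep & x$samples$condition == "tMCAO"
  if (!any(keep)) {
    stop(sprintf("no samples for region %s, time point %s (%s)",
                 region, time_point, composition), call. = FALSE)
  }
  out <- ct_matrix(x$ct[keep, , drop = FALSE],
                   x$samples$condition[keep],
                   x$samples$time_point[keep],
                   x$samples$region[keep],
                   sample_ids = x$samples$sample_id[keep])
  class(out) <- c("ct_block", "ct_matrix")
  attr(out, "group_labels") <- out$samples$condition
  attr(out, "block_id") <- c(region = region, time_point = time_point)
  out
}

#' @export
print.ct_block <- function(x, ...) {
  id <- attr(x, "block_id")
  cat(sprintf("<ct_block> %s %s: %d samples x %d genes (%s)\n",
              id["region"], id["time_point"], nrow(x$ct), ncol(x$ct),
              paste(sprintf("%s n=%d", names(table(attr(x, "group_labels"))),
                            table(attr(x, "group_labels"))), collapse = ", ")))
  invisible(x)
}

#' Handle missing Ct values in a block
#'
#' The default policy removes every sample carrying at least one missing Ct
#' (reported via `message()`); `"error"` aborts on any missing value. The
#' stability algorithms all require complete data.
#'
#' @param b A `ct_block`.
#' @param policy `"drop_sample"` (default) or `"error"`.
#' @return A complete-data `ct_block`.
#' @export
drop_missing <- function(b, policy = c("drop_sample", "error")) {
  stopifnot(inherits(b, "ct_block"))
  policy <- match.arg(policy)
  incomplete <- rowSums(is.na(b$ct)) > 0L
  if (!any(incomplete)) return(b)
  if (policy == "error") {
    stop("missing Ct values in samples: ",
         paste(b$samples$sample_id[incomplete], collapse = ", "), call. = FALSE)
  }
  if (sum(!incomplete) < 3L) {
    stop("fewer than 3 complete samples remain after dropping missing data",
         call. = FALSE)
  }
  message("dropping ", sum(incomplete), " sample(s) with missing Ct: ",
          paste(b$samples$sample_id[incomplete], collapse = ", "))
  keep <- !incomplete
  out <- ct_matrix(b$ct[keep, , drop = FALSE],
                   b$samples$condition[keep], b$samples$time_point[keep],
                   b$samples$region[keep], b$samples$sample_id[keep])
  class(out) <- class(b)
  attr(out, "group_labels") <- attr(b, "group_labels")[keep]
  attr(out, "block_id") <- attr(b, "block_id")
  out
}

block_ct <- function(b) {
  if (anyNA(b$ct)) {
    stop("block contains missing Ct values; apply drop_missing() first",
         call. = FALSE)
  }
  b$ct
}

check_block_size <- function(ct, min_genes = 2L, min_samples = 3L) {
  if (ncol(ct) < min_genes) {
    stop("at least ", min_genes, " genes are required", call. = FALSE)
  }
  if (nrow(ct) < min_samples) {
    stop("at least ", min_samples, " samples are required", call. = FALSE)
  }
  invisible(ct)
}
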