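#' Read an expression matrix (TSV or MatrixMarket)
#'
#' Two dialects are supported. TSV: rows are genes, first column `gene_id`,
#' header row of cell ids, values CPM. MatrixMarket: a genes x cells `.mtx`
#' triplet with sidecar files `genes.tsv` and `cells.tsv` (one id per line)
#' in the same directory. Both are returned cells x genes. Readers reject —
#' never silently coerce — malformed input: duplicate ids, negative or
#' non-numeric CPM values are errors naming the offending entry.
#'
#' @param path path to the `.tsv`/`.txt` table or `.mtx` file.
#' @param pseudotime_path optional pseudotime TSV (see [read_pseudotime()]);
#'   reconciled to the matrix by cell id, not position.
#' @return an [expression_profile()].
#' @export
read_expression <- function(path, pseudotime_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- readLines(file.path(dir, "genes.tsv"))
    cells <- readLines(file.path(dir, "cells.tsv"))
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("sidecar genes.tsv/cells.tsv lengths do not match the matrix")
    cpm <- t(m)
    dimnames(cpm) <- list(cells, genes)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (names(df)[1] != "gene_id")
      stop("expression TSV must have 'gene_id' as its first column")
    vals <- df[, -1, drop = FALSE]
    for (j in seq_along(vals)) {
      if (!is.numeric(vals[[j]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
        stop(sprintf("malformed numeric field in column '%s', line %d",
                     names(vals)[j], bad + 1L))
      }
    }
    cpm <- t(as.matrix(vals))
    dimnames(cpm) <- list(names(vals), df$gene_id)
  }
  pt <- NULL
  if (!is.null(pseudotime_path)) pt <- read_pseudotime(pseudotime_path)
  expression_profile(cpm, pseudotime = pt)
}

#' Write an expression profile
#'
#' Writes the TSV dialect (genes x cells, first column `gene_id`) or, for a
#' `.mtx` path, the MatrixMarket triplet with `genes.tsv`/`cells.tsv`
#' sidecars. A `write then read` round trip reproduces the values to full
#' precision.
#'
#' @param profile an [expression_profile()].
#' @param path output path (`.tsv` or `.mtx`).
#' @export
write_expression <- function(profile, path) {
  stopifnot(inherits(profile, "expression_profile"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(t(profile$cpm), sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(profile$gene_ids, file.path(dir, "genes.tsv"))
    writeLines(profile$cell_ids, file.path(dir, "cells.tsv"))
  } else {
    df <- data.frame(gene_id = profile$gene_ids,
                     t(profile$cpm), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cell pseudotime table
#'
#' Expects a TSV with columns `cell_id` and `pseudotime`. Duplicate cell
#' ids and non-numeric pseudotime values are errors with line numbers.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of pseudotime keyed by cell id.
#' @export
read_pseudotime <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "pseudotime") %in% names(df)))
    stop("pseudotime TSV must have columns 'cell_id' and 'pseudotime'")
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell ids in pseudotime file: ",
         df$cell_id[duplicated(df$cell_id)][1])
  pt <- suppressWarnings(as.numeric(df$pseudotime))
  if (anyNA(pt))
    stop(sprintf("malformed numeric pseudotime at line %d",
                 which(is.na(pt))[1] + 1L))
  names(pt) <- df$cell_id
  pt
}

#' @rdname read_pseudotime
#' @param pseudotime named numeric vector.
#' @export
write_pseudotime <- function(pseudotime, path) {
  utils::write.table(data.frame(cell_id = names(pseudotime),
                                pseudotime = unname(pseudotime)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cumulative-labeling timecourse CSV
#'
#' Accepts `time_h,labeled,total,replicate` (counts) or
#' `time_h,li_percent,replicate` (labeling index directly).
#'
#' @param path path to the CSV file.
#' @return a [labeling_timecourse()].
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num_cols <- intersect(c("time_h", "labeled", "total", "li_percent"),
                        names(df))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v))
      stop(sprintf("malformed numeric field in column '%s', line %d",
                   cl, which(is.na(v))[1] + 1L))
    df[[cl]] <- v
  }
  labeling_timecourse(df)
}

#' @rdname read_timecourse
#' @param tc a [labeling_timecourse()].
#' @export
write_timecourse <- function(tc, path) {
  cols <- intersect(c("time_h", "labeled", "total", "replicate",
                      "li_percent"), names(tc))
  utils::write.csv(as.data.frame(tc)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param results a named list of results (coercible by jsonlite).
#' @param path output path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Estimate a whole-structure cell count from sampled sections
#'
#' Stereological scaling for counts made on a systematic series of sections:
#' with sections sampled at a known fraction of the structure (here 40-um
#' sections spaced 240 um apart, counted in one hemisphere — a 1-in-12
#' series), the per-section counts are summed and multiplied by the
#' sampling multiplier (default 12) to estimate the total, e.g. the number
#' of EdU- or BrdU-positive cells in the entire dentate gyrus. Averaging
#' per section before scaling is available behind `method = "mean"`.
#'
#' @param counts nonnegative integer vector of per-section immunopositive
#'   cell counts (at least one section).
#' @param multiplier positive integer sampling multiplier (default 12).
#' @param method `"sum"` (default) or `"mean"` aggregation before scaling.
#' @return the estimated whole-structure count.
#' @examples
#' estimate_total_count(c(3, 5, 2, 4))  # 168
#' @export
estimate_total_count <- function(counts, multiplier = 12,
                                 method = c("sum", "mean")) {
  method <- match.arg(method)
  if (length(counts) == 0) stop("at least one section count is required")
  if (anyNA(counts) || any(counts < 0))
    stop("section counts must be nonnegative")
  if (multiplier < 1) stop("'multiplier' must be at least 1")
  agg <- if (method == "sum") sum(counts) else mean(counts)
  agg * multiplier
}
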