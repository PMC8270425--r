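#' Cells-by-genes CPM expression profile
#'
#' The substrate of all trajectory and cell-cycle scoring stages: a numeric
#' cells x genes matrix of counts-per-million together with unique cell and
#' gene identifiers and an optional per-cell pseudotime. Pseudotime is an
#' input here (taken from an upstream trajectory inference), never estimated.
#'
#' @param cpm numeric matrix, cells in rows and genes in columns, all entries
#'   finite and nonnegative. Row and column names are used as cell and gene
#'   identifiers when `cell_ids`/`gene_ids` are not given.
#' @param pseudotime optional numeric vector of per-cell pseudotime values
#'   (finite; arbitrary units), one per row of `cpm`. May be named by cell id,
#'   in which case it is reconciled to the matrix by id, not position.
#' @param cell_ids,gene_ids optional character vectors of unique identifiers.
#'
#' @return An object of class `"expression_profile"`: a list with elements
#'   `cpm` (named matrix), `cell_ids`, `gene_ids` and `pseudotime` (or `NULL`).
#' @examples
#' m <- matrix(c(0, 1, 3, 5, 2, 0), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), c("Tbr2", "Gapdh")))
#' expression_profile(m, pseudotime = c(0, 0.5, 1))
#' @export
expression_profile <- function(cpm, pseudotime = NULL, cell_ids = NULL,
                               gene_ids = NULL) {
  if (!is.matrix(cpm) || !is.numeric(cpm))
    stop("'cpm' must be a numeric matrix (cells x genes)")
  if (is.null(cell_ids)) cell_ids <- rownames(cpm)
  if (is.null(gene_ids)) gene_ids <- colnames(cpm)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(cpm)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(cpm)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(cpm))
    stop("length of 'cell_ids' does not match nrow(cpm)")
  if (length(gene_ids) != ncol(cpm))
    stop("length of 'gene_ids' does not match ncol(cpm)")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyNA(cpm) || any(!is.finite(cpm)))
    stop("'cpm' contains missing or non-finite values")
  if (any(cpm < 0)) {
    idx <- which(cpm < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative CPM at cell '%s', gene '%s'",
                 cell_ids[idx[1]], gene_ids[idx[2]]))
  }
  dimnames(cpm) <- list(cell_ids, gene_ids)
  if (!is.null(pseudotime)) {
    if (!is.null(names(pseudotime))) {
      missing_pt <- setdiff(cell_ids, names(pseudotime))
      if (length(missing_pt))
        stop("cells missing a pseudotime value: ",
             paste(utils::head(missing_pt, 5), collapse = ", "))
      pseudotime <- pseudotime[cell_ids]
    }
    if (length(pseudotime) != nrow(cpm))
      stop("'pseudotime' must have one value per cell")
    if (anyNA(pseudotime) || any(!is.finite(pseudotime)))
      stop("'pseudotime' must be finite for every cell")
    pseudotime <- as.numeric(pseudotime)
    names(pseudotime) <- cell_ids
  }
  structure(list(cpm = cpm, cell_ids = cell_ids, gene_ids = gene_ids,
                 pseudotime = pseudotime),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile: %d cells x %d genes (CPM)\n",
              length(x$cell_ids), length(x$gene_ids)))
  if (!is.null(x$pseudotime))
    cat(sprintf("  pseudotime: [%.4g, %.4g]\n",
                min(x$pseudotime), max(x$pseudotime)))
  invisible(x)
}

#' @export
dim.expression_profile <- function(x) dim(x$cpm)

# internal: fetch one gene's CPM vector, erroring on unknown ids
gene_cpm <- function(profile, gene) {
  stopifnot(inherits(profile, "expression_profile"))
  if (length(gene) != 1L || !gene %in% profile$gene_ids)
    stop("unknown gene id: ", gene)
  profile$cpm[, gene]
}

profile_pseudotime <- function(profile) {
  if (is.null(profile$pseudotime))
    stop("this analysis requires a per-cell pseudotime in the profile")
  profile$pseudotime
}
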