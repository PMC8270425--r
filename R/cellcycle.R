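#' Cell-cycle phase marker set
#'
#' Pairs a G1/S marker list with a G2/M marker list. The package bundles the
#' Tirosh et al. melanoma cell-cycle program signatures converted to mouse
#' symbol casing (see [default_markers()]); any custom lists can be supplied.
#'
#' @param g1s_genes,g2m_genes nonempty character vectors of unique gene
#'   identifiers.
#' @param provenance free-text note on where the lists come from.
#' @return an object of class `"marker_set"`.
#' @export
marker_set <- function(g1s_genes, g2m_genes, provenance = "") {
  g1s_genes <- as.character(g1s_genes)
  g2m_genes <- as.character(g2m_genes)
  if (length(g1s_genes) == 0 || length(g2m_genes) == 0)
    stop("both marker lists must be nonempty")
  if (anyDuplicated(g1s_genes) || anyDuplicated(g2m_genes))
    stop("marker identifiers must be unique within each list")
  structure(list(g1s_genes = g1s_genes, g2m_genes = g2m_genes,
                 provenance = provenance),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d G1/S and %d G2/M genes\n",
              length(x$g1s_genes), length(x$g2m_genes)))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Bundled mouse cell-cycle marker lists
#'
#' Loads the G1/S and G2/M signatures shipped with the package
#' (Tirosh et al. human lists mouse-cased by upper/lower-case conversion),
#' stored as editable plain-text files under `extdata`.
#'
#' @return a [marker_set()].
#' @export
default_markers <- function() {
  read_markers(system.file("extdata", "markers_g1s_mouse.txt",
                           package = "stemcycle"),
               system.file("extdata", "markers_g2m_mouse.txt",
                           package = "stemcycle"))
}

#' Read marker lists from files
#'
#' Accepts either two plain-text files (one gene per line, `#` comments
#' allowed) or a single JSON file with keys `g1s` and `g2m`.
#'
#' @param g1s_path path to the G1/S list, or to the JSON file.
#' @param g2m_path path to the G2/M list; omit for JSON input.
#' @return a [marker_set()].
#' @export
read_markers <- function(g1s_path, g2m_path = NULL) {
  for (p in c(g1s_path, g2m_path))
    if (!file.exists(p)) stop("marker file not found: ", p)
  if (is.null(g2m_path)) {
    lst <- jsonlite::read_json(g1s_path, simplifyVector = TRUE)
    if (!all(c("g1s", "g2m") %in% names(lst)))
      stop("JSON marker file must have keys 'g1s' and 'g2m'")
    return(marker_set(lst$g1s, lst$g2m,
                      provenance = paste("read from", g1s_path)))
  }
  read_one <- function(path) {
    lines <- trimws(readLines(path))
    lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  marker_set(read_one(g1s_path), read_one(g2m_path),
             provenance = paste("read from", g1s_path, "and", g2m_path))
}

#' Summed-marker cell-cycle scores, median-normalized
#'
#' Computes per-cell G1/S and G2/M scores as the sum of transformed
#' expression over the phase's marker genes, then divides each score by its
#' median across cells so that a typical cell scores 1. Markers absent from
#' the matrix are dropped with a warning; if a phase's raw-score median is 0
#' the score is normalized by the mean of the strictly positive raw scores
#' instead (and left unnormalized, with a warning, if there are none).
#'
#' @param profile an [expression_profile()].
#' @param markers a [marker_set()]; defaults to the bundled mouse lists.
#' @param transform `"log2cpm1"` (default, `log2(CPM + 1)`) or `"cpm"`.
#' @return an object of class `"cycle_scores"`: data frame with columns
#'   `cell_id`, `raw_g1s`, `raw_g2m`, `norm_g1s`, `norm_g2m`.
#' @examples
#' m <- matrix(c(0, 3, 7, 0, 1, 1), 3, 2,
#'             dimnames = list(paste0("c", 1:3), c("a", "b")))
#' score_cell_cycle(expression_profile(m),
#'                  marker_set(c("a", "b"), "a"), transform = "cpm")
#' @export
score_cell_cycle <- function(profile, markers = default_markers(),
                             transform = c("log2cpm1", "cpm")) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(markers, "marker_set"))
  transform <- match.arg(transform)
  phase_score <- function(genes, phase) {
    present <- intersect(genes, profile$gene_ids)
    if (length(present) == 0)
      stop("no ", phase, " marker genes found in the expression matrix")
    if (length(present) < length(genes))
      warning(sprintf("%d of %d %s markers absent from the matrix; dropped",
                      length(genes) - length(present), length(genes), phase))
    x <- profile$cpm[, present, drop = FALSE]
    if (transform == "log2cpm1") x <- log2(x + 1)
    rowSums(x)
  }
  raw_g1s <- phase_score(markers$g1s_genes, "G1/S")
  raw_g2m <- phase_score(markers$g2m_genes, "G2/M")
  normalize <- function(raw, phase) {
    med <- stats::median(raw)
    if (med > 0) return(raw / med)
    pos <- raw[raw > 0]
    if (length(pos) > 0) return(raw / mean(pos))
    warning("all ", phase, " raw scores are zero; left unnormalized")
    raw
  }
  out <- data.frame(cell_id = profile$cell_ids,
                    raw_g1s = unname(raw_g1s), raw_g2m = unname(raw_g2m),
                    norm_g1s = unname(normalize(raw_g1s, "G1/S")),
                    norm_g2m = unname(normalize(raw_g2m, "G2/M")))
  attr(out, "transform") <- transform
  class(out) <- c("cycle_scores", "data.frame")
  out
}

#' Classify cells as cycling
#'
#' A cell is called cycling when the larger of its normalized G1/S and G2/M
#' scores reaches the threshold. The decision rule and its default threshold
#' of 2 (twice the typical cell's score) are the package's construction; the
#' threshold is recorded on the result and should be reported with it.
#'
#' @param scores a `"cycle_scores"` from [score_cell_cycle()].
#' @param threshold positive threshold on the normalized scores (default 2).
#' @return an object of class `"cycling_call"`: named logical vector with a
#'   `threshold` attribute.
#' @export
classify_cycling <- function(scores, threshold = 2) {
  stopifnot(inherits(scores, "cycle_scores"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  if (any(!is.finite(c(scores$norm_g1s, scores$norm_g2m))))
    stop("scores must be finite")
  call <- pmax(scores$norm_g1s, scores$norm_g2m) >= threshold
  names(call) <- scores$cell_id
  structure(call, threshold = threshold, class = "cycling_call")
}

#' @export
print.cycling_call <- function(x, ...) {
  cat(sprintf("cycling_call: %d of %d cells cycling (threshold %.3g)\n",
              sum(x), length(x), attr(x, "threshold")))
  invisible(x)
}

#' Cross-tabulate cycling status by marker positivity
#'
#' @param calls a `"cycling_call"` covering every cell in the profile.
#' @param profile an [expression_profile()].
#' @param gene marker gene whose positivity defines the rows.
#' @param positivity_threshold CPM threshold; positive iff CPM exceeds it.
#' @return 2x2 integer matrix, rows `positive`/`negative` for the gene,
#'   columns `cycling`/`noncycling`.
#' @export
tabulate_by_positivity <- function(calls, profile, gene,
                                   positivity_threshold = 0) {
  stopifnot(inherits(calls, "cycling_call"))
  x <- gene_cpm(profile, gene)
  if (!all(profile$cell_ids %in% names(calls)))
    stop("cycling calls do not cover every cell in the profile")
  cyc <- as.logical(calls[profile$cell_ids])
  pos <- x > positivity_threshold
  out <- matrix(c(sum(pos & cyc), sum(!pos & cyc),
                  sum(pos & !cyc), sum(!pos & !cyc)),
                2, 2, dimnames = list(c("positive", "negative"),
                                      c("cycling", "noncycling")))
  attr(out, "gene_id") <- gene
  attr(out, "positivity_threshold") <- positivity_threshold
  out
}

#' Percentage of cycling cells per positivity group
#'
#' Row-wise percentages `100 * cycling / (cycling + noncycling)`, rounded
#' half-away-from-zero to one decimal place. An empty row yields `NA`
#' (undefined), never 0.
#'
#' @param table 2x2 table with columns `cycling`, `noncycling` (as from
#'   [tabulate_by_positivity()]).
#' @return named numeric vector of per-row percentages.
#' @examples
#' percent_cycling(matrix(c(1, 20, 17, 62), 2, 2,
#'                 dimnames = list(c("positive", "negative"), NULL)))
#' @export
percent_cycling <- function(table) {
  tab <- check_2x2(table)
  n <- rowSums(tab)
  pct <- ifelse(n > 0, round_half_up(100 * tab[, 1] / n, 1), NA_real_)
  names(pct) <- rownames(tab)
  pct
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
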