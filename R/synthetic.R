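#' Specification of one simulated gene trend along pseudotime
#'
#' Describes the expected CPM of a gene as a smooth function of pseudotime,
#' emulating the qualitative profiles seen along the neurogenic trajectory:
#' a decreasing sigmoid (an H2-K1-like gene), a constant (Gapdh-like), an
#' increasing sigmoid (Ki67- or Tbr2-like), or a Gaussian bump (unimodal).
#' Sigmoid shapes are logistic in pseudotime; the functional family is the
#' package's own choice of a smooth two-parameter curve that is monotone
#' where monotonicity is required.
#'
#' The noiseless expected curve is
#' `baseline + amplitude * s(t)` where `s` is a logistic sigmoid rising from
#' 0 to 1 across `inflection` (shape increasing/decreasing), identically 0
#' (constant), or a unit Gaussian bump peaking at `inflection` (unimodal).
#'
#' @param gene_id gene identifier.
#' @param shape one of `"decreasing"`, `"constant"`, `"increasing"`,
#'   `"unimodal"`.
#' @param baseline mean CPM at the start of the trajectory (nonnegative).
#' @param amplitude CPM change across the trajectory; its sign must be
#'   consistent with `shape` (nonpositive for decreasing, nonnegative for
#'   increasing/unimodal, ignored for constant).
#' @param inflection pseudotime location of the sigmoid midpoint or unimodal
#'   peak (on the [0, 1] pseudotime scale).
#' @param steepness sigmoid steepness scale (pseudotime units); smaller is
#'   sharper. Width of the unimodal bump.
#' @param dropout probability in [0, 1] that a cell's value is zeroed.
#' @param dispersion multiplicative log-normal noise scale (sdlog, >= 0).
#'
#' @return an object of class `"gene_trend_spec"`.
#' @examples
#' gene_trend_spec("H2-K1", "decreasing", baseline = 100, amplitude = -90,
#'                 inflection = 0.6)
#' @export
gene_trend_spec <- function(gene_id, shape = c("decreasing", "constant",
                                               "increasing", "unimodal"),
                            baseline, amplitude = 0, inflection = 0.5,
                            steepness = 0.1, dropout = 0, dispersion = 0) {
  shape <- match.arg(shape)
  stopifnot(length(gene_id) == 1L, is.numeric(baseline), baseline >= 0,
            is.numeric(amplitude), is.finite(amplitude),
            steepness > 0, dispersion >= 0)
  if (dropout < 0 || dropout > 1) stop("'dropout' must be in [0, 1]")
  if (shape == "decreasing" && amplitude > 0)
    stop("decreasing shape requires amplitude <= 0")
  if (shape %in% c("increasing", "unimodal") && amplitude < 0)
    stop(shape, " shape requires amplitude >= 0")
  spec <- structure(list(gene_id = as.character(gene_id), shape = shape,
                         baseline = baseline, amplitude = amplitude,
                         inflection = inflection, steepness = steepness,
                         dropout = dropout, dispersion = dispersion),
                    class = "gene_trend_spec")
  # noiseless expectation must be a valid CPM everywhere on [0, 1]
  mu <- trend_mean(spec, seq(0, 1, length.out = 101))
  if (any(mu < -1e-9))
    stop("spec implies a negative expected CPM along the trajectory")
  spec
}

# expected (noiseless) CPM of a trend spec at pseudotimes t in [0, 1]
trend_mean <- function(spec, t) {
  switch(spec$shape,
    constant   = rep(spec$baseline, length(t)),
    increasing = ,
    decreasing = spec$baseline + spec$amplitude /
      (1 + exp(-(t - spec$inflection) / spec$steepness)),
    unimodal   = spec$baseline + spec$amplitude *
      exp(-(t - spec$inflection)^2 / (2 * spec$steepness^2))
  )
}

#' Simulate a pseudotime-ordered expression profile
#'
#' Generates a cells x genes CPM matrix whose genes follow the expected
#' curves of the supplied trend specifications, with multiplicative
#' log-normal noise and Bernoulli dropout per gene. Pseudotime is evenly
#' spaced on [0, 1] and strictly increasing over cells. With
#' `dispersion = 0` and `dropout = 0` each gene equals its expected curve
#' exactly.
#'
#' @param specs list of [gene_trend_spec()] objects (nonempty).
#' @param n_cells number of cells (>= 2).
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return an [expression_profile()] with pseudotime.
#' @examples
#' sp <- list(gene_trend_spec("Gapdh", "constant", baseline = 10))
#' simulate_trajectory(sp, n_cells = 5, seed = 1)
#' @export
simulate_trajectory <- function(specs, n_cells, seed = 1L) {
  if (!is.list(specs) || length(specs) == 0L)
    stop("'specs' must be a nonempty list of gene_trend_spec objects")
  if (!all(vapply(specs, inherits, logical(1), "gene_trend_spec")))
    stop("'specs' must contain gene_trend_spec objects")
  if (!is.numeric(n_cells) || n_cells < 2)
    stop("'n_cells' must be at least 2")
  n_cells <- as.integer(n_cells)
  set.seed(as.integer(seed))
  t <- seq(0, 1, length.out = n_cells)
  cpm <- matrix(0, n_cells, length(specs))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    mu <- pmax(trend_mean(sp, t), 0)
    x <- mu
    if (sp$dispersion > 0)
      x <- mu * exp(stats::rnorm(n_cells, -sp$dispersion^2 / 2, sp$dispersion))
    if (sp$dropout > 0)
      x[stats::runif(n_cells) < sp$dropout] <- 0
    cpm[, j] <- x
  }
  colnames(cpm) <- vapply(specs, `[[`, character(1), "gene_id")
  rownames(cpm) <- sprintf("cell_%03d", seq_len(n_cells))
  expression_profile(cpm, pseudotime = t)
}

#' Specification of a cumulative-labeling simulation
#'
#' Forward model for a cumulative S-phase labeling (EdU) experiment on an
#' asynchronously cycling population: the labeling index rises linearly,
#' `LI(t) = GF * (Ts + t) / Tc`, until it plateaus at the growth fraction GF
#' once every cycling cell has passed through S phase (at `t = Tc - Ts`).
#'
#' @param GF growth fraction, percent in (0, 100].
#' @param Tc cell-cycle length in hours (> 0).
#' @param Ts S-phase length in hours (0 <= Ts <= Tc).
#' @param sample_times hours at which samples are taken (sorted ascending,
#'   all >= 0).
#' @param cells_per_sample cells scored per sample; `Inf` is the noiseless
#'   sentinel under which the theoretical curve is returned exactly.
#' @param replicates replicate samples per timepoint (default 2, matching a
#'   duplicate in vitro design).
#' @return an object of class `"kinetics_sim_spec"`.
#' @export
kinetics_sim_spec <- function(GF, Tc, Ts,
                              sample_times = seq(2, 24, by = 2),
                              cells_per_sample = 200, replicates = 2) {
  stopifnot(is.numeric(GF), is.numeric(Tc), is.numeric(Ts))
  if (GF <= 0 || GF > 100) stop("'GF' must be in (0, 100]")
  if (Tc <= 0) stop("'Tc' must be positive")
  if (Ts < 0 || Ts > Tc) stop("'Ts' must satisfy 0 <= Ts <= Tc")
  if (length(sample_times) == 0L) stop("'sample_times' must be nonempty")
  if (any(sample_times < 0)) stop("'sample_times' must be nonnegative")
  if (is.unsorted(sample_times)) stop("'sample_times' must be ascending")
  if (!identical(cells_per_sample, Inf) &&
      (cells_per_sample < 1 || cells_per_sample != round(cells_per_sample)))
    stop("'cells_per_sample' must be a positive integer or Inf")
  if (replicates < 1) stop("'replicates' must be positive")
  structure(list(GF = GF, Tc = Tc, Ts = Ts, sample_times = sample_times,
                 cells_per_sample = cells_per_sample,
                 replicates = as.integer(replicates)),
            class = "kinetics_sim_spec")
}

#' Simulate a cumulative-labeling timecourse
#'
#' Draws labeled-cell counts `Binomial(cells_per_sample, LI(t)/100)` per
#' (timepoint, replicate) from the theoretical labeling curve of the
#' specification. With `cells_per_sample = Inf` the expectation is returned
#' exactly (noiseless mode).
#'
#' @param spec a [kinetics_sim_spec()].
#' @param seed integer RNG seed (unused in noiseless mode).
#' @return a [labeling_timecourse()] data frame with columns
#'   `time_h`, `labeled`, `total`, `replicate`, `li_percent`.
#' @examples
#' simulate_labeling(kinetics_sim_spec(16.257, 26.508, 13.038,
#'                                     cells_per_sample = Inf))
#' @export
simulate_labeling <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "kinetics_sim_spec"))
  k <- cycle_kinetics(GF = spec$GF, Tc = spec$Tc, Ts = spec$Ts)
  li <- forward_model(k, spec$sample_times)
  tt <- rep(spec$sample_times, each = spec$replicates)
  li_rep <- rep(li, each = spec$replicates)
  rep_id <- rep(seq_len(spec$replicates), times = length(spec$sample_times))
  if (identical(spec$cells_per_sample, Inf)) {
    df <- data.frame(time_h = tt, labeled = NA_real_, total = NA_real_,
                     replicate = rep_id, li_percent = li_rep)
  } else {
    set.seed(as.integer(seed))
    lab <- stats::rbinom(length(tt), spec$cells_per_sample, li_rep / 100)
    df <- data.frame(time_h = tt, labeled = lab,
                     total = spec$cells_per_sample, replicate = rep_id,
                     li_percent = 100 * lab / spec$cells_per_sample)
  }
  labeling_timecourse(df)
}

#' Specification of a two-subpopulation cycling simulation
#'
#' Generates the fixture behind cycling-versus-marker-positivity analyses:
#' two groups of cells (positive and negative for a marker gene such as
#' H2-K1) with different cycling probabilities. Cycling cells express one
#' phase's cell-cycle markers (G1/S or G2/M, chosen at random per cell) at
#' `cycling_marker_mean` CPM; noncycling cells express all phase markers at
#' `noncycling_marker_mean`. The defaults reproduce the observed study
#' condition: 18 marker-positive cells of which 1/18 cycle, 82 negative
#' cells of which 20/82 cycle.
#'
#' @param n_pos,n_neg cell counts per positivity group (positive integers).
#' @param cycling_frac_pos,cycling_frac_neg cycling probabilities in [0, 1].
#' @param pos_gene marker gene whose expression defines the groups.
#' @param pos_gene_mean mean CPM of `pos_gene` in the positive group (it is
#'   0 in the negative group).
#' @param g1s_genes,g2m_genes phase marker gene identifiers.
#' @param cycling_marker_mean,noncycling_marker_mean mean CPM of phase
#'   markers in cycling (active phase) vs noncycling cells.
#' @param dispersion multiplicative log-normal noise scale on all CPM values.
#' @return an object of class `"population_sim_spec"`.
#' @export
population_sim_spec <- function(n_pos = 18, n_neg = 82,
                                cycling_frac_pos = 1 / 18,
                                cycling_frac_neg = 20 / 82,
                                pos_gene = "H2-K1", pos_gene_mean = 50,
                                g1s_genes = paste0("g1s_", 1:5),
                                g2m_genes = paste0("g2m_", 1:5),
                                cycling_marker_mean = 40,
                                noncycling_marker_mean = 2,
                                dispersion = 0.2) {
  if (n_pos < 1 || n_neg < 1) stop("group cell counts must be positive")
  for (p in c(cycling_frac_pos, cycling_frac_neg))
    if (p < 0 || p > 1) stop("cycling fractions must be in [0, 1]")
  stopifnot(pos_gene_mean >= 0, cycling_marker_mean >= 0,
            noncycling_marker_mean >= 0, dispersion >= 0,
            length(g1s_genes) >= 1, length(g2m_genes) >= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 cycling_frac_pos = cycling_frac_pos,
                 cycling_frac_neg = cycling_frac_neg,
                 pos_gene = pos_gene, pos_gene_mean = pos_gene_mean,
                 g1s_genes = as.character(g1s_genes),
                 g2m_genes = as.character(g2m_genes),
                 cycling_marker_mean = cycling_marker_mean,
                 noncycling_marker_mean = noncycling_marker_mean,
                 dispersion = dispersion),
            class = "population_sim_spec")
}

#' Simulate a cycling/noncycling cell population
#'
#' @param spec a [population_sim_spec()].
#' @param seed integer RNG seed.
#' @return a list with elements `profile` (an [expression_profile()] without
#'   pseudotime) and `cycling` (named logical vector, the ground-truth
#'   cycling indicator per cell).
#' @examples
#' sim <- simulate_cycling_population(population_sim_spec(), seed = 1)
#' table(positive = sim$profile$cpm[, "H2-K1"] > 0, cycling = sim$cycling)
#' @export
simulate_cycling_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_sim_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_pos + spec$n_neg
  positive <- rep(c(TRUE, FALSE), c(spec$n_pos, spec$n_neg))
  cycling <- stats::runif(n) <
    ifelse(positive, spec$cycling_frac_pos, spec$cycling_frac_neg)
  # cycling cells occupy one phase; its markers are elevated
  in_g2m <- stats::runif(n) < 0.5
  genes <- c(spec$pos_gene, spec$g1s_genes, spec$g2m_genes)
  mu <- matrix(spec$noncycling_marker_mean, n, length(genes),
               dimnames = list(sprintf("cell_%04d", seq_len(n)), genes))
  mu[, spec$pos_gene] <- ifelse(positive, spec$pos_gene_mean, 0)
  mu[cycling & !in_g2m, spec$g1s_genes] <- spec$cycling_marker_mean
  mu[cycling & in_g2m, spec$g2m_genes] <- spec$cycling_marker_mean
  cpm <- mu
  if (spec$dispersion > 0) {
    noise <- exp(stats::rnorm(length(mu), -spec$dispersion^2 / 2,
                              spec$dispersion))
    cpm <- mu * matrix(noise, n, length(genes))
  }
  profile <- expression_profile(cpm)
  names(cycling) <- profile$cell_ids
  list(profile = profile, cycling = cycling)
}
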