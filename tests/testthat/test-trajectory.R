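test_that("relative expression is the max-scaled log2(CPM+1)", {
  p <- make_profile(matrix(c(0, 1, 3), 3, 1, dimnames = list(NULL, "g")))
  expect_equal(unname(relative_expression(p, "g")), c(0, 0.5, 1))
  # all-zero gene: 0/0 convention gives the all-zero vector
  pz <- make_profile(matrix(0, 4, 1, dimnames = list(NULL, "z")))
  expect_equal(unname(relative_expression(pz, "z")), rep(0, 4))
  expect_error(relative_expression(p, "nope"), "unknown gene")
})

test_that("relative expression stays in [0,1] with max exactly 1", {
  set.seed(42)
  for (i in 1:20) {
    cpm <- matrix(rexp(60, 1 / 50), 20, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
    cpm[sample(60, 15)] <- 0
    p <- make_profile(cpm)
    for (g in c("a", "b", "c")) {
      r <- relative_expression(p, g)
      expect_true(all(r >= 0 & r <= 1))
      if (any(cpm[, g] > 0)) expect_equal(max(r), 1)
    }
  }
})

test_that("loess trend reproduces constants and monotone curves", {
  t <- seq(0, 1, length.out = 60)
  # constant relative expression c: fitted == c everywhere
  pc <- make_profile(matrix(7, 60, 1, dimnames = list(NULL, "g")),
                     pseudotime = t)
  fc <- fit_trend(pc, "g")
  expect_true(all(abs(fc$fitted - 1) < 1e-6))  # rel. expr. of constant is 1
  expect_true(all(fc$ci_low <= fc$fitted & fc$fitted <= fc$ci_high))
  expect_true(all(diff(fc$grid) > 0))
  # noiseless increasing sigmoid: fitted nondecreasing up to tolerance
  sp <- list(gene_trend_spec("g", "increasing", baseline = 1,
                             amplitude = 80, inflection = 0.5))
  ps <- simulate_trajectory(sp, 100, seed = 1)
  fs <- fit_trend(ps, "g", span = 0.5)
  expect_true(all(diff(fs$fitted) > -1e-3))
})

test_that("span near 1 on linear data approaches the global OLS slope", {
  t <- seq(0, 1, length.out = 50)
  cpm <- matrix(2^(3 * t) - 1, 50, 1, dimnames = list(NULL, "g"))
  p <- make_profile(cpm, pseudotime = t)  # log2(cpm+1) linear in t
  f <- fit_trend(p, "g", span = 1)
  ols <- coef(lm(relative_expression(p, "g") ~ t))[2]
  slope_hat <- (f$fitted[200] - f$fitted[1]) / (f$grid[200] - f$grid[1])
  expect_equal(unname(slope_hat), unname(ols), tolerance = 1e-6)
})

test_that("trend fitting validates its inputs", {
  t <- seq(0, 1, length.out = 5)
  p <- make_profile(matrix(1, 5, 1, dimnames = list(NULL, "g")),
                    pseudotime = t)
  expect_error(fit_trend(p, "g"), "at least 10 cells")
  p2 <- make_profile(matrix(1, 20, 1, dimnames = list(NULL, "g")),
                     pseudotime = rep(0.5, 20))
  expect_error(fit_trend(p2, "g"), "degenerate pseudotime")
  p3 <- make_profile(matrix(1, 20, 1, dimnames = list(NULL, "g")),
                     pseudotime = seq(0, 1, length.out = 20))
  expect_error(fit_trend(p3, "g", span = 0), "span")
  expect_error(fit_trend(p3, "g", n_grid = 10), "n_grid")
})

test_that("stage cutoff finds the rightmost pre-rise stationary point", {
  g <- seq(0, 1, length.out = 200)
  step <- g[2] - g[1]
  # quadratic with minimum at 0.6
  cut_q <- stage_cutoff(trend_fit("q", g, (g - 0.6)^2))
  expect_lt(abs(cut_q$cutoff - 0.6), step + 1e-12)
  # strictly increasing line: explicit no-cutoff error
  expect_error(stage_cutoff(trend_fit("l", g, 2 * g)), "no-cutoff")
  # two minima (0.3 and 0.7) then rising: rightmost wins
  antider <- function(t) t^4 / 4 - 1.5 * t^3 / 3 + 0.71 * t^2 / 2 - 0.105 * t
  cut_w <- stage_cutoff(trend_fit("w", g, antider(g)))
  expect_lt(abs(cut_w$cutoff - 0.7), step + 1e-12)
})

test_that("stage cutoff recovers unimodal turning points within a grid step", {
  # dip-shaped trends: the minimum precedes the final rise
  for (n_grid in c(100, 200)) {
    for (dip in c(0.3, 0.55, 0.8)) {
      g <- seq(0, 1, length.out = n_grid)
      cut <- stage_cutoff(trend_fit("d", g, (g - dip)^2))
      expect_lt(abs(cut$cutoff - dip), (g[2] - g[1]) + 1e-12)
    }
  }
  # peak-shaped trends that rise from the start and end flat: the last
  # sign change (the peak) is the cutoff
  for (n_grid in c(100, 200)) {
    for (par in list(c(0.3, 0.1), c(0.35, 0.12), c(0.45, 0.13))) {
      g <- seq(0, 1, length.out = n_grid)
      f <- 0.1 + 0.8 * exp(-(g - par[1])^2 / (2 * par[2]^2))
      cut <- stage_cutoff(trend_fit("u", g, f))
      expect_lt(abs(cut$cutoff - par[1]), (g[2] - g[1]) + 1e-12)
    }
  }
})

test_that("stage labels follow the <= convention and cover all cells", {
  t <- seq(0, 1, length.out = 41)  # includes t = 0.6 exactly
  cpm <- matrix(2^(5 * (t - 0.6)^2) - 1, 41, 1, dimnames = list(NULL, "g"))
  p <- make_profile(cpm, pseudotime = t)
  cut <- stage_cutoff(fit_trend(p, "g", span = 0.6))
  expect_s3_class(cut, "stage_cut")
  expect_equal(length(cut$stage_of_cell), 41)
  expect_true(all(cut$stage_of_cell[p$pseudotime <= cut$cutoff] == "T1"))
  expect_true(all(cut$stage_of_cell[p$pseudotime > cut$cutoff] == "T2"))
})

test_that("positive-by-stage tables match brute-force counts", {
  set.seed(5)
  t <- seq(0, 1, length.out = 100)
  cpm <- matrix(rexp(100, 1 / 20) * (runif(100) > 0.4), 100, 1,
                dimnames = list(NULL, "g"))
  p <- make_profile(cpm, pseudotime = t)
  tab <- count_positive_by_stage(p, "g", cut = 0.37)
  expect_equal(tab["T1", "positive"], sum(t <= 0.37 & cpm > 0))
  expect_equal(tab["T2", "negative"], sum(t > 0.37 & cpm == 0))
  expect_equal(rowSums(tab), c(T1 = sum(t <= 0.37), T2 = sum(t > 0.37)))
  # threshold at the max: nobody is positive
  tmax <- count_positive_by_stage(p, "g", 0.37,
                                  positivity_threshold = max(cpm))
  expect_equal(unname(tmax[, "positive"]), c(0L, 0L))
  # all positive, 30/70 split
  pall <- make_profile(matrix(5, 100, 1, dimnames = list(NULL, "g")),
                       pseudotime = t)
  t30 <- count_positive_by_stage(pall, "g", t[30])
  expect_equal(unname(t30), matrix(c(30L, 70L, 0L, 0L), 2, 2),
               ignore_attr = TRUE)
})

test_that("fisher p-values match enumeration and fisher.test", {
  # exhaustive check over all small tables
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    if (a + b + c + d == 0) next
    tab <- matrix(c(a, c, b, d), 2, 2)
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(a, b, c, d),
                 tolerance = 1e-12)
  }
  # spot checks against the stats implementation on larger random tables
  set.seed(1)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 15), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("odds ratio follows the cross-product conventions", {
  expect_equal(round(odds_ratio(matrix(c(1, 20, 17, 62), 2, 2)), 2), 0.18)
  sym <- fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  expect_equal(odds_ratio(matrix(c(3, 0, 0, 7), 2, 2)), Inf)
  expect_equal(odds_ratio(matrix(c(0, 3, 7, 0), 2, 2)), 0)
  expect_equal(odds_ratio(matrix(c(0, 3, 0, 0), 2, 2)), 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
})

test_that("odds ratio symmetry under table rearrangements", {
  set.seed(2)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    or <- odds_ratio(tab)
    expect_equal(odds_ratio(t(tab)), or)
    expect_equal(odds_ratio(tab[2:1, 2:1]), or)
    expect_equal(odds_ratio(tab[2:1, ]), 1 / or)
  }
})
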