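test_that("summed-marker scores match hand arithmetic and are median-1", {
  cpm <- matrix(c(0, 3, 7,   # marker a (G1/S)
                  0, 1, 1,   # marker b (G1/S)
                  2, 2, 2),  # marker c (G2/M)
                3, 3, dimnames = list(paste0("c", 1:3), c("a", "b", "c")))
  p <- make_profile(cpm)
  sc <- score_cell_cycle(p, marker_set(c("a", "b"), "c"), transform = "cpm")
  expect_equal(sc$raw_g1s, c(0, 4, 8))
  expect_equal(sc$norm_g1s, c(0, 1, 2))  # median 4
  expect_equal(sc$norm_g2m, c(1, 1, 1))
  # median of the normalized score is 1 whenever the raw median is positive
  expect_equal(median(sc$norm_g1s), 1, tolerance = 1e-9)
})

test_that("identical cells all score 1; G2/M sum is linear in CPM", {
  cpm <- matrix(5, 4, 3, dimnames = list(paste0("c", 1:4),
                                         c("a", "b", "c")))
  p <- make_profile(cpm)
  sc <- score_cell_cycle(p, marker_set("a", c("b", "c")))
  expect_true(all(sc$norm_g1s == 1) && all(sc$norm_g2m == 1))
  # doubling one cell's CPM at every G2/M marker doubles its raw score
  cpm2 <- cpm
  cpm2["c2", c("b", "c")] <- 10
  sc2 <- score_cell_cycle(make_profile(cpm2), marker_set("a", c("b", "c")),
                          transform = "cpm")
  expect_equal(sc2$raw_g2m[2], 2 * sum(cpm[2, c("b", "c")]))
})

test_that("scores ignore marker order, absent markers warn, all-zero added marker is neutral", {
  set.seed(3)
  cpm <- matrix(rexp(40, 1 / 10), 10, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  cpm <- cbind(cpm, zero = 0)
  p <- make_profile(cpm)
  s1 <- score_cell_cycle(p, marker_set(c("a", "b"), c("c", "d")))
  s2 <- score_cell_cycle(p, marker_set(c("b", "a"), c("d", "c")))
  expect_equal(s1$norm_g1s, s2$norm_g1s)
  expect_equal(s1$norm_g2m, s2$norm_g2m)
  # adding an all-zero marker leaves scores unchanged
  s3 <- score_cell_cycle(p, marker_set(c("a", "b", "zero"), c("c", "d")))
  expect_equal(s3$raw_g1s, s1$raw_g1s)
  # absent markers are dropped with a warning; all-absent is an error
  expect_warning(s4 <- score_cell_cycle(p, marker_set(c("a", "missing"),
                                                      c("c", "d"))),
                 "dropped")
  expect_equal(s4$raw_g1s, rowSums(log2(cpm[, "a", drop = FALSE] + 1)),
               ignore_attr = TRUE)
  expect_error(score_cell_cycle(p, marker_set("nope", c("c", "d"))),
               "no G1/S marker genes")
})

test_that("median normalization is idempotent", {
  # a profile whose raw G1/S scores already have median 1 (cpm transform)
  cpm <- matrix(c(0.2, 0.5, 1, 1.4, 1.8,
                  1, 1, 1, 1, 1), 5, 2,
                dimnames = list(paste0("c", 1:5), c("a", "b")))
  sc <- score_cell_cycle(make_profile(cpm), marker_set("a", "b"),
                         transform = "cpm")
  expect_equal(sc$norm_g1s, sc$raw_g1s)  # dividing by median 1 changes nothing
})

test_that("cycling classification follows the max-score threshold rule", {
  cpm <- matrix(c(1, 1, 8, 1,
                  1, 1, 1, 9), 4, 2,
                dimnames = list(paste0("c", 1:4), c("a", "b")))
  sc <- score_cell_cycle(make_profile(cpm), marker_set("a", "b"),
                         transform = "cpm")
  calls <- classify_cycling(sc)
  expect_equal(unname(as.logical(calls)), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(calls, "threshold"), 2)
  # an unreachable threshold calls nobody
  expect_equal(sum(classify_cycling(sc, threshold = 1e6)), 0)
  # an all-identical population has every normalized score 1
  flat <- score_cell_cycle(make_profile(matrix(5, 4, 2,
                             dimnames = list(NULL, c("a", "b")))),
                           marker_set("a", "b"))
  expect_equal(sum(classify_cycling(flat)), 0)
  expect_error(classify_cycling(sc, threshold = 0), "positive")
})

test_that("well-separated simulated populations are classified accurately", {
  spec <- population_sim_spec(n_pos = 200, n_neg = 800,
                              cycling_marker_mean = 40,
                              noncycling_marker_mean = 5,   # 8x separation
                              dispersion = 0.2)
  sim <- simulate_cycling_population(spec, seed = 21)
  sc <- score_cell_cycle(sim$profile,
                         marker_set(spec$g1s_genes, spec$g2m_genes),
                         transform = "cpm")
  calls <- classify_cycling(sc)
  acc <- mean(as.logical(calls) == sim$cycling[names(calls)])
  expect_gte(acc, 0.99)
})

test_that("positivity cross-tabulation matches manual counts", {
  cpm <- matrix(c(5, 5, 0, 0, 5, 0,    # gene "H2-K1"
                  9, 1, 9, 1, 1, 1,    # g1s marker
                  1, 1, 1, 1, 1, 1),   # g2m marker
                6, 3, dimnames = list(paste0("c", 1:6),
                                      c("H2-K1", "a", "b")))
  p <- make_profile(cpm)
  sc <- score_cell_cycle(p, marker_set("a", "b"), transform = "cpm")
  calls <- classify_cycling(sc)  # cycling: cells with g1s = 9 (norm 9/5)
  tab <- tabulate_by_positivity(calls, p, "H2-K1")
  manual_cyc <- cpm[, "a"] == 9  # norm score 9 vs median 1
  pos <- cpm[, "H2-K1"] > 0
  expect_equal(unname(tab), matrix(c(sum(pos & manual_cyc),
                                     sum(!pos & manual_cyc),
                                     sum(pos & !manual_cyc),
                                     sum(!pos & !manual_cyc)), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(tab), 6L)
  # no positive cells: first row all zero
  pneg <- make_profile(cbind(cpm[, c("a", "b")], `H2-K1` = 0))
  tab0 <- tabulate_by_positivity(calls, pneg, "H2-K1")
  expect_equal(unname(tab0["positive", ]), c(0, 0), ignore_attr = TRUE)
  expect_error(tabulate_by_positivity(calls, p, "nope"), "unknown gene")
})

test_that("the published cycling table reproduces its printed statistics", {
  tab <- matrix(c(1, 20, 17, 62), 2, 2,
                dimnames = list(c("positive", "negative"),
                                c("cycling", "noncycling")))
  pct <- percent_cycling(tab)
  expect_identical(unname(pct), c(5.6, 24.4))
  expect_equal(round(odds_ratio(tab), 2), 0.18)
})

test_that("percent cycling rounds half away from zero and keeps NA rows", {
  expect_equal(unname(percent_cycling(matrix(c(0, 1, 10, 1), 2, 2))),
               c(0, 50))
  # 0.25 -> 0.3 under half-away-from-zero at one decimal
  expect_equal(unname(percent_cycling(matrix(c(1, 1, 399, 1), 2, 2))[1]),
               0.3)
  empty <- percent_cycling(matrix(c(0, 1, 0, 1), 2, 2))
  expect_true(is.na(empty[1]))
  expect_equal(unname(empty[2]), 50)
})

test_that("odds ratio worked examples", {
  expect_equal(odds_ratio(matrix(c(2, 5, 8, 5), 2, 2)), 0.25)
  expect_equal(odds_ratio(matrix(c(3, 3, 11, 11), 2, 2)), 1)
})

test_that("bundled marker lists load and JSON markers round-trip", {
  mk <- default_markers()
  expect_s3_class(mk, "marker_set")
  expect_gt(length(mk$g1s_genes), 30)
  expect_gt(length(mk$g2m_genes), 40)
  expect_true("Mki67" %in% mk$g2m_genes)
  expect_true("Pcna" %in% mk$g1s_genes)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(g1s = c("a", "b"), g2m = "c"), js)
  mk2 <- read_markers(js)
  expect_equal(mk2$g1s_genes, c("a", "b"))
  expect_error(read_markers("/no/such/file.txt", "/none.txt"), "not found")
})
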