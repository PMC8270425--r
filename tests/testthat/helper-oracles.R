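# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates tables with choose()
# arithmetic, and the segmented-fit oracle refits every admissible split
# with lm().

# two-sided probability-mass Fisher p by exhaustive enumeration over all
# tables sharing the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  prob <- choose(c1, ks) * choose(N - c1, r1 - ks) / choose(N, r1)
  p_obs <- prob[ks == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# brute-force two-segment fit: every admissible breakpoint, rise via lm(),
# plateau via mean
oracle_two_segment <- function(time_h, li, min_rise = 3, min_plateau = 2) {
  times <- sort(unique(time_h))
  cands <- (times[-length(times)] + times[-1]) / 2
  best <- NULL
  for (bp in cands) {
    rise <- time_h <= bp
    if (sum(rise) < min_rise || sum(!rise) < min_plateau) next
    fit <- lm(li[rise] ~ time_h[rise])
    plateau <- mean(li[!rise])
    sse <- sum(residuals(fit)^2) + sum((li[!rise] - plateau)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(bp = bp, b = unname(coef(fit)[1]),
                   m = unname(coef(fit)[2]), GF = plateau, sse = sse)
  }
  best
}

# minimal profile builder for hand fixtures
make_profile <- function(cpm, pseudotime = NULL) {
  if (is.null(rownames(cpm)))
    rownames(cpm) <- paste0("c", seq_len(nrow(cpm)))
  expression_profile(cpm, pseudotime = pseudotime)
}
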