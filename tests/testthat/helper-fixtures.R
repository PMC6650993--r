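# Shared small fixtures built in code.

# straight-tube voxel labels for segment tests: a synthetic skeleton along z
# with a hand-built tube volume
straight_skeleton <- function(length_mm = 100, n_samples = 201) {
  arc <- seq(0, length_mm, length.out = n_samples)
  structure(list(curve = cbind(0, 0, arc), arc = arc,
                 arc_length = length_mm,
                 voxel_path = NULL, clip_bounds = c(0, length_mm)),
            class = "skeleton")
}

# participant data with an exact sample correlation r against x
vectors_with_correlation <- function(r, n, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1 <- scale(z1)[, 1]
  e <- stats::residuals(lm(z2 ~ z1))
  e <- scale(e)[, 1]
  list(x = z1, y = r * z1 + sqrt(1 - r^2) * e)
}

# closed-form correlation Bayes factor (independent oracle: hypergeometric
# representation instead of numerical integration)
bf10_closed_form <- function(r, n, kappa = 1) {
  f21 <- function(a, b, cc, z) {          # plain power series, |z| < 1
    term <- 1; s <- 1
    for (k in 0:100000) {
      term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
      s <- s + term
      if (abs(term) < 1e-14 * abs(s)) break
    }
    s
  }
  h <- f21((n - 1) / 2, (n - 1) / 2, (n + 2 / kappa) / 2, r^2)
  2^(1 - 2 / kappa) * sqrt(pi) / beta(1 / kappa, 1 / kappa) *
    exp(lgamma((n + 2 / kappa - 1) / 2) - lgamma((n + 2 / kappa) / 2)) * h
}
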