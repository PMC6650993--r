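#' Linear ballistic accumulator parameters for a single accumulator
#'
#' In a simple reaction-time task there is only one possible response, so the
#' decision stage is modelled by a single linear ballistic accumulator:
#' evidence grows linearly from a start point drawn uniformly on `(0, a)`
#' towards a threshold `b`, at a drift rate drawn once per trial from a
#' truncated normal with mean `mu` and standard deviation `sigma` (truncated
#' at zero so every trial terminates). The predicted reaction time is the
#' accumulation duration plus a constant non-decision time `t_er` that
#' absorbs stimulus encoding and motor initiation.
#'
#' @param t_er Non-decision time in seconds (> 0).
#' @param b Decision threshold (> `a`).
#' @param mu Mean drift rate (evidence/s).
#' @param sigma Trial-to-trial drift-rate standard deviation (>= 0).
#' @param a Start-point range; fixed at 0.5 as the model's scaling constant
#'   unless explicitly overridden.
#' @return An object of class `lba_params`.
#' @export
#' @examples
#' p <- lba_params(t_er = 0.25, b = 1, mu = 3, sigma = 1)
#' rt <- simulate_lba(p, 1000, seed = 1)
#' mean(rt)
lba_params <- function(t_er, b, mu, sigma, a = 0.5) {
  stopifnot(is.numeric(t_er), is.numeric(b), is.numeric(mu), is.numeric(sigma))
  if (t_er <= 0) stop("t_er must be > 0")
  if (b <= a) stop("threshold b must exceed the start-point range a")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(t_er = t_er, b = b, mu = mu, sigma = sigma, a = a),
            class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat(sprintf(
    "LBA parameters: t_er = %.4g s, b = %.4g, mu = %.4g, sigma = %.4g (a = %g)\n",
    x$t_er, x$b, x$mu, x$sigma, x$a))
  invisible(x)
}

#' Exclude implausibly fast or slow reaction times
#'
#' Trials with RT below `lo` or above `hi` milliseconds are removed; the
#' bounds themselves are retained (the exclusion rule is strict in both
#' directions). Counts of removed trials are recorded.
#'
#' @param rts Numeric vector of reaction times in milliseconds.
#' @param lo,hi Retention bounds in milliseconds (default 150 and 1500).
#' @return An object of class `rt_sample` with elements `rts` (retained
#'   values, ms), `n_excluded_low` and `n_excluded_high`.
#' @export
exclude_rts <- function(rts, lo = 150, hi = 1500) {
  stopifnot(length(rts) > 0, lo < hi)
  keep <- rts >= lo & rts <= hi
  out <- list(rts = rts[keep],
              n_excluded_low = sum(rts < lo),
              n_excluded_high = sum(rts > hi))
  if (length(out$rts) == 0L)
    stop("all trials excluded by the RT bounds [", lo, ", ", hi, "] ms")
  structure(out, class = "rt_sample")
}

## Inverse-CDF draw from a normal truncated to (0, Inf)
rtnorm_pos <- function(u, mu, sigma) {
  if (sigma == 0) {
    if (mu <= 0) stop("mu <= 0 with sigma = 0: the accumulator never finishes")
    return(rep(mu, length(u)))
  }
  plo <- pnorm(0, mu, sigma)
  if (plo >= 1 - 1e-14)
    stop("drift distribution has essentially no mass above zero")
  qnorm(plo + u * (1 - plo), mu, sigma)
}

#' Simulate reaction times from the single-accumulator LBA
#'
#' Each trial draws a start point `k ~ Uniform(0, a)` and a drift rate from
#' `Normal(mu, sigma)` truncated to positive values, and returns
#' `t_er + (b - k) / v` in seconds.
#'
#' @param params An [lba_params] object.
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed; the draw is reproducible given the seed
#'   and leaves the global RNG state untouched.
#' @param u Optional list with components `u1`, `u2` of pre-drawn uniforms
#'   (common random numbers); overrides `seed`.
#' @return Numeric vector of RTs in seconds, all strictly greater than `t_er`.
#' @export
simulate_lba <- function(params, n_trials, seed = NULL, u = NULL) {
  stopifnot(inherits(params, "lba_params"), n_trials >= 1)
  if (is.null(u)) {
    u <- with_seed(seed, list(u1 = runif(n_trials), u2 = runif(n_trials)))
  }
  k <- params$a * u$u1
  v <- rtnorm_pos(u$u2, params$mu, params$sigma)
  params$t_er + (params$b - k) / v
}

#' Closed-form distribution function of the single-accumulator LBA
#'
#' Under the positive-truncation convention for drift rates the finishing-time
#' distribution is proper, and for decision time `s = t - t_er`:
#' `F(t) = F_raw(s) / Phi(mu/sigma)` where `F_raw` is the classic untruncated
#' single-accumulator expression. Used as the analytic oracle for the
#' simulator and as a fast alternative for model bin probabilities.
#'
#' @param t Time(s) in seconds; vectorized.
#' @param params An [lba_params] object.
#' @return Probabilities in `[0, 1]`; 0 for `t <= t_er`.
#' @export
lba_cdf <- function(t, params) {
  stopifnot(inherits(params, "lba_params"))
  t_er <- params$t_er; b <- params$b; a <- params$a
  mu <- params$mu; sigma <- params$sigma
  s <- t - t_er
  out <- numeric(length(t))
  pos <- which(s > 0)
  if (!length(pos)) return(out)
  s <- s[pos]
  if (sigma == 0) {
    if (mu <= 0) stop("mu <= 0 with sigma = 0: degenerate model")
    # k >= b - mu*s, k ~ U(0, a)
    f <- if (a > 0) pmin(pmax((a - (b - mu * s)) / a, 0), 1) else
      as.numeric(s >= b / mu)
    out[pos] <- f
    return(out)
  }
  z_norm <- pnorm(mu / sigma)
  if (a < 1e-9) {
    f <- pnorm((mu - b / s) / sigma) / z_norm
  } else {
    z1 <- (b - a - s * mu) / (s * sigma)
    z2 <- (b - s * mu) / (s * sigma)
    f_raw <- 1 + ((b - a - s * mu) / a) * pnorm(z1) -
      ((b - s * mu) / a) * pnorm(z2) +
      ((s * sigma) / a) * (dnorm(z1) - dnorm(z2))
    f <- f_raw / z_norm
  }
  out[pos] <- pmin(pmax(f, 0), 1)
  out
}

#' Quantile function of the single-accumulator LBA (numeric inversion)
#'
#' @param p Probabilities in (0, 1); vectorized.
#' @param params An [lba_params] object.
#' @return Times in seconds such that `lba_cdf(t) = p`.
#' @export
lba_quantile <- function(p, params) {
  stopifnot(all(p > 0 & p < 1))
  vapply(p, function(pp) {
    hi <- params$t_er + 1
    while (lba_cdf(hi, params) < pp) hi <- params$t_er + (hi - params$t_er) * 2
    stats::uniroot(function(t) lba_cdf(t, params) - pp,
                   lower = params$t_er, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

#' Empirical RT quantiles
#'
#' Linear-interpolation (type 7) quantiles of a reaction-time vector, the
#' convention used throughout the fitting routine.
#'
#' @param rts Non-empty numeric vector.
#' @param probs Strictly increasing probabilities in (0, 1); default the five
#'   canonical fitting quantiles 0.1, 0.3, 0.5, 0.7, 0.9.
#' @return Numeric vector of quantiles, in the units of `rts`.
#' @export
rt_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(rts) == 0) stop("empty RT vector")
  stopifnot(all(diff(probs) > 0), all(probs > 0 & probs < 1))
  unname(quantile(rts, probs = probs, type = 7, names = FALSE))
}

## Bin counts of `x` in the bins delimited by (-Inf, edges, Inf)
bin_counts <- function(x, edges) {
  tabulate(findInterval(x, edges, left.open = FALSE) + 1L,
           nbins = length(edges) + 1L)
}

#' Likelihood-ratio chi-square between observed and model RT distributions
#'
#' The observed RT distribution is summarized by its quantiles at `probs`
#' (default 0.1/0.3/0.5/0.7/0.9), giving six bins with observed counts in
#' proportions 0.1, 0.2, 0.2, 0.2, 0.2, 0.1 of the sample size. Model bin
#' probabilities are estimated from `n_sim` simulated RTs (or from the
#' closed-form CDF with `method = "cdf"`), floored at `1/(2 n_sim)`, and the
#' statistic is `G^2 = 2 sum_i O_i log(O_i / (N pi_i))`.
#'
#' @param params An [lba_params] object.
#' @param sample An [exclude_rts] result (RTs in ms).
#' @param n_sim Number of model simulations (default 1e5).
#' @param seed Seed for the simulation draw.
#' @param probs Quantile probabilities defining the bin edges.
#' @param u Optional common-random-number list forwarded to [simulate_lba].
#' @param method `"simulation"` (default) or `"cdf"` for closed-form bin
#'   probabilities.
#' @return Non-negative scalar `G^2`.
#' @export
gsq_objective <- function(params, sample, n_sim = 1e5, seed = NULL,
                          probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          u = NULL, method = c("simulation", "cdf")) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "rt_sample"))
  rts_s <- sample$rts / 1000
  n <- length(rts_s)
  q_obs <- rt_quantiles(rts_s, probs)
  if (any(diff(q_obs) <= 0))
    stop("degenerate sample: observed quantiles are not strictly increasing")
  o_prop <- diff(c(0, probs, 1))
  o <- n * o_prop
  if (method == "simulation") {
    sim <- simulate_lba(params, n_sim, seed = seed, u = u)
    pi_hat <- bin_counts(sim, q_obs) / n_sim
  } else {
    cf <- lba_cdf(q_obs, params)
    pi_hat <- diff(c(0, cf, 1))
  }
  pi_hat <- pmax(pi_hat, 1 / (2 * n_sim))
  max(2 * sum(o * log(o / (n * pi_hat))), 0)
}

## log-parameterization used by the optimizer: theta = log(t_er, b - a, mu, sigma)
theta_to_params <- function(theta, a = 0.5) {
  lba_params(t_er = exp(theta[1]), b = a + exp(theta[2]),
             mu = exp(theta[3]), sigma = exp(theta[4]), a = a)
}

## Initial candidates: t_er uniform over its admissible range (log-uniform
## concentrates mass at implausibly small values and, because the quantile
## objective is nearly flat in t_er, the selected optimum inherits that
## downward bias); the scale-like parameters are log-uniform.
draw_candidates <- function(n, min_rt_s, a = 0.5) {
  lunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
  t_hi <- max(min_rt_s, 0.051)
  data.frame(t_er = runif(n, 0.05, t_hi),
             b = pmax(lunif(n, 0.5, 5), a + 1e-6),
             mu = lunif(n, 0.1, 10),
             sigma = lunif(n, 0.05, 3))
}

#' Fit the single-accumulator LBA by quantile likelihood-ratio chi-square
#'
#' Nelder-Mead simplex minimization of [gsq_objective] over
#' `(t_er, b, mu, sigma)` with the start-point range fixed at 0.5. For each of
#' `n_repeats` repetitions, `n_init_candidates` random parameter sets (drawn
#' log-uniform over wide ranges, with `t_er` capped below the minimum observed
#' RT) are scored and the best one seeds the simplex; the best optimum across
#' repetitions is returned. Within a repetition the simulation noise is frozen
#' by common random numbers, so the objective surface the simplex sees is
#' deterministic.
#'
#' @param sample An [exclude_rts] result with at least 25 trials.
#' @param n_init_candidates Random initial sets scored per repetition
#'   (default 100).
#' @param n_repeats Repetitions of the whole procedure (default 20).
#' @param n_sim Simulated trials per objective evaluation (default 1e5).
#' @param seed Master seed (each repetition derives its own stream).
#' @param probs Quantile probabilities for the fit.
#' @param method Bin-probability method, `"simulation"` or `"cdf"`.
#' @param maxit Maximum simplex evaluations per repetition (default 2000).
#' @return An object of class `lba_fit`: `params`, `gsq`, `observed_q` and
#'   `predicted_q` (ms), `n_restarts_used`, `seed`.
#' @export
fit_lba <- function(sample, n_init_candidates = 100, n_repeats = 20,
                    n_sim = 1e5, seed = 1,
                    probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                    method = c("simulation", "cdf"), maxit = 2000) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "rt_sample"))
  if (length(sample$rts) < 25)
    stop("need at least 25 retained trials for stable quantiles")
  min_rt_s <- min(sample$rts) / 1000
  a <- 0.5
  best <- list(gsq = Inf)
  n_used <- 0L
  for (j in seq_len(n_repeats)) {
    seed_j <- substream_seed(seed, "lba", j)
    crn <- with_seed(seed_j, {
      list(u = if (method == "simulation")
             list(u1 = runif(n_sim), u2 = runif(n_sim)) else NULL,
           cand = draw_candidates(n_init_candidates, min_rt_s, a))
    })
    obj <- function(theta) {
      if (any(!is.finite(theta)) || any(abs(theta) > 20)) return(1e10)
      p <- theta_to_params(theta, a)
      if (p$t_er >= min_rt_s) return(1e10)
      gsq_objective(p, sample, n_sim = n_sim, probs = probs,
                    u = crn$u, method = method)
    }
    cand_scores <- apply(crn$cand, 1, function(row) {
      th <- log(c(row[["t_er"]], row[["b"]] - a, row[["mu"]], row[["sigma"]]))
      obj(th)
    })
    k <- which.min(cand_scores)
    th0 <- log(c(crn$cand$t_er[k], crn$cand$b[k] - a,
                 crn$cand$mu[k], crn$cand$sigma[k]))
    fit <- tryCatch(
      optim(th0, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, abstol = 1e-4, reltol = 1e-6)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_used <- n_used + 1L
    if (fit$value < best$gsq) {
      best <- list(gsq = fit$value, theta = fit$par, u = crn$u)
    }
  }
  if (!is.finite(best$gsq))
    stop("optimizer failed on all restarts; best objective = ", best$gsq)
  params <- theta_to_params(best$theta, a)
  q_obs_ms <- rt_quantiles(sample$rts, probs)
  pred_rts <- if (method == "simulation")
    simulate_lba(params, n_sim, u = best$u) else NULL
  q_pred_s <- if (is.null(pred_rts)) lba_quantile(probs, params) else
    rt_quantiles(pred_rts, probs)
  structure(list(params = params, gsq = best$gsq,
                 observed_q = q_obs_ms, predicted_q = q_pred_s * 1000,
                 n_restarts_used = n_used, seed = seed),
            class = "lba_fit")
}

#' @export
print.lba_fit <- function(x, ...) {
  cat(sprintf("LBA fit: t_er = %.1f ms, b = %.3f, mu = %.3f, sigma = %.3f\n",
              x$params$t_er * 1000, x$params$b, x$params$mu, x$params$sigma))
  cat(sprintf("  G^2 = %.4f over %d restarts\n", x$gsq, x$n_restarts_used))
  invisible(x)
}

#' @export
as.list.lba_fit <- function(x, ...) {
  list(t_er_ms = x$params$t_er * 1000, b = x$params$b, mu = x$params$mu,
       sigma = x$params$sigma, gsq = x$gsq,
       observed_q_ms = x$observed_q, predicted_q_ms = x$predicted_q,
       seed = x$seed)
}
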