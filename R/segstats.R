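#' Segment-wise general linear model with a nuisance covariate
#'
#' Ordinary least squares of a segment's metric values on an intercept, the
#' behavioural regressor and age. Returns the standardized coefficient of the
#' regressor (the raw coefficient rescaled by `sd(x)/sd(y)`, i.e. the
#' coefficient obtained after z-scoring outcome and regressor while age stays
#' in the model) and its t statistic.
#'
#' @param y Numeric outcome vector (one value per participant).
#' @param regressor Behavioural variable (e.g. non-decision time in ms).
#' @param nuisance Nuisance covariate (age in years), or `NULL`.
#' @return List with `beta_std` and `t_stat` (t is capped at 1e6 for exact
#'   fits and flagged via attribute `exact_fit`).
#' @export
glm_segment <- function(y, regressor, nuisance = NULL) {
  n <- length(y)
  X <- cbind(1, regressor, nuisance)
  if (n <= ncol(X) + 1) stop("too few participants for the design")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  xtxi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * xtxi[2, 2])
  beta <- fit$coefficients[2]
  exact <- se < 1e-12 * max(abs(beta), 1)
  t_stat <- if (exact) sign(beta) * 1e6 else beta / se
  res <- list(beta_std = unname(beta * sd(regressor) / sd(y)),
              t_stat = unname(t_stat))
  if (exact) attr(res$t_stat, "exact_fit") <- TRUE
  res
}

#' One-dimensional threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over thresholds:
#' `tfce(s) = sum_{h = dh, 2dh, ... <= stat(s)} e(h, s)^E * h^H * dh`, where
#' `e(h, s)` is the length (in segments) of the maximal contiguous run of
#' segments with `stat >= h` containing `s`. Adjacency is segment order;
#' negative entries contribute nothing (compute the enhancement of `-stat`
#' separately for the negative direction).
#'
#' @param stat Numeric vector of segment statistics.
#' @param E Extent exponent (default 0.5).
#' @param H Height exponent (default 2).
#' @param dh Threshold step; default `max(stat)/100`.
#' @return Non-negative vector of enhanced statistics.
#' @export
tfce_1d <- function(stat, E = 0.5, H = 2, dh = NULL) {
  s <- pmax(stat, 0)
  if (all(s == 0)) return(numeric(length(stat)))
  if (is.null(dh)) dh <- max(s) / 100
  if (dh <= 0) stop("dh must be positive")
  tfce1d_cpp(as.numeric(s), E, H, dh)
}

## signed two-direction TFCE of a t map
tfce_signed <- function(t_map, E, H, dh) {
  tfce_1d(t_map, E, H, dh) - tfce_1d(-t_map, E, H, dh)
}

#' Permutation familywise-error control for segment-wise associations
#'
#' For every segment and metric, fits the GLM of the metric on the regressor
#' with age as nuisance, enhances the segment-wise t maps with 1-D TFCE in
#' both directions, and controls the familywise error across all segments,
#' metrics and both signs with a Freedman-Lane max-statistic permutation
#' scheme: the outcome is residualized on the nuisance model, residuals are
#' permuted, the full model is refit, and the maximum enhanced statistic over
#' the whole family is recorded per permutation.
#' `p_fwe = (1 + #\{max_perm >= tfce_obs\}) / (n_perm + 1)`.
#'
#' @param profiles A [build_profiles] result, or a participants x segments x
#'   metrics array.
#' @param regressor Behavioural variable per participant.
#' @param nuisance Nuisance covariate (age), or `NULL` for intercept-only
#'   nuisance.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; permutations are reproducible.
#' @param E,H TFCE exponents (defaults 0.5 and 2).
#' @param dh TFCE step; default `max |t_observed| / 100`, shared by all maps
#'   and permutations.
#' @return An object of class `tfce_result`: matrices `beta_std`, `t_stat`,
#'   `tfce` (signed), `p_fwe` (segments x metrics), plus `n_perm`, `seed`,
#'   `dh`, `max_dist` (the permutation null of the family maximum).
#' @export
permutation_fwe <- function(profiles, regressor, nuisance = NULL,
                            n_perm = 10000, seed = 1, E = 0.5, H = 2,
                            dh = NULL) {
  vals <- if (inherits(profiles, "tract_profile")) profiles$values else profiles
  stopifnot(length(dim(vals)) == 3, n_perm >= 100)
  n <- dim(vals)[1]; n_seg <- dim(vals)[2]; n_met <- dim(vals)[3]
  stopifnot(length(regressor) == n)
  if (var(regressor) == 0) stop("regressor has zero variance")

  Z <- cbind(rep(1, n), nuisance)             # nuisance model (incl. intercept)
  Y <- matrix(vals, nrow = n)                 # n x (n_seg*n_met)
  ok_col <- apply(Y, 2, function(col) !anyNA(col) && var(col) > 0)
  if (anyNA(Y)) {
    # pairwise deletion is delegated to a per-segment slow path
    return(permutation_fwe_missing(vals, regressor, nuisance, n_perm, seed,
                                   E, H, dh))
  }
  qz <- qr.Q(qr(Z))
  resid_z <- function(M) M - qz %*% crossprod(qz, M)
  x_t <- resid_z(matrix(regressor, ncol = 1))
  xx <- sum(x_t^2)
  df <- n - ncol(Z) - 1

  t_of <- function(W) {
    # W: Y residualized on Z (n x k); t statistic of the regressor
    b <- crossprod(x_t, W) / xx
    rss <- colSums(W^2) - as.numeric(b)^2 * xx
    as.numeric(b) / sqrt(pmax(rss, 0) / df / xx)
  }

  W_obs <- resid_z(Y)
  t_obs <- t_of(W_obs)
  t_obs[!ok_col] <- NA
  t_mat <- matrix(t_obs, n_seg, n_met)
  if (is.null(dh)) dh <- max(abs(t_obs), na.rm = TRUE) / 100
  tfce_mat <- apply(t_mat, 2, function(col) {
    col[is.na(col)] <- 0
    tfce_signed(col, E, H, dh)
  })

  ey <- W_obs                                  # Freedman-Lane residuals
  max_dist <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(n)
      W <- resid_z(ey[perm, , drop = FALSE])
      tp <- t_of(W)
      tp[!ok_col] <- 0
      tpm <- matrix(tp, n_seg, n_met)
      max(apply(tpm, 2, function(col)
        max(tfce_1d(col, E, H, dh), tfce_1d(-col, E, H, dh))))
    }, numeric(1))
  })

  obs_abs <- abs(tfce_mat)
  p_fwe <- matrix((1 + vapply(as.numeric(obs_abs), function(o)
    sum(max_dist >= o), numeric(1))) / (n_perm + 1), n_seg, n_met)
  p_fwe[matrix(!ok_col, n_seg, n_met)] <- NA

  beta_std <- matrix(NA_real_, n_seg, n_met)
  for (m in seq_len(n_met)) for (s in seq_len(n_seg)) {
    if (ok_col[(m - 1) * n_seg + s])
      beta_std[s, m] <- glm_segment(vals[, s, m], regressor, nuisance)$beta_std
  }
  metrics <- if (inherits(profiles, "tract_profile")) profiles$metrics else
    dimnames(vals)[[3]]
  if (!is.null(metrics)) {
    colnames(beta_std) <- colnames(t_mat) <- colnames(tfce_mat) <-
      colnames(p_fwe) <- metrics
  }
  structure(list(beta_std = beta_std, t_stat = t_mat, tfce = tfce_mat,
                 p_fwe = p_fwe, n_perm = n_perm, seed = seed, dh = dh,
                 max_dist = max_dist),
            class = "tfce_result")
}

## slow path with per-segment pairwise deletion of missing participants
permutation_fwe_missing <- function(vals, regressor, nuisance, n_perm, seed,
                                    E, H, dh) {
  n_seg <- dim(vals)[2]; n_met <- dim(vals)[3]
  t_mat <- matrix(NA_real_, n_seg, n_met)
  cell_keep <- vector("list", n_seg * n_met)
  for (m in seq_len(n_met)) for (s in seq_len(n_seg)) {
    y <- vals[, s, m]
    keep <- !is.na(y)
    cell_keep[[(m - 1) * n_seg + s]] <- keep
    if (sum(keep) > 4 && var(y[keep]) > 0) {
      t_mat[s, m] <- glm_segment(y[keep], regressor[keep],
                                 if (is.null(nuisance)) NULL else
                                   nuisance[keep])$t_stat
    }
  }
  if (is.null(dh)) dh <- max(abs(t_mat), na.rm = TRUE) / 100
  tfce_mat <- apply(t_mat, 2, function(col) {
    col[is.na(col)] <- 0; tfce_signed(col, E, H, dh)
  })
  n <- dim(vals)[1]
  max_dist <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(n)
      tp <- matrix(0, n_seg, n_met)
      for (m in seq_len(n_met)) for (s in seq_len(n_seg)) {
        keep <- cell_keep[[(m - 1) * n_seg + s]]
        if (is.na(t_mat[s, m])) next
        y <- vals[, s, m]
        Z <- cbind(rep(1, length(y)),
                   if (is.null(nuisance)) NULL else nuisance)[keep, , drop = FALSE]
        yk <- y[keep]
        qz <- qr.Q(qr(Z))
        e <- yk - qz %*% crossprod(qz, yk)
        pk <- order(perm[keep])          # permutation restricted to the subset
        ystar <- e[pk] + (yk - e)
        tp[s, m] <- glm_segment(as.numeric(ystar), regressor[keep],
                                if (is.null(nuisance)) NULL else
                                  nuisance[keep])$t_stat
      }
      max(apply(tp, 2, function(col)
        max(tfce_1d(col, E, H, dh), tfce_1d(-col, E, H, dh))))
    }, numeric(1))
  })
  obs_abs <- abs(tfce_mat)
  p_fwe <- matrix((1 + vapply(as.numeric(obs_abs), function(o)
    sum(max_dist >= o), numeric(1))) / (n_perm + 1), n_seg, n_met)
  p_fwe[is.na(t_mat)] <- NA
  beta_std <- matrix(NA_real_, n_seg, n_met)
  for (m in seq_len(n_met)) for (s in seq_len(n_seg)) {
    keep <- cell_keep[[(m - 1) * n_seg + s]]
    if (!is.na(t_mat[s, m]))
      beta_std[s, m] <- glm_segment(vals[keep, s, m], regressor[keep],
                                    if (is.null(nuisance)) NULL else
                                      nuisance[keep])$beta_std
  }
  structure(list(beta_std = beta_std, t_stat = t_mat, tfce = tfce_mat,
                 p_fwe = p_fwe, n_perm = n_perm, seed = seed, dh = dh,
                 max_dist = max_dist),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  nsig <- sum(x$p_fwe < 0.05, na.rm = TRUE)
  cat(sprintf("tfce_result: %d segments x %d metrics, %d permutations\n",
              nrow(x$p_fwe), ncol(x$p_fwe), x$n_perm))
  cat(sprintf("  %d cells significant at p_fwe < 0.05\n", nsig))
  invisible(x)
}

## Gauss hypergeometric 2F1 by power series (|z| < 1, c > 0)
gauss_2f1 <- function(a, b, cc, z, tol = 1e-13, kmax = 1e5) {
  term <- 1; s <- 1
  for (k in 0:kmax) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) break
  }
  s
}

## exact sampling density of Pearson r given population rho (up to constants
## that cancel in the Bayes factor)
r_likelihood <- function(r, rho, n) {
  (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^((3 - 2 * n) / 2) *
    gauss_2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
}

#' Default Bayes factor for a Pearson correlation
#'
#' Two-sided Bayes factor BF10 comparing a stretched-beta prior of width
#' `kappa` on the population correlation against the point null, computed by
#' numerical integration of the exact sampling distribution of `r`.
#'
#' @param r Observed Pearson correlation.
#' @param n Sample size (>= 4).
#' @param kappa Prior width (default 1, i.e. uniform on (-1, 1)).
#' @return BF10 (> 0).
#' @export
correlation_bf10 <- function(r, n, kappa = 1) {
  stopifnot(n >= 4, abs(r) < 1, kappa > 0)
  prior <- function(rho) stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
  num <- integrate(function(rho)
    vapply(rho, function(p) r_likelihood(r, p, n), numeric(1)) * prior(rho),
    -1, 1, rel.tol = 1e-10)$value
  num / r_likelihood(r, 0, n)
}

#' Frequentist and Bayesian Pearson correlation report
#'
#' Product-moment correlation with a two-sided t-test p-value
#' (`t = r sqrt(n-2)/sqrt(1-r^2)` on `n - 2` df), a Fisher-z 95% confidence
#' interval (`atanh(r) +/- 1.959964 / sqrt(n - 3)`), and the default
#' two-sided Bayes factor from [correlation_bf10].
#'
#' @param x,y Participant vectors of equal length (n >= 4).
#' @param kappa Stretched-beta prior width for the Bayes factor.
#' @return An object of class `correlation_report`: `r`, `p`, `ci95`, `bf10`,
#'   `n`.
#' @export
pearson_report <- function(x, y, kappa = 1) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (var(x) == 0 || var(y) == 0) stop("zero-variance input")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0; ci <- c(r, r); bf <- Inf
  } else {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tt), df = n - 2)
    z <- atanh(r)
    hw <- 1.959964 / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
    bf <- correlation_bf10(r, n, kappa)
  }
  structure(list(r = r, p = p, ci95 = ci, bf10 = bf, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.3g, 95%% CI = (%.3f, %.3f), BF10 = %.3f (n = %d)\n",
              x$r, x$p, x$ci95[1], x$ci95[2], x$bf10, x$n))
  invisible(x)
}

## orthonormal contrast matrix, (k-1) x k (polynomial contrasts are already
## orthonormal and orthogonal to the constant)
ortho_contrasts <- function(k) {
  t(stats::contr.poly(k))
}

gg_epsilon <- function(scores, C) {
  # scores: n x k matrix of within-subject cell scores; C: (d x k) contrasts
  M <- C %*% stats::cov(scores) %*% t(C)
  d <- nrow(C)
  (sum(diag(M)))^2 / (d * sum(M^2))
}

#' Two-factor repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject two-factor ANOVA (factors: hemisphere and tract
#' segment) computed from the classical sums-of-squares decomposition, with
#' Greenhouse-Geisser epsilon per effect estimated from the sample covariance
#' of the orthonormalized level differences and applied to the F test's
#' degrees of freedom. A two-level factor is automatically spherical
#' (epsilon = 1).
#'
#' @param data 3-D array: participants x factor A levels x factor B levels
#'   (e.g. participants x hemispheres x segments). Complete data required.
#' @return An object of class `rm_anova`: per effect (`A`, `B`, `AB`) the
#'   uncorrected `F`, `df1`, `df2`, `eps_gg`, corrected dfs and `p_gg`.
#' @export
rm_anova_gg <- function(data) {
  stopifnot(length(dim(data)) == 3)
  if (anyNA(data)) stop("missing cells; repeated-measures ANOVA needs complete data")
  n <- dim(data)[1]; a <- dim(data)[2]; b <- dim(data)[3]
  stopifnot(n >= 2, a >= 2, b >= 2)
  m <- mean(data)
  m_i <- apply(data, 1, mean)
  m_j <- apply(data, 2, mean)
  m_k <- apply(data, 3, mean)
  m_ij <- apply(data, c(1, 2), mean)
  m_ik <- apply(data, c(1, 3), mean)
  m_jk <- apply(data, c(2, 3), mean)

  ss_a <- n * b * sum((m_j - m)^2)
  ss_b <- n * a * sum((m_k - m)^2)
  ss_ab <- n * sum((m_jk - outer(m_j, rep(1, b)) - outer(rep(1, a), m_k) + m)^2)
  ss_as <- b * sum((m_ij - outer(m_i, rep(1, a)) - outer(rep(1, n), m_j) + m)^2)
  ss_bs <- a * sum((m_ik - outer(m_i, rep(1, b)) - outer(rep(1, n), m_k) + m)^2)
  ss_tot <- sum((data - m)^2)
  ss_s <- a * b * sum((m_i - m)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  eff <- function(ss_eff, ss_err, df1, df2, eps) {
    if (ss_err <= 1e-300 * max(ss_eff, 1)) {
      return(list(F = NA_real_, df1 = df1, df2 = df2, eps_gg = eps,
                  p_gg = NA_real_, flag = "degenerate"))
    }
    Fv <- (ss_eff / df1) / (ss_err / df2)
    list(F = Fv, df1 = df1, df2 = df2, eps_gg = eps,
         df1_gg = eps * df1, df2_gg = eps * df2,
         p_gg = pf(Fv, eps * df1, eps * df2, lower.tail = FALSE))
  }
  Ca <- ortho_contrasts(a); Cb <- ortho_contrasts(b)
  eps_a <- if (a == 2) 1 else gg_epsilon(m_ij, Ca)
  eps_b <- if (b == 2) 1 else gg_epsilon(m_ik, Cb)
  cells <- matrix(aperm(data, c(1, 3, 2)), n)  # n x (b*a), B fastest
  Cab <- kronecker(Ca, Cb)
  eps_ab <- if (a == 2 && b == 2) 1 else gg_epsilon(cells, Cab)

  structure(list(
    A = eff(ss_a, ss_as, a - 1, (a - 1) * (n - 1), eps_a),
    B = eff(ss_b, ss_bs, b - 1, (b - 1) * (n - 1), eps_b),
    AB = eff(ss_ab, ss_abs, (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1),
             eps_ab)),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  for (nm in c("A", "B", "AB")) {
    e <- x[[nm]]
    cat(sprintf("%-3s F(%.2f, %.2f) = %.3f, p_gg = %.3g (eps = %.3f)\n",
                nm, e$eps_gg * e$df1, e$eps_gg * e$df2,
                ifelse(is.na(e$F), NaN, e$F), e$p_gg, e$eps_gg))
  }
  invisible(x)
}
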