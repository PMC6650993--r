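#' Specification of a tube phantom around a known 3-D curve
#'
#' Describes a synthetic "tract": a parametric space curve (line, arc or
#' helix) inside a voxel grid, around which a tube of tract probability is
#' generated with a Gaussian radial decay, emulating thresholded
#' probabilistic-tractography output with a known ground-truth centreline.
#'
#' @param curve `"line"`, `"arc"`, `"helix"`, or a function mapping `[0, 1]`
#'   to world-mm coordinates (n x 3).
#' @param tube_radius_mm Hard support radius of the tube (default 7 mm,
#'   i.e. 3.5 voxels at 2 mm: inside the skeleton-accuracy regime).
#' @param grid_shape Grid dimensions (default `c(64, 64, 64)`).
#' @param voxel_mm Isotropic voxel size (default 2 mm, the DWI resolution the
#'   generator emulates).
#' @param prob_decay_mm Gaussian width `w` of the radial probability profile
#'   `exp(-d^2 / (2 w^2))`; default `tube_radius_mm / 2.2`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(curve = "line", tube_radius_mm = 7,
                         grid_shape = c(64, 64, 64), voxel_mm = 2,
                         prob_decay_mm = tube_radius_mm / 2.2) {
  stopifnot(tube_radius_mm >= 3 * voxel_mm / 2)
  fov <- grid_shape * voxel_mm
  ctr <- fov / 2
  curve_fun <- if (is.function(curve)) curve else switch(
    curve,
    line = function(s) cbind(ctr[1], ctr[2], fov[3] * (0.15 + 0.7 * s)),
    arc = function(s) {
      # quarter circle of radius 40 mm in the xz plane
      th <- pi / 2 * s
      cbind(ctr[1] - 40 * cos(th) + 20, ctr[2], ctr[3] - 40 * sin(th) + 20)
    },
    helix = function(s) {
      th <- 3 * pi * s
      cbind(ctr[1] + 20 * cos(th), ctr[2] + 20 * sin(th),
            fov[3] * (0.2 + 0.6 * s))
    },
    stop("unknown curve type: ", curve))
  structure(list(curve_fun = curve_fun, curve_name =
                   if (is.function(curve)) "custom" else curve,
                 tube_radius_mm = tube_radius_mm, grid_shape = grid_shape,
                 voxel_mm = voxel_mm, prob_decay_mm = prob_decay_mm),
            class = "phantom_spec")
}

#' Generate a tube phantom tract-probability volume
#'
#' Voxel values are `exp(-d^2 / (2 w^2))` of the distance `d` from the voxel
#' centre to the true curve, zeroed beyond the tube radius and below the
#' tractography threshold `5e-5`; optional multiplicative log-normal noise.
#' The true curve is returned for skeleton validation.
#'
#' @param spec A [phantom_spec].
#' @param seed Optional seed for the multiplicative noise.
#' @param noise_sd SD of log-normal multiplicative noise (default 0, none).
#' @param n_curve_samples Dense samples of the true curve used for distance
#'   computation.
#' @return List: `vol` (a [tract_volume]), `curve_mm` (dense true curve),
#'   `curve_arc` (arc-length positions), `spec`.
#' @export
make_phantom <- function(spec, seed = NULL, noise_sd = 0,
                         n_curve_samples = 400) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  affine <- diag(c(rep(spec$voxel_mm, 3), 1))
  s <- seq(0, 1, length.out = n_curve_samples)
  curve <- spec$curve_fun(s)
  arc <- c(0, cumsum(sqrt(rowSums(diff(curve)^2))))

  # restrict the distance computation to a bounding box around the curve
  pad <- spec$tube_radius_mm + 2 * spec$voxel_mm
  lo <- pmax(floor((apply(curve, 2, min) - pad) / spec$voxel_mm), 1)
  hi <- pmin(ceiling((apply(curve, 2, max) + pad) / spec$voxel_mm), dm)
  sub_idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  xyz <- voxels_to_world(sub_idx, affine)
  d <- nearest_ref_cpp(xyz, curve)$distance

  val <- exp(-d^2 / (2 * spec$prob_decay_mm^2))
  val[d > spec$tube_radius_mm] <- 0
  if (noise_sd > 0) {
    val <- val * with_seed(seed, exp(rnorm(length(val), 0, noise_sd)))
  }
  val[val < 5e-5] <- 0
  data <- array(0, dm)
  data[sub_idx] <- val
  list(vol = tract_volume(data, affine, threshold = 5e-5),
       curve_mm = curve, curve_arc = arc, spec = spec)
}

#' Specification of a synthetic cohort
#'
#' Describes the study conditions the generators emulate: 46 participants
#' aged 19-24 years, non-decision times around 250 +/- 48 ms, 50 trials of a
#' simple reaction-time task per participant, and a negative association
#' (standardized beta -0.5) between non-decision time and neurite density
#' restricted to segments 18-30 of a 30-segment tract. Only NDI carries the
#' planted effect; ODI, FA and MD receive baseline plus noise so specificity
#' is testable.
#'
#' @param n_participants Cohort size (default 46).
#' @param age_range Age bounds in years (default 19-24).
#' @param ter_mean_ms,ter_sd_ms Population mean and SD of non-decision time
#'   (defaults 250 and 48 ms).
#' @param n_trials Trials per participant (default 50).
#' @param effect_segments Segments carrying the planted NDI effect (default
#'   18:30).
#' @param effect_beta_std Standardized effect size (default -0.5; negative:
#'   slower non-decision time, lower neurite density).
#' @param participant_noise_sd SD of the smooth participant-level deviation
#'   of each metric profile, in metric units (default 0.02).
#' @param voxel_noise_sd SD of voxel-level metric noise (default 0.01).
#' @param affine_jitter Max rotation (degrees) and translation (mm) of the
#'   per-participant template-to-native affine (default `c(3, 2)`).
#' @param n_segments Number of segments (default 30).
#' @param overlap Segment overlap (default 0.2).
#' @param seed Master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 46, age_range = c(19, 24),
                        ter_mean_ms = 250, ter_sd_ms = 48, n_trials = 50,
                        effect_segments = 18:30, effect_beta_std = -0.5,
                        participant_noise_sd = 0.02, voxel_noise_sd = 0.01,
                        affine_jitter = c(3, 2), n_segments = 30,
                        overlap = 0.2, seed = 1) {
  stopifnot(all(effect_segments >= 1), all(effect_segments <= n_segments),
            participant_noise_sd > 0 || voxel_noise_sd > 0,
            abs(effect_beta_std) < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

## baseline along-tract metric profiles (arc fraction s in [0, 1]); shapes
## loosely follow published corticospinal-tract profiles
baseline_profiles <- list(
  NDI = function(s) 0.55 + 0.08 * sin(pi * s) + 0.03 * s,
  ODI = function(s) 0.15 + 0.25 * s^2,
  FA = function(s) 0.62 - 0.15 * s^1.5,
  MD = function(s) 7e-4 + 1e-4 * cos(pi * s)
)

## smooth random per-participant profile deviation with pointwise SD `sd`
participant_deviation <- function(coef, s, sd) {
  sd / sqrt(2) * (coef[1] * sin(pi * s) + coef[2] * cos(pi * s) +
                    coef[3] * sin(2 * pi * s) + coef[4] * cos(2 * pi * s))
}

## arc-fraction intervals of the effect segments under the overlap scheme
effect_intervals <- function(spec) {
  n <- spec$n_segments; o <- spec$overlap
  l <- 1 / (1 + (n - 1) * (1 - o))
  starts <- (spec$effect_segments - 1) * (1 - o) * l
  cbind(starts, starts + l)
}

in_effect_zone <- function(s_frac, iv) {
  hit <- rep(FALSE, length(s_frac))
  for (r in seq_len(nrow(iv))) hit <- hit | (s_frac >= iv[r, 1] & s_frac <= iv[r, 2])
  hit
}

## planted-effect amplitude in metric units: chosen so the population
## correlation between the behavioural z-score and a segment's mean NDI
## equals effect_beta_std when segment averaging leaves participant-level
## noise dominant
effect_amplitude <- function(spec) {
  b <- spec$effect_beta_std
  b / sqrt(1 - b^2) * spec$participant_noise_sd
}

#' Generate per-participant RT samples from known LBA parameters
#'
#' True non-decision times are drawn from `Normal(ter_mean_ms, ter_sd_ms)`
#' (truncated at 50 ms); thresholds, mean drifts and drift SDs are drawn
#' uniformly from ranges that put mean RT near 360 ms with realistic
#' trial-to-trial variability. RTs are simulated from the single-accumulator
#' LBA and filtered by the 150-1500 ms exclusion rule.
#'
#' @param spec A [cohort_spec].
#' @return List: `samples` (list of [exclude_rts] results), `true_params`
#'   (data frame of the generating parameters, t_er in ms), `age` (years).
#' @export
make_rt_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(substream_seed(spec$seed, "synthesis", 1), {
    t_er_ms <- pmax(rnorm(n, spec$ter_mean_ms, spec$ter_sd_ms), 50)
    b <- runif(n, 0.9, 1.3)
    mu <- runif(n, 5, 8)
    sigma <- runif(n, 1, 2)
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      p <- lba_params(t_er = t_er_ms[i] / 1000, b = b[i], mu = mu[i],
                      sigma = sigma[i])
      rt_ms <- simulate_lba(p, spec$n_trials) * 1000
      samples[[i]] <- exclude_rts(rt_ms)
    }
    list(samples = samples,
         true_params = data.frame(t_er_ms = t_er_ms, b = b, mu = mu,
                                  sigma = sigma),
         age = age)
  })
}

#' Generate native-space metric maps for one participant
#'
#' Builds NDI/ODI/FA/MD volumes, a white-matter mask and a native tract
#' probability map on the participant's jittered native grid. Metric value at
#' a voxel = baseline profile at the voxel's arc position + smooth
#' participant deviation + (NDI only) the planted behavioural effect inside
#' the effect segments + voxel noise. The FA baseline exceeds 0.2 inside the
#' tube so the inclusion rules pass; the WM mask equals the tube support.
#'
#' @param phantom A [make_phantom] result (template space).
#' @param spec A [cohort_spec].
#' @param i Participant index.
#' @param z_behav Participant's z-scored behavioural value (drives the
#'   planted NDI effect).
#' @return List: `metric_maps` (named arrays), `wm_mask`, `tract_prob`,
#'   `affine_t2n` (4x4 world transform template -> native), `native_affine`,
#'   `native_dim`.
#' @export
make_metric_maps <- function(phantom, spec, i, z_behav = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  vol <- phantom$vol
  dm <- dim(vol$data)
  with_seed(substream_seed(spec$seed, "synthesis", 100 + i), {
    # small rigid jitter: template -> native world transform
    ang <- runif(3, -1, 1) * spec$affine_jitter[1] * pi / 180
    tr <- runif(3, -1, 1) * spec$affine_jitter[2]
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                c(-sin(ang[2]), 0, cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    ctr <- dm * voxel_sizes(vol$affine) / 2
    R <- Rx %*% Ry %*% Rz
    affine_t2n <- diag(4)
    affine_t2n[1:3, 1:3] <- R
    affine_t2n[1:3, 4] <- ctr - R %*% ctr + tr

    native_affine <- vol$affine
    native_dim <- dm
    # native voxel centres mapped back to template space -> arc position
    nat_idx <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]),
                                     seq_len(dm[3])))
    world_nat <- voxels_to_world(nat_idx, native_affine)
    world_tmpl <- cbind(world_nat, 1) %*% t(solve(affine_t2n))
    # distance/arc only needed near the tube: prefilter by bounding box
    pad <- phantom$spec$tube_radius_mm + 6
    lo <- apply(phantom$curve_mm, 2, min) - pad
    hi <- apply(phantom$curve_mm, 2, max) + pad
    near <- world_tmpl[, 1] >= lo[1] & world_tmpl[, 1] <= hi[1] &
      world_tmpl[, 2] >= lo[2] & world_tmpl[, 2] <= hi[2] &
      world_tmpl[, 3] >= lo[3] & world_tmpl[, 3] <= hi[3]
    nn <- nearest_ref_cpp(world_tmpl[near, 1:3, drop = FALSE],
                          phantom$curve_mm)
    arc_frac <- phantom$curve_arc[nn$index] / max(phantom$curve_arc)
    inside <- nn$distance <= phantom$spec$tube_radius_mm

    n_in <- sum(inside)
    lin_in <- which(near)[inside]
    s_in <- arc_frac[inside]
    d_in <- nn$distance[inside]

    tract_prob <- array(0, dm)
    tract_prob[lin_in] <- exp(-d_in^2 / (2 * phantom$spec$prob_decay_mm^2))
    tract_prob[tract_prob < 5e-5 & tract_prob > 0] <- 0
    wm_mask <- array(0, dm)
    wm_mask[lin_in] <- 1

    iv <- effect_intervals(spec)
    amp <- effect_amplitude(spec)
    eff <- in_effect_zone(s_in, iv)
    dev_coef <- matrix(rnorm(16), 4, 4)  # one smooth deviation per metric
    metric_maps <- list()
    for (m in seq_along(baseline_profiles)) {
      nm <- names(baseline_profiles)[m]
      scale_m <- if (nm == "MD") 1e-3 else 1   # MD in mm^2/s units
      base <- baseline_profiles[[nm]](s_in)
      dev <- participant_deviation(dev_coef[, m], s_in,
                                   spec$participant_noise_sd * scale_m)
      val <- base + dev + rnorm(n_in, 0, spec$voxel_noise_sd * scale_m)
      if (nm == "NDI") val <- val + amp * z_behav * eff
      arr <- array(0, dm)
      arr[lin_in] <- val
      metric_maps[[nm]] <- arr
    }
    list(metric_maps = metric_maps, wm_mask = wm_mask,
         tract_prob = tract_prob, affine_t2n = affine_t2n,
         native_affine = native_affine, native_dim = native_dim)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of along-tract profiles directly
#'
#' Profile-level counterpart of the imaging generators: draws behavioural
#' values and ages, then segment x metric profiles with a planted
#' standardized effect of `effect_beta_std` on NDI inside the effect
#' segments (population correlation equal to the standardized beta) and pure
#' baseline-plus-noise elsewhere. Used for statistical calibration at scale.
#'
#' @param spec A [cohort_spec].
#' @param null_effect If `TRUE`, the effect is suppressed (fully null cohort).
#' @return List: `profiles` (a `tract_profile`-shaped array participants x
#'   segments x 4), `t_er_ms`, `age`, `effect_segments`.
#' @export
simulate_profiles <- function(spec, null_effect = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants; ns <- spec$n_segments
  metrics <- names(baseline_profiles)
  with_seed(substream_seed(spec$seed, "synthesis", 5000), {
    t_er_ms <- pmax(rnorm(n, spec$ter_mean_ms, spec$ter_sd_ms), 50)
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    z <- as.numeric(scale(t_er_ms))
    b <- if (null_effect) 0 else spec$effect_beta_std
    s_mid <- (seq_len(ns) - 0.5) / ns
    vals <- array(NA_real_, c(n, ns, length(metrics)),
                  dimnames = list(NULL, NULL, metrics))
    for (m in seq_along(metrics)) {
      nm <- metrics[m]
      scale_m <- if (nm == "MD") 1e-3 else 1
      base <- baseline_profiles[[nm]](s_mid)
      noise <- matrix(rnorm(n * ns, 0, spec$participant_noise_sd * scale_m),
                      n, ns)
      vals[, , m] <- matrix(base, n, ns, byrow = TRUE) + noise
      if (nm == "NDI" && b != 0) {
        amp <- b / sqrt(1 - b^2) * spec$participant_noise_sd
        for (s in spec$effect_segments) {
          vals[, s, m] <- vals[, s, m] + amp * z
        }
      }
    }
    list(profiles = structure(list(values = vals, metrics = metrics,
                                   n_voxels = matrix(1L, n, ns)),
                              class = "tract_profile"),
         t_er_ms = t_er_ms, age = age,
         effect_segments = spec$effect_segments)
  })
}
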