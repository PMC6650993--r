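#' Read a NIfTI volume into a tract_volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param threshold Foreground threshold stored on the object (default 5e-5).
#' @return A [tract_volume] with the file's voxel-to-mm affine.
#' @export
read_volume <- function(path, threshold = 5e-5) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  data <- array(as.numeric(img), dim(img))
  tract_volume(data, matrix(affine, 4, 4), threshold = threshold)
}

#' Write a tract_volume to a NIfTI file
#'
#' @param vol A [tract_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4x4 affine from a whitespace-delimited text file
#'
#' @param path Text file with 4 rows of 4 numbers.
#' @return 4x4 matrix; errors when not invertible.
#' @export
read_affine <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4, 4))) stop("affine file must be 4x4: ", path)
  if (abs(det(m)) < 1e-12) stop("affine is not invertible: ", path)
  m
}

#' Write a 4x4 affine as text
#' @param m 4x4 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affine <- function(m, path) {
  write.table(format(m, digits = 17), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' Tab-separated file with one row per participant and columns
#' `participant`, `age`, `tract_prob`, `NDI`, `ODI`, `FA`, `MD`, `wm_mask`,
#' `affine`, `rt_file`. All paths must exist (relative paths are resolved
#' against the manifest's directory) and participant ids must be unique.
#'
#' @param path Manifest TSV.
#' @return Data frame with absolute paths.
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant", "age", "tract_prob", "NDI", "ODI", "FA", "MD",
            "wm_mask", "affine", "rt_file")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$participant)) stop("duplicate participant ids")
  if (!is.numeric(man$age)) stop("ages must be numeric")
  root <- dirname(normalizePath(path))
  for (col in c("tract_prob", "NDI", "ODI", "FA", "MD", "wm_mask", "affine",
                "rt_file")) {
    p <- man[[col]]
    abs <- ifelse(grepl("^/", p), p, file.path(root, p))
    bad <- !file.exists(abs)
    if (any(bad))
      stop("manifest row ", which(bad)[1], " (participant ",
           man$participant[which(bad)[1]], "): missing file ", abs[which(bad)[1]])
    man[[col]] <- abs
  }
  man
}

#' Default run configuration
#'
#' All pipeline tunables with their standard values: 30 segments with 20%
#' overlap, FA threshold 0.2, tract-probability threshold 5e-5, 2 mm cleaning
#' kernel, 10000 permutations, 1e5 LBA simulations, 100 initial candidate
#' sets and 20 repetitions of the fit, fitting quantiles
#' 0.1/0.3/0.5/0.7/0.9, RT exclusion bounds 150-1500 ms, TFCE E = 0.5 and
#' H = 2.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(n_segments = 30L, overlap = 0.2, fa_thresh = 0.2,
              prob_thresh = 5e-5, dilate_mm = 2, n_perm = 10000L,
              n_sim = 100000L, n_init = 100L, n_repeats = 20L,
              quantiles = c(0.1, 0.3, 0.5, 0.7, 0.9),
              rt_bounds_ms = c(150, 1500), tfce_E = 0.5, tfce_H = 2,
              tfce_dh = NULL, clip = NULL, orient_mm = NULL,
              n_curve_samples = 200L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar and vector entries map onto [run_config] fields; unknown keys are
#' rejected. Entries omitted from the file keep their defaults.
#'
#' @param path YAML file.
#' @return A [run_config].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a mapping")
  do.call(run_config, vals)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a full file-based cohort: template tract phantom, per
#' participant native-space metric maps, WM mask, tract probability map,
#' affine text file and RT CSV, plus a manifest TSV and a ground-truth JSON.
#'
#' @param dir Output directory (created).
#' @param phantom A [make_phantom] result.
#' @param spec A [cohort_spec].
#' @return Path of the manifest file.
#' @export
simulate_cohort <- function(dir, phantom, spec) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$vol, file.path(dir, "group_tract.nii.gz"))
  rt <- make_rt_cohort(spec)
  z <- as.numeric(scale(rt$true_params$t_er_ms))
  rows <- list()
  for (i in seq_len(spec$n_participants)) {
    id <- sprintf("sub%03d", i)
    pd <- file.path(dir, id)
    dir.create(pd, showWarnings = FALSE)
    maps <- make_metric_maps(phantom, spec, i, z_behav = z[i])
    paths <- list()
    for (nm in names(maps$metric_maps)) {
      paths[[nm]] <- file.path(pd, paste0(nm, ".nii.gz"))
      write_volume(tract_volume(maps$metric_maps[[nm]], maps$native_affine,
                                threshold = 0), paths[[nm]])
    }
    paths$wm_mask <- file.path(pd, "wm_mask.nii.gz")
    write_volume(tract_volume(maps$wm_mask, maps$native_affine, threshold = 0.5),
                 paths$wm_mask)
    paths$tract_prob <- file.path(pd, "tract_prob.nii.gz")
    write_volume(tract_volume(maps$tract_prob, maps$native_affine),
                 paths$tract_prob)
    paths$affine <- file.path(pd, "affine_t2n.txt")
    write_affine(maps$affine_t2n, paths$affine)
    paths$rt_file <- file.path(pd, "rt.csv")
    write.csv(data.frame(rt_ms = rt$samples[[i]]$rts), paths$rt_file,
              row.names = FALSE)
    rows[[i]] <- data.frame(participant = id, age = rt$age[i],
                            tract_prob = paths$tract_prob, NDI = paths$NDI,
                            ODI = paths$ODI, FA = paths$FA, MD = paths$MD,
                            wm_mask = paths$wm_mask, affine = paths$affine,
                            rt_file = paths$rt_file)
  }
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(true_t_er_ms = rt$true_params$t_er_ms, true_b = rt$true_params$b,
         true_mu = rt$true_params$mu, true_sigma = rt$true_params$sigma,
         age = rt$age, effect_segments = spec$effect_segments,
         effect_beta_std = spec$effect_beta_std, seed = spec$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  man_path
}

#' Run the full along-tract analysis pipeline
#'
#' Sequences the stages: fit the accumulator model to each participant's RT
#' file, skeletonize the group tract volume, divide the skeleton into
#' overlapping segments and assign tract voxels, map segment labels to each
#' native grid, apply the voxel inclusion rules, build
#' connection-probability-weighted profiles, and test segment-wise
#' associations of each behavioural regressor with TFCE permutation FWE
#' control. All outputs are written under `out_dir` together with a
#' provenance JSON; a rerun with identical inputs and seed is reproducible.
#'
#' @param manifest_path Path to a cohort manifest TSV (see [read_manifest]).
#' @param group_tract_path NIfTI tract-probability map in template space.
#' @param out_dir Output directory.
#' @param config A [run_config].
#' @param regressors Which behavioural regressors to test: any of
#'   `"t_er_ms"`, `"mean_rt_ms"`.
#' @param fit_method LBA bin-probability method (`"simulation"` or `"cdf"`).
#' @return List with `fits`, `skeleton`, `profiles`, `stats` (one
#'   `tfce_result` per regressor), `out_dir`.
#' @export
run_pipeline <- function(manifest_path, group_tract_path, out_dir,
                         config = run_config(),
                         regressors = c("t_er_ms", "mean_rt_ms"),
                         fit_method = "simulation") {
  man <- read_manifest(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(man)

  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed",
           if (!is.null(id)) paste0(" for participant ", id) else "",
           ": ", conditionMessage(e), call. = FALSE))
  }

  ## 1. accumulator-model fits
  fits <- vector("list", n)
  mean_rt <- numeric(n)
  for (i in seq_len(n)) {
    id <- man$participant[i]
    sample <- stage("fit-lba", id, {
      rt <- utils::read.csv(man$rt_file[i])
      if (!"rt_ms" %in% names(rt)) stop("RT file lacks column rt_ms")
      exclude_rts(rt$rt_ms, config$rt_bounds_ms[1], config$rt_bounds_ms[2])
    })
    mean_rt[i] <- mean(sample$rts)
    fits[[i]] <- stage("fit-lba", id, {
      fit_lba(sample, n_init_candidates = config$n_init,
              n_repeats = config$n_repeats, n_sim = config$n_sim,
              seed = substream_seed(config$seed, "lba", i * 1000L),
              probs = config$quantiles, method = fit_method)
    })
  }
  t_er_ms <- vapply(fits, function(f) f$params$t_er * 1000, numeric(1))
  jsonlite::write_json(
    setNames(lapply(fits, as.list), man$participant),
    file.path(out_dir, "lba_fits.json"), auto_unbox = TRUE, digits = NA)

  ## 2. skeletonization (template space)
  skel <- stage("skeletonize", NULL, {
    vol <- read_volume(group_tract_path, threshold = config$prob_thresh)
    skeletonize_tract(vol, dilate_mm = config$dilate_mm, clip = config$clip,
                      n_samples = config$n_curve_samples,
                      orient_mm = config$orient_mm)
  })
  utils::write.csv(data.frame(x_mm = skel$curve[, 1], y_mm = skel$curve[, 2],
                              z_mm = skel$curve[, 3], arclength_mm = skel$arc),
                   file.path(out_dir, "skeleton.csv"), row.names = FALSE)

  ## 3. segments + template-space voxel assignment
  vol <- read_volume(group_tract_path, threshold = config$prob_thresh)
  segs <- divide_segments(skel, config$n_segments, config$overlap)
  labels <- stage("assign-voxels", NULL, assign_voxels(vol, skel, segs))

  ## 4. native-space profiles
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    id <- man$participant[i]
    participants[[i]] <- stage("profile", id, {
      prob <- read_volume(man$tract_prob[i], threshold = config$prob_thresh)
      wm <- read_volume(man$wm_mask[i])$data
      fa <- read_volume(man$FA[i])$data
      aff <- read_affine(man$affine[i])
      native <- to_native(labels, aff, dim(prob$data), prob$affine)
      native <- include_voxels(native, wm, fa, prob$data,
                               fa_thresh = config$fa_thresh,
                               prob_thresh = config$prob_thresh)
      maps <- list(NDI = read_volume(man$NDI[i])$data,
                   ODI = read_volume(man$ODI[i])$data,
                   FA = fa, MD = read_volume(man$MD[i])$data)
      list(labels = native, tract_prob = prob$data, metric_maps = maps)
    })
  }
  names(participants) <- man$participant
  profiles <- build_profiles(participants)
  utils::write.csv(as.data.frame(profiles),
                   file.path(out_dir, "profiles.csv"), row.names = FALSE)

  ## 5. segment-wise statistics per regressor
  behav <- list(t_er_ms = t_er_ms, mean_rt_ms = mean_rt)
  stats_out <- list()
  for (reg in regressors) {
    res <- stage("stats", NULL,
                 permutation_fwe(profiles, behav[[reg]], nuisance = man$age,
                                 n_perm = config$n_perm, seed = config$seed,
                                 E = config$tfce_E, H = config$tfce_H,
                                 dh = config$tfce_dh))
    stats_out[[reg]] <- res
    long <- expand.grid(segment = seq_len(nrow(res$p_fwe)),
                        metric = profiles$metrics, stringsAsFactors = FALSE)
    long$beta_std <- as.vector(res$beta_std)
    long$t <- as.vector(res$t_stat)
    long$tfce <- as.vector(res$tfce)
    long$p_fwe <- as.vector(res$p_fwe)
    long$significant <- !is.na(long$p_fwe) & long$p_fwe < 0.05
    utils::write.csv(long, file.path(out_dir, paste0("stats_", reg, ".csv")),
                     row.names = FALSE)
  }

  ## provenance
  jsonlite::write_json(
    list(config = unclass(config), n_participants = n,
         seed = config$seed,
         package_version = as.character(utils::packageVersion("alongtract")),
         behavioural = list(t_er_ms = t_er_ms, mean_rt_ms = mean_rt)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  list(fits = fits, skeleton = skel, profiles = profiles, stats = stats_out,
       out_dir = out_dir)
}
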