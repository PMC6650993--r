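#' Divide a skeleton into equal-length overlapping segments
#'
#' With `n` segments of common length `l` overlapping by a fraction
#' `overlap`, the clipped arc length `S` satisfies
#' `S = l * (1 + (n - 1) * (1 - overlap))`, so
#' `l = S / (1 + (n - 1) * (1 - overlap))` and segment `i` (0-based) spans
#' `[i * (1 - overlap) * l, i * (1 - overlap) * l + l]`. Defaults are 30
#' segments with 20% overlap.
#'
#' @param skel A [skeleton] (already clipped).
#' @param n Number of segments (>= 1).
#' @param overlap Overlap fraction in `[0, 1)`.
#' @return An object of class `segment_set`: `n_segments`, `overlap`,
#'   `length` (mm), `intervals` (n x 2 matrix of start/end mm).
#' @export
divide_segments <- function(skel, n = 30, overlap = 0.2) {
  stopifnot(inherits(skel, "skeleton"), n >= 1, overlap >= 0, overlap < 1)
  S <- skel$arc_length
  if (S <= 0) stop("skeleton has non-positive arc length")
  l <- S / (1 + (n - 1) * (1 - overlap))
  starts <- (seq_len(n) - 1) * (1 - overlap) * l
  structure(list(n_segments = as.integer(n), overlap = overlap, length = l,
                 intervals = cbind(start_mm = starts, end_mm = starts + l)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d segments of %.2f mm, %.0f%% overlap\n",
              x$n_segments, x$length, 100 * x$overlap))
  invisible(x)
}

## segment ids whose interval contains each arc position (list of int vectors)
segment_ids_at <- function(arc_pos, segs) {
  iv <- segs$intervals
  lapply(arc_pos, function(p) {
    ids <- which(iv[, 1] - 1e-9 <= p & p <= iv[, 2] + 1e-9)
    if (length(ids) == 0) ids <- if (p < iv[1, 1]) 1L else segs$n_segments
    as.integer(ids)
  })
}

#' Assign tract voxels to skeleton segments
#'
#' Each foreground voxel's world-mm centre is projected to its nearest curve
#' sample (Euclidean distance); the voxel receives every segment whose
#' arc-length interval contains that sample's position (one or two ids under
#' 20% overlap). Voxels projecting beyond the clipped curve ends are assigned
#' to the terminal segments.
#'
#' @param vol A thresholded [tract_volume] in the skeleton's (template) space.
#' @param skel A clipped [skeleton].
#' @param segs A [divide_segments] result.
#' @return An object of class `voxel_labels`: `voxels` (m x 3 indices),
#'   `arc_pos`, `ids` (list of segment-id vectors), `segment_voxels` (per
#'   segment, linear indices into the template grid), `dim`, `affine`.
#' @export
assign_voxels <- function(vol, skel, segs) {
  fg <- vol_foreground(vol)
  vox <- mask_to_indices(fg)
  if (nrow(vox) == 0) stop("no foreground voxels to assign")
  xyz <- voxels_to_world(vox, vol$affine)
  nn <- nearest_ref_cpp(xyz, skel$curve)
  arc_pos <- skel$arc[nn$index]
  ids <- segment_ids_at(arc_pos, segs)
  lin <- vox[, 1] + dim(fg)[1] * (vox[, 2] - 1) +
    prod(dim(fg)[1:2]) * (vox[, 3] - 1)
  seg_vox <- lapply(seq_len(segs$n_segments), function(s)
    lin[vapply(ids, function(v) s %in% v, logical(1))])
  # dense per-voxel label arrays (primary/secondary id; 0 = unlabeled) for
  # fast native-space resampling
  id1 <- array(0L, dim(fg)); id2 <- array(0L, dim(fg))
  id1[lin] <- vapply(ids, `[`, integer(1), 1L)
  two <- lengths(ids) > 1L
  id2[lin[two]] <- vapply(ids[two], `[`, integer(1), 2L)
  structure(list(voxels = vox, arc_pos = arc_pos, ids = ids,
                 segment_voxels = seg_vox, id_arrays = list(id1, id2),
                 dim = dim(fg),
                 affine = vol$affine, n_segments = segs$n_segments),
            class = "voxel_labels")
}

#' Map template-space segment labels to a participant's native grid
#'
#' Nearest-neighbour pull resampling: each native voxel centre is mapped
#' through the native affine, the inverse template-to-native world transform
#' and the inverse template affine; if it lands (after rounding) on a labeled
#' template voxel, the native voxel inherits that voxel's full label set.
#'
#' @param labels A [assign_voxels] result (template space).
#' @param affine_t2n 4x4 world-mm transform from template space to native
#'   space.
#' @param native_dim Native grid dimensions (length 3).
#' @param native_affine Native voxel-to-mm affine.
#' @return A `voxel_labels`-like object in native space (`segment_voxels`
#'   hold native linear indices).
#' @export
to_native <- function(labels, affine_t2n, native_dim, native_affine) {
  stopifnot(inherits(labels, "voxel_labels"))
  if (abs(det(affine_t2n)) < 1e-12) stop("template-to-native affine not invertible")
  id1 <- labels$id_arrays[[1]]; id2 <- labels$id_arrays[[2]]

  nat_idx <- as.matrix(expand.grid(seq_len(native_dim[1]),
                                   seq_len(native_dim[2]),
                                   seq_len(native_dim[3])))
  world_nat <- voxels_to_world(nat_idx, native_affine)
  world_tmpl <- cbind(world_nat, 1) %*% t(solve(affine_t2n))
  tmpl_idx <- round(world_to_voxels(world_tmpl[, 1:3], labels$affine))
  ok <- tmpl_idx[, 1] >= 1 & tmpl_idx[, 1] <= labels$dim[1] &
    tmpl_idx[, 2] >= 1 & tmpl_idx[, 2] <= labels$dim[2] &
    tmpl_idx[, 3] >= 1 & tmpl_idx[, 3] <= labels$dim[3]
  hit_lin_tmpl <- tmpl_idx[ok, 1] + labels$dim[1] * (tmpl_idx[ok, 2] - 1) +
    prod(labels$dim[1:2]) * (tmpl_idx[ok, 3] - 1)
  nat_lin <- which(ok)
  nid1 <- id1[hit_lin_tmpl]; nid2 <- id2[hit_lin_tmpl]
  labeled <- nid1 > 0L
  if (!any(labeled)) stop("all labels map outside the native grid")
  nat_lin <- nat_lin[labeled]
  nid1 <- nid1[labeled]; nid2 <- nid2[labeled]
  seg_vox <- lapply(seq_len(labels$n_segments), function(s)
    nat_lin[nid1 == s | nid2 == s])
  ids <- lapply(seq_along(nat_lin), function(i)
    if (nid2[i] > 0L) c(nid1[i], nid2[i]) else nid1[i])
  vox <- arrayInd(nat_lin, native_dim)
  out_id1 <- array(0L, native_dim); out_id2 <- array(0L, native_dim)
  out_id1[nat_lin] <- nid1
  out_id2[nat_lin] <- nid2
  structure(list(voxels = vox, arc_pos = NULL, ids = ids,
                 segment_voxels = seg_vox, id_arrays = list(out_id1, out_id2),
                 dim = native_dim,
                 affine = native_affine, n_segments = labels$n_segments),
            class = "voxel_labels")
}

#' Filter native-space labeled voxels by the inclusion rules
#'
#' A voxel enters the metric computation only if (1) it lies in the
#' individual white-matter mask, (2) its FA value exceeds `fa_thresh`
#' (strict inequality), and (3) its tract connection probability is at or
#' above `prob_thresh` (the tractography threshold survives).
#'
#' @param labels Native-space [to_native]/[assign_voxels] result.
#' @param wm_mask,fa_map,tract_prob 3-D arrays on the native grid.
#' @param fa_thresh FA cutoff (default 0.2, strict `>`).
#' @param prob_thresh Connection-probability cutoff (default 5e-5, `>=`).
#' @return The labels object with filtered `segment_voxels` and a logical
#'   `missing_segments` vector flagging emptied segments.
#' @export
include_voxels <- function(labels, wm_mask, fa_map, tract_prob,
                           fa_thresh = 0.2, prob_thresh = 5e-5) {
  stopifnot(inherits(labels, "voxel_labels"))
  stopifnot(all(dim(wm_mask) == labels$dim), all(dim(fa_map) == labels$dim),
            all(dim(tract_prob) == labels$dim))
  keep_ok <- function(lin) {
    lin[wm_mask[lin] > 0 & fa_map[lin] > fa_thresh & tract_prob[lin] >= prob_thresh]
  }
  labels$segment_voxels <- lapply(labels$segment_voxels, keep_ok)
  labels$missing_segments <-
    vapply(labels$segment_voxels, length, integer(1)) == 0L
  labels
}

#' Connection-probability-weighted mean of a metric over a voxel set
#'
#' `sum_v P(v) m(v) / sum_v P(v)` with the tract connection probability as
#' the weight, so voxels with uncertain tract membership contribute less.
#'
#' @param metric_map 3-D array of the metric in native space.
#' @param tract_prob 3-D array of connection probabilities (weights).
#' @param voxels Linear indices of the included voxels.
#' @return The weighted mean, or `NA` (with attribute `flag = "empty"`) when
#'   the voxel set is empty or all weights vanish.
#' @export
weighted_metric <- function(metric_map, tract_prob, voxels) {
  if (length(voxels) == 0)
    return(structure(NA_real_, flag = "empty"))
  w <- tract_prob[voxels]
  if (any(w < 0)) stop("negative connection-probability weights")
  sw <- sum(w)
  if (sw == 0) return(structure(NA_real_, flag = "empty"))
  sum(w * metric_map[voxels]) / sw
}

#' Assemble along-tract metric profiles for a cohort
#'
#' For each participant, computes the weighted mean of every metric map over
#' the included voxels of each segment, yielding a participants x segments x
#' metrics array plus per-cell voxel support counts. Missing segments
#' propagate as `NA`; a participant with more than half their segments
#' missing triggers a warning but is retained.
#'
#' @param participants List; each element holds `labels` (filtered native
#'   [voxel_labels]), `tract_prob` (native array) and `metric_maps` (named
#'   list of native arrays).
#' @param metrics Ordered metric names (default `c("NDI","ODI","FA","MD")`).
#' @return An object of class `tract_profile`: `values` (array), `metrics`,
#'   `n_voxels` (participants x segments).
#' @export
build_profiles <- function(participants, metrics = c("NDI", "ODI", "FA", "MD")) {
  stopifnot(length(participants) >= 1)
  n <- length(participants)
  ns <- participants[[1]]$labels$n_segments
  values <- array(NA_real_, c(n, ns, length(metrics)),
                  dimnames = list(names(participants), NULL, metrics))
  n_vox <- matrix(0L, n, ns)
  for (i in seq_len(n)) {
    p <- participants[[i]]
    segs <- p$labels$segment_voxels
    n_vox[i, ] <- vapply(segs, length, integer(1))
    for (m in seq_along(metrics)) {
      mm <- p$metric_maps[[metrics[m]]]
      if (is.null(mm)) stop("participant ", i, " lacks metric ", metrics[m])
      values[i, , m] <- vapply(segs, function(v)
        as.numeric(weighted_metric(mm, p$tract_prob, v)), numeric(1))
    }
    if (mean(n_vox[i, ] == 0) > 0.5)
      warning("participant ", i, " has >50% missing segments; retained")
  }
  structure(list(values = values, metrics = metrics, n_voxels = n_vox),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("tract_profile: %d participants x %d segments x %d metrics (%s)\n",
              d[1], d[2], d[3], paste(x$metrics, collapse = ", ")))
  invisible(x)
}

#' Convert a tract profile to a long-format data frame
#'
#' @param x A [build_profiles] result.
#' @param ... Unused.
#' @return Data frame with columns `participant`, `segment`, `metric`,
#'   `value`, `n_voxels`, `flag`.
#' @export
as.data.frame.tract_profile <- function(x, ...) {
  d <- dim(x$values)
  ids <- dimnames(x$values)[[1]]
  if (is.null(ids)) ids <- as.character(seq_len(d[1]))
  out <- expand.grid(participant = ids, segment = seq_len(d[2]),
                     metric = x$metrics, stringsAsFactors = FALSE)
  out$value <- as.vector(x$values)
  out$n_voxels <- rep(as.vector(x$n_voxels), times = d[3])
  out$flag <- ifelse(is.na(out$value), "missing", "")
  out
}
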