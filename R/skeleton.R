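#' Clean a binary tract volume before skeletonization
#'
#' Removes isolated voxels (no other foreground voxel within Chebyshev
#' distance 2, i.e. no second-order neighbours), dilates the remainder with a
#' ball-shaped structuring element of the given world-mm radius to close
#' holes and discontinuities, and fills internal cavities. The result must be
#' a single connected component; if several comparably sized components
#' survive, an error lists their sizes.
#'
#' @param vol A [tract_volume]; its foreground is taken at `vol$threshold`.
#' @param kernel_radius_mm Structuring-element radius in mm (default 2).
#' @param kernel `"ball"` (default, isotropic 3-D) or `"disk"` (slice-wise
#'   2-D in the xy plane).
#' @return A binary [tract_volume].
#' @export
clean_volume <- function(vol, kernel_radius_mm = 2, kernel = c("ball", "disk")) {
  kernel <- match.arg(kernel)
  fg <- vol_foreground(vol)
  if (!any(fg)) stop("empty foreground")
  dm <- dim(fg)
  vs <- voxel_sizes(vol$affine)

  # 1. drop voxels with no second-order neighbour (Chebyshev distance <= 2)
  counts <- neighbour_count(fg, radius = 2L)
  fg[counts == 0] <- FALSE
  if (!any(fg)) stop("empty foreground after isolated-voxel removal")

  # 2. dilation by the structuring element (world-mm ball or in-plane disk)
  offs <- kernel_offsets(kernel_radius_mm, vs, kernel)
  fg <- dilate_mask(fg, offs)

  # 3. fill internal cavities: 6-connected background components that do not
  #    touch the grid border are inside the object
  bg_lab <- label_components(!fg, connectivity = 6)
  border_labs <- unique(c(bg_lab[1, , ], bg_lab[dm[1], , ],
                          bg_lab[, 1, ], bg_lab[, dm[2], ],
                          bg_lab[, , 1], bg_lab[, , dm[3]]))
  border_labs <- setdiff(border_labs, 0L)
  fg[bg_lab != 0 & !(bg_lab %in% border_labs)] <- TRUE

  # 4. connectivity check
  lab <- label_components(fg, connectivity = 26)
  sizes <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
  if (length(sizes) > 1) {
    if (sizes[2] > max(27, 0.01 * sizes[1]))
      stop("foreground splits into multiple large components after cleaning; ",
           "sizes: ", paste(sizes, collapse = ", "))
    keep <- which.max(tabulate(lab[lab > 0]))
    fg <- lab == keep
  }
  tract_volume(array(as.numeric(fg), dm), vol$affine, threshold = 0.5)
}

## count of foreground neighbours within Chebyshev radius (excluding self)
neighbour_count <- function(mask, radius = 2L) {
  dm <- dim(mask)
  acc <- array(0L, dm)
  m <- array(as.integer(mask), dm)
  for (dx in -radius:radius) for (dy in -radius:radius) for (dz in -radius:radius) {
    if (dx == 0 && dy == 0 && dz == 0) next
    acc <- acc + shift_array(m, c(dx, dy, dz))
  }
  acc[!mask] <- 0L
  acc
}

## integer array shifted by offset, zero-padded
shift_array <- function(arr, off) {
  dm <- dim(arr)
  out <- array(0L, dm)
  src <- dst <- vector("list", 3)
  for (d in 1:3) {
    o <- off[d]
    if (o >= 0) { src[[d]] <- seq_len(dm[d] - o); dst[[d]] <- src[[d]] + o }
    else        { src[[d]] <- seq(1 - o, dm[d]); dst[[d]] <- src[[d]] + o }
    if (length(src[[d]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

kernel_offsets <- function(radius_mm, voxel_sizes, kernel) {
  r_vox <- ceiling(radius_mm / voxel_sizes)
  grid <- expand.grid(dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                      dz = if (kernel == "disk") 0L else -r_vox[3]:r_vox[3])
  d_mm <- sqrt((grid$dx * voxel_sizes[1])^2 + (grid$dy * voxel_sizes[2])^2 +
                 (grid$dz * voxel_sizes[3])^2)
  as.matrix(grid[d_mm <= radius_mm + 1e-9, , drop = FALSE])
}

dilate_mask <- function(mask, offsets) {
  m <- array(as.integer(mask), dim(mask))
  acc <- array(0L, dim(mask))
  for (i in seq_len(nrow(offsets))) {
    acc <- acc + shift_array(m, offsets[i, ])
  }
  acc > 0
}

#' Topology-preserving curve-skeleton thinning
#'
#' Iteratively removes simple voxels from the object boundary in six
#' directional sub-iterations until no removable voxel remains. A voxel is
#' simple when its deletion changes neither the number of 26-connected
#' foreground components nor the number of 6-connected background components
#' in its neighbourhood (the standard topological characterization), so
#' components, tunnels and cavities of the object are preserved exactly.
#' Curve endpoints (voxels with a single foreground neighbour) are retained
#' so elongated objects thin to their full-length centreline.
#'
#' @param vol A binary [tract_volume] with a single 26-connected foreground
#'   component.
#' @return A list with `mask` (logical array) and `voxels` (n x 3 index
#'   matrix) of the skeleton.
#' @export
thin_volume <- function(vol) {
  fg <- vol_foreground(vol)
  lab <- label_components(fg, 26)
  if (max(lab) != 1) stop("foreground must be a single connected component")
  thin <- thin_volume_cpp(as.logical(fg), dim(fg))
  mask <- array(thin, dim(fg))
  list(mask = mask, voxels = mask_to_indices(mask))
}

## weighted 26-adjacency graph over skeleton voxels; weights = Euclidean mm
skeleton_graph <- function(voxels, affine) {
  n <- nrow(voxels)
  xyz <- voxels_to_world(voxels, affine)
  edges <- NULL
  key <- voxels %*% c(1, 1e4, 1e8)
  lookup <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_len(n)) {
    nb <- sweep(offs, 2, as.numeric(voxels[i, ]), "+")
    nbkey <- nb %*% c(1, 1e4, 1e8)
    for (k in seq_along(nbkey)) {
      j <- mget(as.character(nbkey[k]), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) {
        from <- c(from, i); to <- c(to, j)
        w <- c(w, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
      }
    }
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Prune side branches to the principal trunk of a voxel skeleton
#'
#' Finds the longest geodesic path between any two endpoints of the skeleton
#' graph (26-connectivity, Euclidean edge weights) and discards all side
#' branches.
#'
#' @param voxels n x 3 matrix of skeleton voxel indices (must be connected).
#' @param affine Voxel-to-mm affine used for edge weights.
#' @return Ordered m x 3 matrix of trunk voxel indices.
#' @export
prune_branches <- function(voxels, affine = diag(4)) {
  voxels <- matrix(voxels, ncol = 3)
  n <- nrow(voxels)
  if (n == 1) return(voxels)
  g <- skeleton_graph(voxels, affine)
  if (igraph::components(g)$no != 1) stop("skeleton is not connected")
  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) == 0)
    stop("skeleton has no endpoints (closed loop); cannot extract a trunk")
  d <- igraph::distances(g, v = ends, to = ends)
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  path <- igraph::shortest_paths(g, from = ends[best[1]], to = ends[best[2]],
                                 output = "vpath")$vpath[[1]]
  voxels[as.integer(igraph::as_ids(path)), , drop = FALSE]
}

#' Fit a smoothing cubic spline through a voxel path
#'
#' Converts the ordered trunk voxels to world mm, fits a cubic smoothing
#' spline to each coordinate against normalized chord length, and resamples
#' the smooth curve at points uniform in arc length. The smoothing level is
#' chosen (by bisection on the spline's smoothing parameter) as the heaviest
#' smoothing whose mean squared deviation from the voxel centres stays within
#' `smoothing` (default `(0.5 * mean voxel size)^2`).
#'
#' @param path Ordered m x 3 voxel index matrix, m >= 4.
#' @param affine Voxel-to-mm affine.
#' @param smoothing Target mean squared deviation in mm^2, or `NULL` for the
#'   half-voxel default.
#' @param n_samples Number of arc-length-uniform samples (default 200).
#' @return An object of class `skeleton`: `curve` (n_samples x 3 mm),
#'   `arc_length` (total mm), `arc` (per-sample positions), `voxel_path`,
#'   `clip_bounds`.
#' @export
fit_spline <- function(path, affine = diag(4), smoothing = NULL,
                       n_samples = 200) {
  path <- matrix(path, ncol = 3)
  if (nrow(path) < 4) stop("path too short for spline fitting (need >= 4 voxels)")
  xyz <- voxels_to_world(path, affine)
  if (is.null(smoothing)) smoothing <- (0.5 * mean(voxel_sizes(affine)))^2
  tt <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
  if (any(diff(tt) <= 0)) tt <- seq_along(tt) - 1  # degenerate duplicates
  tt <- tt / max(tt)

  fit_at <- function(spar) {
    lapply(1:3, function(d)
      smooth.spline(tt, xyz[, d], spar = spar, cv = FALSE,
                    all.knots = nrow(path) <= 50))
  }
  msd_of <- function(fits) {
    pred <- sapply(fits, function(f) predict(f, tt)$y)
    mean(rowSums((pred - xyz)^2))
  }
  lo <- -1.5; hi <- 1.5
  fits <- fit_at(lo)
  if (msd_of(fits) <= smoothing) {
    for (it in 1:20) {
      mid <- (lo + hi) / 2
      fm <- fit_at(mid)
      if (msd_of(fm) <= smoothing) { lo <- mid; fits <- fm } else hi <- mid
    }
  }
  dense_t <- seq(0, 1, length.out = max(10 * n_samples, 1000))
  dense <- sapply(fits, function(f) predict(f, dense_t)$y)
  seg <- sqrt(rowSums(diff(dense)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  target <- seq(0, total, length.out = n_samples)
  curve <- sapply(1:3, function(d)
    approx(cum, dense[, d], xout = target, ties = "ordered")$y)
  structure(list(curve = curve, arc = target, arc_length = total,
                 voxel_path = path, clip_bounds = c(0, total)),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d samples, arc length %.1f mm (clip %.1f-%.1f mm)\n",
              nrow(x$curve), x$arc_length, x$clip_bounds[1], x$clip_bounds[2]))
  invisible(x)
}

#' Clip a skeleton to an arc-length window
#'
#' Restricts the smooth curve to `[lo_mm, hi_mm]` and re-zeroes arc length at
#' `lo_mm`, keeping samples uniform in arc length.
#'
#' @param skel A [fit_spline] result.
#' @param lo_mm,hi_mm Window in mm, `0 <= lo_mm < hi_mm <= arc_length`.
#' @param n_samples Samples in the clipped curve; default keeps the original
#'   sampling density.
#' @return A clipped `skeleton`.
#' @export
clip_skeleton <- function(skel, lo_mm, hi_mm, n_samples = NULL) {
  stopifnot(inherits(skel, "skeleton"))
  L <- skel$arc_length
  if (!(lo_mm >= 0 && lo_mm < hi_mm && hi_mm <= L + 1e-9))
    stop("invalid clip range [", lo_mm, ", ", hi_mm, "] for arc length ", L)
  if (is.null(n_samples))
    n_samples <- max(2L, round(nrow(skel$curve) * (hi_mm - lo_mm) / L))
  target <- seq(lo_mm, hi_mm, length.out = n_samples)
  curve <- sapply(1:3, function(d)
    approx(skel$arc, skel$curve[, d], xout = target, ties = "ordered")$y)
  structure(list(curve = curve, arc = target - lo_mm,
                 arc_length = hi_mm - lo_mm, voxel_path = skel$voxel_path,
                 clip_bounds = c(lo_mm, hi_mm)),
            class = "skeleton")
}

#' Orient a skeleton so it starts near an anatomical anchor
#'
#' The direction of a pruned trunk is arbitrary; along-tract analyses fix it
#' by anchoring the start at a known structure (e.g. the cerebral peduncle
#' end of the corticospinal tract). Flips the curve when its far end is
#' closer to the anchor.
#'
#' @param skel A [skeleton].
#' @param start_mm Length-3 world-mm coordinate of the desired start.
#' @return The skeleton, possibly reversed (arc re-zeroed at the new start).
#' @export
orient_skeleton <- function(skel, start_mm) {
  stopifnot(inherits(skel, "skeleton"), length(start_mm) == 3)
  n <- nrow(skel$curve)
  d_first <- sum((skel$curve[1, ] - start_mm)^2)
  d_last <- sum((skel$curve[n, ] - start_mm)^2)
  if (d_last < d_first) {
    skel$curve <- skel$curve[n:1, , drop = FALSE]
    skel$arc <- skel$arc_length - rev(skel$arc)
    if (!is.null(skel$voxel_path))
      skel$voxel_path <- skel$voxel_path[nrow(skel$voxel_path):1, , drop = FALSE]
  }
  skel
}

#' Full skeletonization of a tract probability volume
#'
#' Convenience wrapper: threshold, clean, thin, prune, spline-smooth and
#' optionally clip (by arc-length fractions) a tract volume.
#'
#' @param vol A [tract_volume] (probability map; threshold taken from the
#'   object).
#' @param dilate_mm Cleaning kernel radius in mm.
#' @param clip Length-2 vector of arc-length fractions to retain (e.g.
#'   `c(0.1, 0.9)`), or `NULL` for no clipping.
#' @param n_samples Curve samples.
#' @param smoothing Spline target mean squared deviation (mm^2), or `NULL`.
#' @param orient_mm Optional world-mm anchor passed to [orient_skeleton];
#'   the skeleton starts at the end nearest this point.
#' @return A `skeleton`.
#' @export
skeletonize_tract <- function(vol, dilate_mm = 2, clip = NULL,
                              n_samples = 200, smoothing = NULL,
                              orient_mm = NULL) {
  cleaned <- clean_volume(vol, kernel_radius_mm = dilate_mm)
  thin <- thin_volume(cleaned)
  trunk <- prune_branches(thin$voxels, vol$affine)
  skel <- fit_spline(trunk, vol$affine, smoothing = smoothing,
                     n_samples = n_samples)
  if (!is.null(orient_mm)) skel <- orient_skeleton(skel, orient_mm)
  if (!is.null(clip)) {
    skel <- clip_skeleton(skel, clip[1] * skel$arc_length,
                          clip[2] * skel$arc_length)
  }
  skel
}
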