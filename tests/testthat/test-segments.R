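test_that("segment division follows the closed-form length and stride", {
  sk <- straight_skeleton(24.2)
  segs <- divide_segments(sk, 30, 0.2)
  expect_equal(segs$length, 1.0, tolerance = 1e-9)
  expect_equal(unname(segs$intervals[2, 1] - segs$intervals[1, 1]), 0.8,
               tolerance = 1e-9)
  expect_equal(unname(segs$intervals[30, 2]), 24.2, tolerance = 1e-9)

  # grid consistency: l * (1 + (n-1)(1-o)) = S
  for (n in c(1, 2, 10, 30, 57)) for (o in c(0, 0.2, 0.5, 0.9)) {
    sk2 <- straight_skeleton(73.3)
    s2 <- divide_segments(sk2, n, o)
    expect_equal(s2$length * (1 + (n - 1) * (1 - o)), 73.3,
                 tolerance = 1e-6 * 73.3)
    expect_equal(unname(s2$intervals[n, 2]), 73.3, tolerance = 1e-6)
  }

  one <- divide_segments(straight_skeleton(10), 1, 0.2)
  expect_equal(unname(one$intervals[1, ]), c(0, 10))

  ten <- divide_segments(straight_skeleton(10), 10, 0)
  expect_equal(ten$length, 1)
  expect_true(all(abs(diff(ten$intervals[, 1]) - 1) < 1e-9))
})

test_that("voxels get the segment ids of their projected arc position", {
  sk <- straight_skeleton(24.2, n_samples = 4841)  # 5 um sampling
  segs <- divide_segments(sk, 30, 0.2)
  # tube volume around the z axis; fine 0.1 mm z pitch so arc positions
  # resolve the 0.2 mm overlap zones
  dm <- c(9, 9, 243)
  arr <- array(0, dm)
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  aff <- diag(c(1, 1, 0.1, 1)); aff[1:3, 4] <- c(-4, -4, 0.031)
  xyz <- alongtract:::voxels_to_world(idx, aff)
  r2 <- xyz[, 1]^2 + xyz[, 2]^2
  arr[idx[r2 <= 4 & xyz[, 3] <= 24.2, ]] <- 1
  vol <- tract_volume(arr, aff, threshold = 0.5)
  lab <- assign_voxels(vol, sk, segs)

  # segment 5 spans [3.2, 4.2]; seg4 [2.4, 3.4]; seg6 [4.0, 5.0].
  # exclusive zone of segment 5 is (3.4, 4.0): take a voxel at its midpoint
  i <- which(abs(lab$arc_pos - 3.7) < 0.04)[1]
  expect_equal(lab$ids[[i]], 5L)
  # overlap zone of segments 5 and 6: [4.0, 4.2]
  j <- which(lab$arc_pos > 4.04 & lab$arc_pos < 4.16)[1]
  expect_equal(sort(lab$ids[[j]]), c(5L, 6L))

  # interior segment support roughly equal on a straight tube
  counts <- lengths(lab$segment_voxels)[3:28]
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.25)

  # dual-label arc measure matches the interval geometry:
  # (n-1) * o * l / S for voxels projecting strictly inside
  interior <- lab$arc_pos > 0.2 & lab$arc_pos < 24.0
  frac2 <- mean(lengths(lab$ids)[interior] == 2)
  expect_equal(frac2, 29 * 0.2 * segs$length / 24.2, tolerance = 0.15)
})

test_that("native-space mapping preserves labels under simple transforms", {
  sk <- straight_skeleton(40, 81)
  segs <- divide_segments(sk, 10, 0.2)
  dm <- c(11, 11, 24)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, 0)
  arr <- array(0, dm)
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  xyz <- alongtract:::voxels_to_world(idx, aff)
  arr[idx[xyz[, 1]^2 + xyz[, 2]^2 <= 36 & xyz[, 3] <= 40, ]] <- 1
  vol <- tract_volume(arr, aff, threshold = 0.5)
  lab <- assign_voxels(vol, sk, segs)

  # identity: labels unchanged
  nat <- to_native(lab, diag(4), dm, aff)
  expect_equal(lengths(nat$segment_voxels), lengths(lab$segment_voxels))
  expect_setequal(nat$segment_voxels[[4]], lab$segment_voxels[[4]])

  # pure translation by exactly one voxel along z (2 mm)
  tr <- diag(4); tr[3, 4] <- 2
  nat_tr <- to_native(lab, tr, dm, aff)
  shifted <- nat_tr$segment_voxels[[4]]
  # z index of every labeled voxel moves by +1: linear index shifts by nx*ny
  expect_setequal(shifted, lab$segment_voxels[[4]] + prod(dm[1:2]))

  # small rigid transform round trip keeps >= 90% of labels
  ang <- 2 * pi / 180
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  t2n <- diag(4); t2n[1:3, 1:3] <- R; t2n[1:3, 4] <- c(1.2, -0.8, 0.6)
  nat_r <- to_native(lab, t2n, dm, aff)
  # represent label sets as vectors over linear indices for comparison
  lab_vec <- function(l) {
    v <- integer(prod(dm))
    for (s in seq_along(l$segment_voxels)) v[l$segment_voxels[[s]]] <-
        v[l$segment_voxels[[s]]] + 2L^s
    v
  }
  back <- to_native(nat_r, solve(t2n), dm, aff)
  v0 <- lab_vec(lab); v1 <- lab_vec(back)
  common <- v0 > 0 | v1 > 0
  expect_gt(mean(v0[common] == v1[common]), 0.9)
})

test_that("inclusion rules follow the threshold semantics exactly", {
  dm <- c(4, 4, 4)
  lab <- structure(list(segment_voxels = list(1:64), dim = dm,
                        n_segments = 1L, affine = diag(4)),
                   class = "voxel_labels")
  wm <- array(1, dm); fa <- array(0.5, dm); pr <- array(1e-3, dm)
  fa[1] <- 0.2          # exactly at threshold -> excluded (strict >)
  pr[2] <- 5e-5         # exactly at threshold -> included (>=)
  wm[3] <- 0            # excluded regardless
  pr[4] <- 1e-6         # below probability threshold -> excluded
  out <- include_voxels(lab, wm, fa, pr)
  kept <- out$segment_voxels[[1]]
  expect_false(1 %in% kept)
  expect_true(2 %in% kept)
  expect_false(3 %in% kept)
  expect_false(4 %in% kept)
  expect_equal(length(kept), 61)
  expect_false(out$missing_segments[1])

  fa_all <- array(0.1, dm)
  out2 <- include_voxels(lab, wm, fa_all, pr)
  expect_true(out2$missing_segments[1])
})

test_that("weighted metric obeys its algebraic contract", {
  m <- array(0, c(2, 2, 1)); w <- array(0, c(2, 2, 1))
  m[1:4] <- c(0.2, 0.6, 0.4, 0.8); w[1:4] <- c(1, 3, 2, 2)
  expect_equal(weighted_metric(m, w, c(1, 2)), 0.5)
  # uniform weights reduce to the mean
  wu <- array(1, dim(w))
  expect_equal(weighted_metric(m, wu, 1:4), mean(m[1:4]))
  # single voxel
  expect_equal(weighted_metric(m, w, 3), 0.4)
  # scale invariance and bounds
  set.seed(2)
  mv <- array(runif(27), c(3, 3, 3)); wv <- array(runif(27), c(3, 3, 3))
  v <- sample(27, 10)
  expect_equal(weighted_metric(mv, wv, v),
               weighted_metric(mv, array(7.3 * wv, dim(wv)), v))
  wm <- weighted_metric(mv, wv, v)
  expect_gte(wm, min(mv[v])); expect_lte(wm, max(mv[v]))
  # empty / zero weight -> flagged NA
  expect_true(is.na(weighted_metric(m, w, integer(0))))
  expect_equal(attr(weighted_metric(m, w, integer(0)), "flag"), "empty")
  w0 <- array(0, dim(w))
  expect_true(is.na(weighted_metric(m, w0, 1:2)))
})

test_that("profiles recover constant and linear planted fields", {
  sk <- straight_skeleton(40, 81)
  segs <- divide_segments(sk, 10, 0.2)
  dm <- c(11, 11, 24)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, 0)
  arr <- array(0, dm)
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  xyz <- alongtract:::voxels_to_world(idx, aff)
  inside <- xyz[, 1]^2 + xyz[, 2]^2 <= 36 & xyz[, 3] >= 0 & xyz[, 3] <= 40
  arr[idx[inside, ]] <- 1
  vol <- tract_volume(arr, aff, threshold = 0.5)
  lab <- assign_voxels(vol, sk, segs)
  lab$missing_segments <- rep(FALSE, 10)

  const_map <- array(0.6, dm)
  lin_map <- array(0, dm); lin_map[idx] <- 0.3 + 0.01 * xyz[, 3]
  part <- list(labels = lab, tract_prob = arr,
               metric_maps = list(NDI = const_map, ODI = const_map,
                                  FA = const_map, MD = lin_map))
  prof <- build_profiles(list(p1 = part, p2 = part))
  expect_equal(unname(prof$values[1, , "NDI"]), rep(0.6, 10))
  # two identical participants -> identical rows
  expect_equal(prof$values[1, , ], prof$values[2, , ])
  # linear gradient: segment means follow the gradient at segment midpoints
  mids <- rowMeans(segs$intervals)
  expect_equal(unname(prof$values[1, , "MD"]), 0.3 + 0.01 * mids,
               tolerance = 0.02 * mean(0.3 + 0.01 * mids))
})
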