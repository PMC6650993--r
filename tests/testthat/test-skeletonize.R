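test_that("cleaning removes isolated voxels, fills holes and merges near gaps", {
  # lone voxel -> removed -> empty-foreground error
  lone <- array(0, c(10, 10, 10)); lone[5, 5, 5] <- 1
  expect_error(clean_volume(tract_volume(lone, threshold = 0.5)),
               "empty foreground")

  # interior hole in a solid cube is restored by cavity filling
  cube <- array(1, c(14, 14, 14)); cube[7, 7, 7] <- 0
  arr <- array(0, c(20, 20, 20)); arr[4:17, 4:17, 4:17] <- cube
  out <- clean_volume(tract_volume(arr, threshold = 0.5))
  expect_equal(out$data[10, 10, 10], 1)

  # two parallel bars one voxel apart merge under a 2 mm kernel at 2 mm voxels
  bars <- array(0, c(12, 12, 20))
  bars[5, 5, 3:18] <- 1; bars[7, 5, 3:18] <- 1
  merged <- clean_volume(tract_volume(bars, voxel_mm = 2, threshold = 0.5))
  lab <- alongtract:::label_components(alongtract:::vol_foreground(merged), 26)
  expect_equal(max(lab), 1)
})

test_that("thinning reduces a bar to its axis and keeps single voxels", {
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  th <- thin_volume(tract_volume(array(as.numeric(single), dim(single)),
                                 threshold = 0.5))
  expect_equal(th$voxels, matrix(c(3, 3, 3), 1, dimnames = NULL),
               ignore_attr = TRUE)

  bar <- bar_volume()
  th <- thin_volume(bar)
  expect_gt(nrow(th$voxels), 35)
  expect_lt(nrow(th$voxels), 50)
  # within one voxel of the bar axis (x = y = centre)
  ctr <- (dim(bar$data)[1] + 1) / 2
  d_axis <- sqrt((th$voxels[, 1] - ctr)^2 + (th$voxels[, 2] - ctr)^2)
  expect_lte(max(d_axis), sqrt(2) + 1e-9)
})

test_that("thinning preserves components and tunnels (topology oracle)", {
  shapes <- list(
    cube = { a <- array(FALSE, c(12, 12, 12)); a[3:10, 3:10, 3:10] <- TRUE; a },
    bar = make_bar_mask(3, 3, 8, pad = 2),
    torus = make_torus_mask()
  )
  set.seed(5)
  for (k in 1:3) {   # random blobs: union of small balls
    a <- array(FALSE, c(14, 14, 14))
    for (b in 1:4) {
      c0 <- sample(4:11, 3, replace = TRUE)
      g <- which(array(TRUE, dim(a)), arr.ind = TRUE)
      d2 <- rowSums(sweep(g, 2, c0)^2)
      a[g[d2 <= 6.5, ]] <- TRUE
    }
    shapes[[paste0("blob", k)]] <- a
  }
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    lab <- alongtract:::label_components(m, 26)
    if (max(lab) != 1) m <- lab == 1      # keep largest for the precondition
    before <- count_topology(m)
    thin <- array(
      alongtract:::thin_volume_cpp(as.logical(m), dim(m)), dim(m))
    after <- count_topology(thin)
    expect_equal(after$components, before$components, info = nm)
    expect_equal(after$tunnels, before$tunnels, info = nm)
    expect_true(all(thin <= m), info = nm)   # skeleton is a subset
  }
})

test_that("torus thins to a ring and a pure loop has no prunable trunk", {
  m <- make_torus_mask()
  thin <- array(alongtract:::thin_volume_cpp(as.logical(m), dim(m)), dim(m))
  top <- count_topology(thin)
  expect_equal(top$components, 1)
  expect_equal(top$tunnels, 1)

  # an endpoint-free voxel loop cannot yield a trunk
  ring <- rbind(cbind(2:8, 2, 2), cbind(8, 3:8, 2), cbind(7:2, 8, 2),
                cbind(2, 7:3, 2))
  expect_error(prune_branches(ring), "loop|endpoint")
})

test_that("branch pruning returns the longest endpoint-to-endpoint path", {
  # brute-force oracle: BFS shortest paths between all endpoint pairs
  brute_trunk_length <- function(vox) {
    n <- nrow(vox)
    adj <- lapply(seq_len(n), function(i) {
      d <- abs(sweep(vox, 2, vox[i, ]))
      which(apply(d, 1, max) == 1)
    })
    deg <- lengths(adj)
    ends <- which(deg == 1)
    dist_w <- function(i, j) sqrt(sum((vox[i, ] - vox[j, ])^2))
    best <- 0; best_n <- 0
    for (a in ends) {
      # Dijkstra from a
      dist <- rep(Inf, n); dist[a] <- 0; done <- rep(FALSE, n)
      hops <- rep(0L, n)
      repeat {
        u <- which(!done & is.finite(dist))
        if (!length(u)) break
        u <- u[which.min(dist[u])]
        done[u] <- TRUE
        for (v in adj[[u]]) {
          nd <- dist[u] + dist_w(u, v)
          if (nd < dist[v]) { dist[v] <- nd; hops[v] <- hops[u] + 1L }
        }
      }
      for (b in ends) if (is.finite(dist[b]) && dist[b] > best) {
        best <- dist[b]; best_n <- hops[b] + 1L
      }
    }
    list(length = best, n_voxels = best_n)
  }

  mk <- function(arms) {
    # arms: list of step vectors; build from a centre voxel
    vox <- matrix(c(20, 20, 20), 1)
    for (arm in arms) {
      p <- c(20, 20, 20)
      for (s in seq_len(arm$len)) {
        p <- p + arm$dir
        vox <- rbind(vox, p)
      }
    }
    unique(vox)
  }
  y_shape <- mk(list(list(dir = c(0, 0, 1), len = 10),
                     list(dir = c(0, 0, -1), len = 10),
                     list(dir = c(1, 0, 0), len = 4)))
  x_shape <- mk(list(list(dir = c(0, 0, 1), len = 8),
                     list(dir = c(0, 0, -1), len = 8),
                     list(dir = c(1, 1, 0), len = 3),
                     list(dir = c(-1, 1, 0), len = 3)))
  straight <- mk(list(list(dir = c(0, 1, 0), len = 12)))

  for (vox in list(y_shape, x_shape, straight)) {
    trunk <- prune_branches(vox)
    oracle <- brute_trunk_length(vox)
    expect_equal(nrow(trunk), oracle$n_voxels)
    tl <- sum(sqrt(rowSums(diff(trunk)^2)))
    expect_equal(tl, oracle$length, tolerance = 1e-9)
  }
  # straight path is returned unchanged (up to orientation)
  trunk <- prune_branches(straight)
  expect_equal(nrow(trunk), nrow(straight))
})

test_that("spline fitting reproduces lines and arc lengths", {
  # collinear path -> exact line
  path <- cbind(5, 5, 2:30)
  sk <- fit_spline(path, affine = diag(c(2, 2, 2, 1)))
  dev <- max(abs(sk$curve[, 1] - 8)) + max(abs(sk$curve[, 2] - 8))
  expect_lt(dev, 1e-6)
  expect_equal(sk$arc_length, 28 * 2, tolerance = 1e-6)

  # quarter circle of radius 50 mm sampled at voxel centres (1 mm voxels)
  th <- seq(0, pi / 2, length.out = 80)
  qc <- cbind(round(50 * cos(th)) + 10, round(50 * sin(th)) + 10, 30)
  qc <- qc[!duplicated(qc), ]
  sk2 <- fit_spline(qc, affine = diag(4), n_samples = 300)
  expect_equal(sk2$arc_length, 25 * pi, tolerance = 0.02 * 25 * pi)

  # uniform arc-length spacing by construction
  sp <- sqrt(rowSums(diff(sk2$curve)^2))
  expect_lt((max(sp) - min(sp)) / mean(sp), 0.01)

  expect_error(fit_spline(cbind(1:3, 1, 1)), "too short")
})

test_that("clipping restricts and re-zeroes arc length", {
  sk <- straight_skeleton(100)
  same <- clip_skeleton(sk, 0, sk$arc_length)
  expect_equal(same$arc_length, 100)
  cl <- clip_skeleton(sk, 10, 30)
  expect_equal(cl$arc_length, 20)
  expect_equal(cl$arc[1], 0)
  expect_equal(max(cl$arc), 20)
  expect_equal(cl$curve[1, 3], 10)
  expect_equal(cl$curve[nrow(cl$curve), 3], 30)
  expect_error(clip_skeleton(sk, 50, 40), "invalid clip")
})
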