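# Brute-force digital-topology oracle for small grids (<= ~20^3): Euler
# characteristic from the cubical complex, components by flood fill, cavities
# as enclosed background components, tunnels from chi = comp + cavities - tunnels.

euler_characteristic <- function(mask) {
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0) return(0L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  verts <- edges <- faces <- character(0)
  corner_offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in seq_len(nrow(vox))) {
    v <- vox[i, ]
    corners <- sweep(corner_offs, 2, as.numeric(v), "+")  # 2x-scaled lattice
    verts <- c(verts, key(2 * corners))
    # 12 edges: midpoints of corner pairs differing in one coordinate
    for (d in 1:3) for (f1 in 0:1) for (f2 in 0:1) {
      mid <- 2 * v + switch(d,
        c(1, 2 * f1, 2 * f2), c(2 * f1, 1, 2 * f2), c(2 * f1, 2 * f2, 1))
      edges <- c(edges, paste(mid, collapse = ","))
    }
    # 6 faces: centres of the cube's faces
    for (d in 1:3) for (f in 0:1) {
      ctr <- 2 * v + c(1, 1, 1); ctr[d] <- 2 * v[d] + 2 * f
      faces <- c(faces, paste(ctr, collapse = ","))
    }
  }
  length(unique(verts)) - length(unique(edges)) + length(unique(faces)) -
    nrow(vox)
}

count_topology <- function(mask) {
  lab_fg <- alongtract:::label_components(mask, 26)
  n_comp <- max(lab_fg)
  lab_bg <- alongtract:::label_components(!mask, 6)
  dm <- dim(mask)
  border <- unique(c(lab_bg[1, , ], lab_bg[dm[1], , ], lab_bg[, 1, ],
                     lab_bg[, dm[2], ], lab_bg[, , 1], lab_bg[, , dm[3]]))
  n_cav <- length(setdiff(unique(as.integer(lab_bg[lab_bg > 0])), border))
  chi <- euler_characteristic(mask)
  list(components = n_comp, cavities = n_cav,
       tunnels = n_comp + n_cav - chi, euler = chi)
}

make_torus_mask <- function(n = 17, R = 5, r = 2) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  d <- (sqrt((g$x - ctr)^2 + (g$y - ctr)^2) - R)^2 + (g$z - ctr)^2
  array(d <= r^2, c(n, n, n))
}

make_bar_mask <- function(nx = 5, ny = 5, nz = 40, pad = 2) {
  m <- array(FALSE, c(nx + 2 * pad, ny + 2 * pad, nz + 2 * pad))
  m[pad + 1:nx, pad + 1:ny, pad + 1:nz] <- TRUE
  m
}

bar_volume <- function(...) {
  m <- make_bar_mask(...)
  tract_volume(array(as.numeric(m), dim(m)), threshold = 0.5)
}
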