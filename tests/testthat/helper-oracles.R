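# Independent brute-force oracles. These deliberately re-derive results
# with naive loops so they share no code with the implementation paths
# they check.

# count voxels >= threshold with an explicit loop
brute_count_ge <- function(arr, thr) {
  n <- 0L
  for (v in as.vector(arr)) if (v >= thr) n <- n + 1L
  n
}

# dilation / erosion / closing by a Euclidean ball, triple loops,
# zero-padded by the radius (matching the documented border contract)
brute_ball <- function(r) {
  offs <- list()
  for (i in -r:r) for (j in -r:r) for (k in -r:r)
    if (i^2 + j^2 + k^2 <= r^2) offs[[length(offs) + 1]] <- c(i, j, k)
  offs
}

brute_dilate <- function(m, r) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  offs <- brute_ball(r)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!m[i, j, k]) next
    for (o in offs) {
      p <- c(i, j, k) + o
      if (all(p >= 1) && all(p <= d)) out[p[1], p[2], p[3]] <- TRUE
    }
  }
  out
}

brute_erode <- function(m, r) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  offs <- brute_ball(r)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    keep <- TRUE
    for (o in offs) {
      p <- c(i, j, k) + o
      if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) {
        keep <- FALSE
        break
      }
    }
    out[i, j, k] <- keep
  }
  out
}

brute_close <- function(m, r) {
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2 * r)
  pad[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] <- m
  res <- brute_erode(brute_dilate(pad, r), r)
  res[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])]
}

# 6-connected component count by breadth-first search
brute_components6 <- function(m) {
  d <- dim(m)
  seen <- array(FALSE, dim = d)
  nbrs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  ncomp <- 0L
  idx <- which(m)
  for (s in idx) {
    p0 <- arrayInd(s, d)
    if (seen[p0]) next
    ncomp <- ncomp + 1L
    queue <- list(as.integer(p0))
    seen[p0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (q in 1:6) {
        w <- p + nbrs[q, ]
        if (any(w < 1) || any(w > d)) next
        if (m[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  ncomp
}

# per-face summation of triangle areas (cm^2), explicit loop
brute_mesh_area <- function(mesh) {
  tot <- 0
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[f, ], ]
    u <- tri[2, ] - tri[1, ]
    w <- tri[3, ] - tri[1, ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    tot <- tot + 0.5 * sqrt(sum(cr^2))
  }
  tot / 100
}

# axis-aligned cube surface mesh of side s (mm) with corner at origin;
# optionally without the top (z = s) face
cube_mesh <- function(s = 10, drop_top = FALSE) {
  V <- as.matrix(expand.grid(x = c(0, s), y = c(0, s), z = c(0, s)))
  # vertex indices: 1:(0,0,0) 2:(s,0,0) 3:(0,s,0) 4:(s,s,0)
  #                 5:(0,0,s) 6:(s,0,s) 7:(0,s,s) 8:(s,s,s)
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom
    c(5, 6, 7), c(6, 8, 7),   # top
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = s
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = s
  if (drop_top) F <- F[-c(3, 4), ]
  triangle_mesh(V, F)
}

# random rigid rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# translate all geometry in a set of partition rules
translate_rules <- function(rules, v) {
  partition_rules(
    hamulus_left = rules$hamulus_left + v,
    hamulus_right = rules$hamulus_right + v,
    maxillary_ridge_curve = sweep(rules$maxillary_ridge_curve, 2, v, "+"),
    mandibular_ridge_curve = sweep(rules$mandibular_ridge_curve, 2, v, "+"),
    lip_crease_plane = list(point = rules$lip_crease_plane$point + v,
                            normal = rules$lip_crease_plane$normal),
    occlusal_plane = list(point = rules$occlusal_plane$point + v,
                          normal = rules$occlusal_plane$normal),
    tooth_seeds = if (nrow(rules$tooth_seeds)) sweep(rules$tooth_seeds, 2,
                                                     v, "+")
    else rules$tooth_seeds,
    tooth_radius_mm = rules$tooth_radius_mm)
}

# small soft-tissue sphere phantom (r mm at `spacing` mm voxels)
sphere_phantom_spec <- function(r = 10, spacing = 0.3, margin = 3,
                                bubble_count = 0, noise_sd_hu = 0) {
  side <- 2 * (r + margin)
  phantom_spec(grid_shape = rep(ceiling(side / spacing), 3),
               voxel_spacing_mm = rep(spacing, 3),
               primitives = list(phantom_primitive(
                 "sphere", rep(r + margin, 3), r, "SOFT_TISSUE", "TONGUE")),
               bubble_count = bubble_count, noise_sd_hu = noise_sd_hu)
}
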