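#' @useDynLib oralarea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd median pt pf var
NULL

# material / region integer codes used in the phantom grids
MATERIALS <- c("AIR", "SOFT_TISSUE", "BONE", "STYROFOAM")
REGIONS <- c("PALATE", "TONGUE", "HARD_TISSUE", "MUCOSA", "EXCLUDED")
LABEL_LEVELS <- c("AIR", REGIONS[1:4])

#' Phantom primitive
#'
#' One geometric solid of the phantom. Supported shapes and their size
#' parameters (mm): `sphere` (radius), `dome` (radius of a hemisphere whose
#' flat base is the horizontal disk at `center`, curving upward in +z),
#' `ellipsoid` (three semi-axes), `cylinder` (radius and height, axis along
#' z), `box` (three edge lengths, centred on `center`).
#'
#' @param shape one of `"sphere"`, `"dome"`, `"ellipsoid"`, `"cylinder"`,
#'   `"box"`.
#' @param center numeric triple, world mm.
#' @param size numeric size parameters in mm (see above).
#' @param material `"SOFT_TISSUE"`, `"BONE"` or `"STYROFOAM"`.
#' @param region region label carried into the ground truth, one of
#'   `"PALATE"`, `"TONGUE"`, `"HARD_TISSUE"`, `"MUCOSA"`.
#' @return an object of class `phantom_primitive`.
#' @export
phantom_primitive <- function(shape, center, size, material = "SOFT_TISSUE",
                              region = "MUCOSA") {
  shape <- match.arg(shape, c("sphere", "dome", "ellipsoid", "cylinder",
                              "box"))
  material <- match.arg(material, MATERIALS[-1])
  region <- match.arg(region, REGIONS[1:4])
  center <- as.numeric(center)
  size <- as.numeric(size)
  need <- switch(shape, sphere = 1L, dome = 1L, ellipsoid = 3L,
                 cylinder = 2L, box = 3L)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be a finite triple")
  if (length(size) != need || any(size <= 0))
    stop(sprintf("shape '%s' needs %d positive size parameter(s)", shape,
                 need))
  structure(list(shape = shape, center = center, size = size,
                 material = material, region = region),
            class = "phantom_primitive")
}

#' Analytic surface area and volume of a primitive
#'
#' Closed forms for sphere, dome (curved cap plus flat base), cylinder
#' (lateral plus both caps) and box; the ellipsoid area is evaluated by a
#' dense deterministic quadrature of the first-fundamental-form integral
#' (relative error well below 1e-6).
#'
#' @param p a [phantom_primitive()].
#' @return area in mm^2 / volume in mm^3.
#' @export
primitive_area <- function(p) {
  stopifnot(inherits(p, "phantom_primitive"))
  s <- p$size
  switch(p$shape,
         sphere = 4 * pi * s[1]^2,
         dome = 3 * pi * s[1]^2,
         cylinder = 2 * pi * s[1] * s[2] + 2 * pi * s[1]^2,
         box = 2 * (s[1] * s[2] + s[2] * s[3] + s[1] * s[3]),
         ellipsoid = ellipsoid_area(s[1], s[2], s[3]))
}

#' @rdname primitive_area
#' @export
primitive_volume <- function(p) {
  stopifnot(inherits(p, "phantom_primitive"))
  s <- p$size
  switch(p$shape,
         sphere = 4 / 3 * pi * s[1]^3,
         dome = 2 / 3 * pi * s[1]^3,
         cylinder = pi * s[1]^2 * s[2],
         box = prod(s),
         ellipsoid = 4 / 3 * pi * s[1] * s[2] * s[3])
}

# trapezoid quadrature of the ellipsoid surface integral in spherical
# parametrisation
ellipsoid_area <- function(a, b, c, n = 1200L) {
  theta <- seq(0, pi, length.out = n)
  phi <- seq(0, 2 * pi, length.out = n)
  st <- sin(theta)
  ct <- cos(theta)
  cp2 <- cos(phi)^2
  sp2 <- sin(phi)^2
  # |r_theta x r_phi| = st * sqrt(b^2 c^2 st^2 cp^2 + a^2 c^2 st^2 sp^2
  #                               + a^2 b^2 ct^2)
  f <- outer(st^2, b^2 * c^2 * cp2 + a^2 * c^2 * sp2) +
    outer(ct^2, rep(a^2 * b^2, length(phi)))
  integrand <- st * sqrt(f)
  wt <- rep(1, n); wt[c(1, n)] <- 0.5
  ht <- pi / (n - 1); hp <- 2 * pi / (n - 1)
  sum((wt * integrand) %*% wt) * ht * hp
}

#' Phantom specification
#'
#' Describes a CBCT-like scene: a voxel grid, a list of solid primitives
#' painted into it in order (later primitives overwrite earlier ones where
#' they overlap, so nested structures are listed outer first), a material
#' to HU table, optional trapped air bubbles inside soft tissue, and
#' additive Gaussian HU noise. Default HU values put soft tissue (+40) and
#' bone (+1200) on opposite sides of the 350 HU bone threshold while both
#' clear the -300 HU soft-tissue threshold, and styrofoam (-980) stays
#' radiolucent, below it.
#'
#' @param grid_shape integer triple of voxel counts.
#' @param primitives list of [phantom_primitive()] objects.
#' @param voxel_spacing_mm positive triple, default 0.3 mm isotropic.
#' @param origin_mm world position of voxel `[1,1,1]`.
#' @param hu_table named HU values for AIR, SOFT_TISSUE, BONE, STYROFOAM.
#' @param bubble_count number of air bubbles to seed strictly inside soft
#'   tissue.
#' @param bubble_radius_mm bubble radius, default 0.5 mm.
#' @param noise_sd_hu standard deviation of additive Gaussian HU noise.
#' @param landmarks optional named list of 3-D points (mm) emitted into the
#'   ground truth as a [landmark_set()].
#' @param rules optional [partition_rules()] describing how the scene
#'   should be partitioned; carried into the truth for pipeline tests.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, primitives = list(),
                         voxel_spacing_mm = c(0.3, 0.3, 0.3),
                         origin_mm = c(0, 0, 0),
                         hu_table = c(AIR = -1000, SOFT_TISSUE = 40,
                                      BONE = 1200, STYROFOAM = -980),
                         bubble_count = 0L, bubble_radius_mm = 0.5,
                         noise_sd_hu = 0, landmarks = NULL, rules = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("grid_shape must be a triple of counts >= 2")
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel spacing must be strictly positive")
  if (!all(MATERIALS %in% names(hu_table)))
    stop("hu_table must name AIR, SOFT_TISSUE, BONE and STYROFOAM")
  if (bubble_count < 0) stop("bubble_count must be >= 0")
  if (bubble_radius_mm <= 0) stop("bubble_radius_mm must be positive")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  for (p in primitives)
    if (!inherits(p, "phantom_primitive"))
      stop("primitives must be phantom_primitive objects")
  structure(list(grid_shape = grid_shape, primitives = primitives,
                 voxel_spacing_mm = voxel_spacing_mm,
                 origin_mm = as.numeric(origin_mm),
                 hu_table = hu_table[MATERIALS],
                 bubble_count = as.integer(bubble_count),
                 bubble_radius_mm = bubble_radius_mm,
                 noise_sd_hu = noise_sd_hu,
                 landmarks = landmarks, rules = rules),
            class = "phantom_spec")
}

# logical sub-grid membership of one primitive; xs/ys/zs are voxel-centre
# coordinate vectors. Returns list(ix, iy, iz, inside).
primitive_membership <- function(p, xs, ys, zs) {
  bb <- switch(p$shape,
               sphere = rbind(p$center - p$size[1], p$center + p$size[1]),
               dome = rbind(c(p$center[1:2] - p$size[1], p$center[3]),
                            p$center + p$size[1]),
               ellipsoid = rbind(p$center - p$size, p$center + p$size),
               cylinder = rbind(p$center - c(p$size[1], p$size[1],
                                             p$size[2] / 2),
                                p$center + c(p$size[1], p$size[1],
                                             p$size[2] / 2)),
               box = rbind(p$center - p$size / 2, p$center + p$size / 2))
  ix <- which(xs >= bb[1, 1] & xs <= bb[2, 1])
  iy <- which(ys >= bb[1, 2] & ys <= bb[2, 2])
  iz <- which(zs >= bb[1, 3] & zs <= bb[2, 3])
  if (!length(ix) || !length(iy) || !length(iz))
    return(list(ix = ix, iy = iy, iz = iz, inside = NULL))
  dx <- xs[ix] - p$center[1]
  dy <- ys[iy] - p$center[2]
  dz <- zs[iz] - p$center[3]
  inside <- switch(p$shape,
    sphere = outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= p$size[1]^2,
    dome = {
      m <- outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= p$size[1]^2
      m & rep(dz >= 0, each = length(ix) * length(iy))
    },
    ellipsoid = outer(outer((dx / p$size[1])^2, (dy / p$size[2])^2, "+"),
                      (dz / p$size[3])^2, "+") <= 1,
    cylinder = {
      rad <- outer(dx^2, dy^2, "+") <= p$size[1]^2
      hgt <- abs(dz) <= p$size[2] / 2
      outer(rad, hgt, "&")
    },
    box = {
      okx <- abs(dx) <= p$size[1] / 2
      oky <- abs(dy) <= p$size[2] / 2
      okz <- abs(dz) <= p$size[3] / 2
      outer(outer(okx, oky, "&"), okz, "&")
    })
  if (p$shape == "dome") inside <- array(inside, dim = c(length(ix),
                                                         length(iy),
                                                         length(iz)))
  list(ix = ix, iy = iy, iz = iz, inside = inside)
}

# world bounding box of a primitive, rows = (min, max)
primitive_bbox <- function(p) {
  switch(p$shape,
         sphere = rbind(p$center - p$size[1], p$center + p$size[1]),
         dome = rbind(c(p$center[1:2] - p$size[1], p$center[3]),
                      p$center + p$size[1]),
         ellipsoid = rbind(p$center - p$size, p$center + p$size),
         cylinder = rbind(p$center - c(p$size[1], p$size[1], p$size[2] / 2),
                          p$center + c(p$size[1], p$size[1], p$size[2] / 2)),
         box = rbind(p$center - p$size / 2, p$center + p$size / 2))
}

#' Generate a phantom volume with analytic ground truth
#'
#' Paints the primitives of `spec` into the voxel grid (membership decided
#' by voxel-centre inclusion; no partial-volume averaging, so the analytic
#' truth stays exact), carves the requested number of air bubbles at
#' seeded random positions strictly inside soft tissue, assigns HU per
#' material, and adds Gaussian noise. The returned truth carries analytic
#' per-region surface areas from the primitive closed forms, the voxel
#' label and material grids, landmarks, and the bubble centres. The same
#' `(spec, seed)` pair reproduces the output bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed for bubbles and noise.
#' @return list with elements `volume` ([hu_volume()]) and `truth`
#'   (class `phantom_truth`: `region_area_cm2`, `voxel_labels`,
#'   `voxel_materials`, `landmarks`, `rules`, `bubble_centers_mm`, `seed`).
#' @export
generate_oral_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing_mm
  org <- spec$origin_mm
  d <- spec$grid_shape
  xs <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  lo <- org
  hi <- org + (d - 1) * sp

  materials <- array(1L, dim = d)   # AIR
  labels <- array(1L, dim = d)      # AIR
  areas <- setNames(numeric(4), REGIONS[1:4])
  for (n in seq_along(spec$primitives)) {
    p <- spec$primitives[[n]]
    bb <- primitive_bbox(p)
    if (any(bb[1, ] < lo - 1e-9) || any(bb[2, ] > hi + 1e-9))
      stop(sprintf("primitive %d (%s, region %s) extends outside the grid",
                   n, p$shape, p$region))
    mem <- primitive_membership(p, xs, ys, zs)
    if (!is.null(mem$inside) && any(mem$inside)) {
      mcode <- match(p$material, MATERIALS)
      lcode <- match(p$region, LABEL_LEVELS)
      sub_m <- materials[mem$ix, mem$iy, mem$iz, drop = FALSE]
      sub_l <- labels[mem$ix, mem$iy, mem$iz, drop = FALSE]
      sub_m[mem$inside] <- mcode
      sub_l[mem$inside] <- lcode
      materials[mem$ix, mem$iy, mem$iz] <- sub_m
      labels[mem$ix, mem$iy, mem$iz] <- sub_l
    }
    areas[p$region] <- areas[p$region] + primitive_area(p)
  }

  bubble_centers <- matrix(numeric(0), ncol = 3)
  vol_data <- NULL
  with_seed(seed, {
    # bubbles: rejection-sample voxel centres whose whole neighbourhood
    # (bubble radius plus one voxel margin) is soft tissue, and keep
    # accepted bubbles disjoint
    if (spec$bubble_count > 0L) {
      rb <- spec$bubble_radius_mm
      soft_idx <- which(materials == 2L)
      if (!length(soft_idx)) stop("no soft tissue to host bubbles")
      guard_vox <- ceiling((rb + max(sp)) / sp)
      gg <- expand.grid(i = -guard_vox[1]:guard_vox[1],
                        j = -guard_vox[2]:guard_vox[2],
                        k = -guard_vox[3]:guard_vox[3])
      keep <- (gg$i * sp[1])^2 + (gg$j * sp[2])^2 + (gg$k * sp[3])^2 <=
        (rb + max(sp))^2
      guard <- as.matrix(gg[keep, , drop = FALSE])
      min_sep2 <- (2 * rb + 2 * max(sp))^2
      centers <- matrix(NA_real_, nrow = spec$bubble_count, ncol = 3)
      for (b in seq_len(spec$bubble_count)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          v <- soft_idx[sample.int(length(soft_idx), 1L)]
          ijk <- arrayInd(v, d)
          nb <- sweep(guard, 2L, as.integer(ijk), "+")
          if (any(nb < 1L) || any(nb[, 1] > d[1]) || any(nb[, 2] > d[2]) ||
              any(nb[, 3] > d[3])) next
          if (!all(materials[nb] == 2L)) next
          ctr <- org + (ijk - 1) * sp
          if (b > 1L) {
            prev <- centers[seq_len(b - 1L), , drop = FALSE]
            if (any(rowSums(sweep(prev, 2L, ctr, "-")^2) < min_sep2)) next
          }
          centers[b, ] <- ctr
          placed <- TRUE
          break
        }
        if (!placed)
          stop(sprintf("bubble %d could not be placed after 1000 retries", b))
      }
      bubble_centers <- centers
      # carve the bubbles
      rvox <- ceiling(rb / sp)
      cg <- expand.grid(i = -rvox[1]:rvox[1], j = -rvox[2]:rvox[2],
                        k = -rvox[3]:rvox[3])
      cg <- as.matrix(cg[(cg$i * sp[1])^2 + (cg$j * sp[2])^2 +
                           (cg$k * sp[3])^2 <= rb^2, , drop = FALSE])
      for (b in seq_len(nrow(centers))) {
        ijk <- round((centers[b, ] - org) / sp) + 1
        nb <- sweep(cg, 2L, as.integer(ijk), "+")
        materials[nb] <- 1L
        labels[nb] <- 1L
      }
    }
    vals <- spec$hu_table[materials]
    if (spec$noise_sd_hu > 0)
      vals <- vals + rnorm(length(vals), sd = spec$noise_sd_hu)
    vol_data <- array(vals, dim = d)
  })

  lm <- if (!is.null(spec$landmarks)) landmark_set(spec$landmarks) else NULL
  truth <- structure(list(
    region_area_cm2 = areas / 100,
    voxel_labels = structure(labels, levels = LABEL_LEVELS),
    voxel_materials = structure(materials, levels = MATERIALS),
    landmarks = lm, rules = spec$rules,
    bubble_centers_mm = bubble_centers, seed = as.integer(seed)),
    class = "phantom_truth")
  list(volume = hu_volume(vol_data, sp, org), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n  analytic areas (cm^2):\n")
  for (r in names(x$region_area_cm2))
    cat(sprintf("    %-12s %8.3f\n", r, x$region_area_cm2[[r]]))
  cat(sprintf("  bubbles: %d, seed: %d\n", nrow(x$bubble_centers_mm),
              x$seed))
  invisible(x)
}

#' Oral cavity phantom specification
#'
#' A ready-made scene emulating a dried, styrofoam-separated oral cavity
#' at CBCT resolution: a hemispherical palatal dome above the occlusal
#' plane, a spherical tongue below it, a set of spherical bone "teeth"
#' (crown plus alveolus lumps) in a posterior band, and a large box of
#' remaining mucosa in an anterior band, all separated by air gaps wider
#' than the closing element. Landmark-driven partition rules (pterygoid
#' hamuli, occlusal plane, ridge polygons, lip-crease plane, tooth seeds)
#' matching the scene are attached, so the end-to-end pipeline can be
#' checked against the analytic truth. `"standard"` is a 75 x 88 x 70 mm
#' field of view; `"compact"` is a smaller, faster scene for ensembles.
#'
#' @param size `"standard"` or `"compact"`.
#' @param n_teeth number of bone teeth to keep (0 for an edentulous
#'   scene); at most 8 (standard) or 4 (compact).
#' @param jitter_frac relative size/position jitter applied per structure
#'   (uniform in `1 +/- jitter_frac`), for ensemble studies.
#' @param jitter_seed RNG seed for the jitter draws.
#' @param bubble_count,noise_sd_hu,voxel_spacing_mm passed to
#'   [phantom_spec()]; spacing defaults to 0.3 mm isotropic.
#' @return a [phantom_spec()] with landmarks and partition rules attached.
#' @export
oral_phantom_spec <- function(size = c("standard", "compact"),
                              n_teeth = NULL, jitter_frac = 0,
                              jitter_seed = 1L, bubble_count = 25L,
                              noise_sd_hu = 0,
                              voxel_spacing_mm = c(0.3, 0.3, 0.3)) {
  size <- match.arg(size)
  if (size == "standard") {
    grid_mm <- c(75, 87.6, 70.2)
    dome <- list(center = c(35, 45, 52), r = 14.6)
    tongue <- list(center = c(35, 45, 32), r = 14)
    mucosa <- list(center = c(35, 78, 32), size = c(60, 12, 60))
    tooth_r <- 5
    tooth_centers <- as.matrix(expand.grid(x = c(11, 27, 43, 59), y = 10,
                                           z = c(20, 44)))
    hamuli <- list(left = c(20, 22, 52), right = c(50, 22, 52))
    occlusal_z <- 49
    poly_x <- c(15, 55); poly_y <- c(25, 65)
    lip_y <- 95
    max_teeth <- 8L
  } else {
    grid_mm <- c(42, 54, 45)
    dome <- list(center = c(21, 27, 33), r = 9)
    tongue <- list(center = c(21, 27, 20), r = 9)
    mucosa <- list(center = c(21, 47, 20), size = c(36, 8, 36))
    tooth_r <- 4
    tooth_centers <- as.matrix(expand.grid(x = c(8, 34), y = 6,
                                           z = c(14, 30)))
    hamuli <- list(left = c(12, 14, 33), right = c(30, 14, 33))
    occlusal_z <- 31
    poly_x <- c(10, 32); poly_y <- c(16, 38)
    lip_y <- 53
    max_teeth <- 4L
  }
  if (is.null(n_teeth)) n_teeth <- max_teeth
  n_teeth <- as.integer(n_teeth)
  if (n_teeth < 0L || n_teeth > max_teeth)
    stop(sprintf("n_teeth must be between 0 and %d", max_teeth))

  jf <- function() if (jitter_frac > 0) runif(1, 1 - jitter_frac,
                                              1 + jitter_frac) else 1
  prims <- with_seed(jitter_seed, {
    out <- list(
      phantom_primitive("box", mucosa$center, mucosa$size * jf(),
                        "SOFT_TISSUE", "MUCOSA"),
      phantom_primitive("sphere", tongue$center, tongue$r * jf(),
                        "SOFT_TISSUE", "TONGUE"),
      phantom_primitive("dome", dome$center, dome$r * jf(),
                        "SOFT_TISSUE", "PALATE"))
    for (t in seq_len(n_teeth))
      out <- c(out, list(phantom_primitive("sphere", tooth_centers[t, ],
                                           tooth_r * jf(), "BONE",
                                           "HARD_TISSUE")))
    out
  })
  seeds <- if (n_teeth > 0)
    tooth_centers[seq_len(n_teeth), , drop = FALSE]
  else matrix(numeric(0), ncol = 3)
  lm <- list(pterygoid_hamulus_left = hamuli$left,
             pterygoid_hamulus_right = hamuli$right)
  rules <- partition_rules(
    hamulus_left = hamuli$left, hamulus_right = hamuli$right,
    maxillary_ridge_curve = rbind(
      c(poly_x[1], poly_y[1], occlusal_z + 2),
      c(poly_x[2], poly_y[1], occlusal_z + 2),
      c(poly_x[2], poly_y[2], occlusal_z + 2),
      c(poly_x[1], poly_y[2], occlusal_z + 2)),
    mandibular_ridge_curve = rbind(
      c(poly_x[1], poly_y[1], occlusal_z - 2),
      c(poly_x[2], poly_y[1], occlusal_z - 2),
      c(poly_x[2], poly_y[2], occlusal_z - 2),
      c(poly_x[1], poly_y[2], occlusal_z - 2)),
    lip_crease_plane = list(point = c(grid_mm[1] / 2, lip_y, grid_mm[3] / 2),
                            normal = c(0, 1, 0)),
    occlusal_plane = list(point = c(grid_mm[1] / 2, grid_mm[2] / 2,
                                    occlusal_z),
                          normal = c(0, 0, 1)),
    tooth_seeds = seeds)
  phantom_spec(grid_shape = ceiling(grid_mm / voxel_spacing_mm),
               primitives = prims, voxel_spacing_mm = voxel_spacing_mm,
               bubble_count = bubble_count, bubble_radius_mm = 0.5,
               noise_sd_hu = noise_sd_hu, landmarks = lm, rules = rules)
}

#' Simulate a subjects-by-raters measurement table
#'
#' Draws `values[i, j] = mu + s_i + r_j + e_ij` with subject, rater and
#' error effects from independent zero-mean normals of the given
#' variances. The implied population two-way absolute-agreement
#' average-measures intraclass correlation is
#' `sigma_s^2 / (sigma_s^2 + (sigma_r^2 + sigma_e^2) / k)`.
#'
#' @param n_subjects number of subjects (rows), at least 2.
#' @param variance_components numeric triple `(subject, rater, error)` of
#'   non-negative variances; subject variance must be positive.
#' @param n_raters number of raters / repeats (columns), at least 2.
#' @param seed RNG seed.
#' @param mu grand mean, default 10.
#' @return a [measurement_table()] with `column_kind = "rater"`.
#' @export
generate_rater_table <- function(n_subjects, variance_components, n_raters,
                                 seed = 1L, mu = 10) {
  if (n_subjects < 2L || n_raters < 2L)
    stop("need at least 2 subjects and 2 raters")
  v <- as.numeric(variance_components)
  if (length(v) != 3L || any(v < 0)) stop("variances must be non-negative")
  if (v[1] <= 0) stop("subject variance must be positive")
  with_seed(seed, {
    s <- rnorm(n_subjects, sd = sqrt(v[1]))
    r <- rnorm(n_raters, sd = sqrt(v[2]))
    e <- matrix(rnorm(n_subjects * n_raters, sd = sqrt(v[3])),
                n_subjects, n_raters)
    vals <- mu + outer(s, r, "+") + e
    measurement_table(vals, column_kind = "rater")
  })
}

#' Simulate a bivariate normal sample with target correlation
#'
#' @param n sample size, at least 3.
#' @param r_target population correlation in `[-1, 1]`.
#' @param seed RNG seed.
#' @return data frame with columns `x` and `y`.
#' @export
generate_correlated_pairs <- function(n, r_target, seed = 1L) {
  if (n < 3L) stop("need n >= 3")
  if (!is.finite(r_target) || abs(r_target) > 1)
    stop("|r_target| must be <= 1")
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    data.frame(x = z1, y = r_target * z1 + sqrt(1 - r_target^2) * z2)
  })
}

#' Synthetic craniofacial landmark set
#'
#' A fixed head geometry (world mm, x lateral, y anterior, z superior)
#' whose pairwise landmark distances land at the scale of adult
#' craniofacial measurements (head length about 23 cm, head width about
#' 16 cm, palatal width about 4.3 cm), with optional isotropic Gaussian
#' digitisation noise per coordinate to emulate repeated caliper
#' measurements.
#'
#' @param seed RNG seed for the noise.
#' @param noise_sd_mm per-coordinate noise standard deviation, default 0.
#' @return a [landmark_set()].
#' @export
generate_head_landmarks <- function(seed = 1L, noise_sd_mm = 0) {
  base <- list(
    vertex = c(0, 30, 240),
    gnathion = c(0, 80, 15),
    glabella = c(0, 95, 155),
    subnasale = c(0, 98, 95),
    chelion_left = c(-28, 95, 72),
    chelion_right = c(28, 95, 72),
    tragus = c(75, 5, 118),
    ext_auditory_meatus_left = c(-79, 0, 120),
    ext_auditory_meatus_right = c(79, 0, 120),
    upper_lip = c(0, 100, 74),
    lower_lip = c(0, 99, 60),
    back_of_head = c(0, -90, 140),
    molar_16 = c(21.5, 60, 70),
    molar_26 = c(-21.5, 60, 70),
    ridge_estimate_16 = c(21, 60, 72),
    ridge_estimate_26 = c(-21, 60, 72),
    pterygoid_hamulus_left = c(-17, 45, 75),
    pterygoid_hamulus_right = c(17, 45, 75))
  if (noise_sd_mm > 0)
    base <- with_seed(seed, lapply(base, function(p)
      p + rnorm(3, sd = noise_sd_mm)))
  landmark_set(base)
}
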