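#' Landmark-driven partition rules
#'
#' Geometric rules formalizing the anatomical separation of the intra-oral
#' surface into four regions. "Top view" means orthographic projection
#' along the occlusal-plane normal; the anterior direction is the
#' lip-crease-plane normal projected into the occlusal plane.
#'
#' @param hamulus_left,hamulus_right 3-D points (mm) of the pterygoid
#'   hamuli; together they fix the posterior limit of palate and tongue.
#' @param maxillary_ridge_curve,mandibular_ridge_curve ordered 3-D point
#'   lists (matrices, one point per row) whose top-view projections bound
#'   the palatal and lingual fields laterally/anteriorly.
#' @param lip_crease_plane list with `point` and `normal`; faces beyond
#'   the plane (positive side of the normal) are excluded, mirroring the
#'   crease left by a lip retractor.
#' @param occlusal_plane list with `point` and `normal` (normal pointing
#'   toward the maxilla); splits maxillary from mandibular faces.
#' @param tooth_seeds matrix of 3-D points marking crowns in situ and the
#'   alveoli of extracted teeth; may have zero rows (edentulous).
#' @param tooth_radius_mm capture radius around each tooth seed, default
#'   6 mm.
#' @return an object of class `partition_rules`.
#' @export
partition_rules <- function(hamulus_left, hamulus_right,
                            maxillary_ridge_curve, mandibular_ridge_curve,
                            lip_crease_plane, occlusal_plane,
                            tooth_seeds = matrix(numeric(0), ncol = 3),
                            tooth_radius_mm = 6) {
  hamulus_left <- as.numeric(hamulus_left)
  hamulus_right <- as.numeric(hamulus_right)
  if (length(hamulus_left) != 3L || length(hamulus_right) != 3L)
    stop("hamuli must be 3-D points")
  if (all(hamulus_left == hamulus_right)) stop("hamuli must be distinct")
  norm1 <- function(v) {
    v <- as.numeric(v)
    n <- sqrt(sum(v^2))
    if (n == 0) stop("plane normal must be non-zero")
    v / n
  }
  chk_plane <- function(pl) {
    if (!is.list(pl) || is.null(pl$point) || is.null(pl$normal))
      stop("planes need `point` and `normal`")
    list(point = as.numeric(pl$point), normal = norm1(pl$normal))
  }
  chk_curve <- function(m) {
    m <- matrix(as.numeric(m), ncol = 3)
    if (nrow(m) < 3L) stop("ridge curves need at least 3 points")
    m
  }
  tooth_seeds <- matrix(as.numeric(tooth_seeds), ncol = 3)
  if (tooth_radius_mm <= 0) stop("tooth radius must be positive")
  structure(list(hamulus_left = hamulus_left,
                 hamulus_right = hamulus_right,
                 maxillary_ridge_curve = chk_curve(maxillary_ridge_curve),
                 mandibular_ridge_curve = chk_curve(mandibular_ridge_curve),
                 lip_crease_plane = chk_plane(lip_crease_plane),
                 occlusal_plane = chk_plane(occlusal_plane),
                 tooth_seeds = tooth_seeds,
                 tooth_radius_mm = tooth_radius_mm),
            class = "partition_rules")
}

# 2-D point-in-polygon (even-odd rule), vectorised over points
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}

# orthonormal in-plane basis (u, v) for a unit normal n
plane_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

#' Partition a surface mesh into anatomical regions
#'
#' Assigns every face (by its centroid) exactly one of PALATE, TONGUE,
#' HARD_TISSUE, MUCOSA or EXCLUDED, with precedence HARD_TISSUE > PALATE >
#' TONGUE > MUCOSA. HARD_TISSUE captures faces within the tooth radius of
#' any seed; PALATE requires the maxillary side of the occlusal plane, a
#' top-view position inside the maxillary ridge polygon, and a position
#' anterior to the trans-hamular plane; TONGUE mirrors this on the
#' mandibular side with the mandibular polygon; everything else is MUCOSA
#' unless it lies beyond the lip-crease plane, which marks it EXCLUDED.
#'
#' @param mesh a non-empty [triangle_mesh()].
#' @param rules a [partition_rules()].
#' @return object of class `region_labeling`: integer vector (one entry
#'   per face) with a `levels` attribute over the five labels.
#' @export
partition_regions <- function(mesh, rules) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(rules,
                                                      "partition_rules"))
  if (nrow(mesh$faces) == 0) stop("mesh has no faces")
  V <- mesh$vertices
  F <- mesh$faces
  C <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3

  occ <- rules$occlusal_plane
  lip <- rules$lip_crease_plane
  n_occ <- occ$normal
  # anterior axis: lip normal projected into the occlusal plane
  ant <- lip$normal - sum(lip$normal * n_occ) * n_occ
  if (sqrt(sum(ant^2)) < 1e-9)
    stop("lip-crease normal is parallel to the occlusal normal")
  ant <- ant / sqrt(sum(ant^2))
  ham_mid <- (rules$hamulus_left + rules$hamulus_right) / 2

  basis <- plane_basis(n_occ)
  proj <- function(P) cbind(P %*% basis$u, P %*% basis$v)
  Cp <- proj(C)
  maxp <- proj(rules$maxillary_ridge_curve)
  manp <- proj(rules$mandibular_ridge_curve)

  side_occ <- as.vector((C - matrix(occ$point, nrow(C), 3,
                                    byrow = TRUE)) %*% n_occ)
  ant_ham <- as.vector((C - matrix(ham_mid, nrow(C), 3,
                                   byrow = TRUE)) %*% ant)
  beyond_lip <- as.vector((C - matrix(lip$point, nrow(C), 3,
                                      byrow = TRUE)) %*% lip$normal) > 0

  lab <- rep(4L, nrow(C))  # MUCOSA
  lab[beyond_lip] <- 5L    # EXCLUDED

  in_max <- points_in_polygon(Cp[, 1], Cp[, 2], maxp[, 1], maxp[, 2])
  in_man <- points_in_polygon(Cp[, 1], Cp[, 2], manp[, 1], manp[, 2])
  tongue <- side_occ <= 0 & in_man & ant_ham >= 0
  palate <- side_occ > 0 & in_max & ant_ham >= 0
  lab[tongue] <- 2L
  lab[palate] <- 1L

  if (nrow(rules$tooth_seeds) > 0) {
    r2 <- rules$tooth_radius_mm^2
    near <- rep(FALSE, nrow(C))
    for (s in seq_len(nrow(rules$tooth_seeds)))
      near <- near | rowSums(sweep(C, 2, rules$tooth_seeds[s, ])^2) <= r2
    lab[near] <- 3L
  }
  structure(lab, levels = REGIONS, class = "region_labeling")
}

#' Per-region surface areas
#'
#' Sums face areas per region label; the reported total is the sum of the
#' four anatomical regions, with EXCLUDED kept separate.
#'
#' @param mesh a [triangle_mesh()].
#' @param labeling a `region_labeling` from [partition_regions()] covering
#'   every face.
#' @return object of class `area_report`: list with `region_area_cm2`
#'   (named over the four regions), `excluded_cm2`, `total_cm2`.
#' @export
region_areas <- function(mesh, labeling) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (length(labeling) != nrow(mesh$faces))
    stop("labeling must cover every face exactly once")
  if (any(is.na(labeling)) || any(!labeling %in% 1:5))
    stop("unlabeled or invalid face label")
  fa <- face_areas(mesh$vertices, mesh$faces) / 100
  areas <- vapply(1:4, function(l) sum(fa[labeling == l]), numeric(1))
  names(areas) <- REGIONS[1:4]
  structure(list(region_area_cm2 = areas,
                 excluded_cm2 = sum(fa[labeling == 5L]),
                 total_cm2 = sum(areas)),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat("<area_report> (cm^2)\n")
  for (r in names(x$region_area_cm2))
    cat(sprintf("  %-12s %8.3f\n", r, x$region_area_cm2[[r]]))
  cat(sprintf("  %-12s %8.3f\n", "Total", x$total_cm2))
  if (x$excluded_cm2 > 0)
    cat(sprintf("  %-12s %8.3f\n", "(excluded)", x$excluded_cm2))
  invisible(x)
}

#' End-to-end surface-area pipeline
#'
#' Segments the volume (smoothing, dual thresholds, closing), meshes the
#' soft-tissue mask, flat-fills small boundary defects, partitions the
#' surface by the landmark rules, and reports per-region areas. All stage
#' parameters are recorded in the returned report. Deterministic: the
#' same inputs give a bit-identical report.
#'
#' @param vol an [hu_volume()].
#' @param rules a [partition_rules()].
#' @param cfg a [segmentation_config()].
#' @param fill_max_mm maximum boundary-loop perimeter for flat filling
#'   (default 0: no filling; closed phantom surfaces have no holes).
#' @return an `area_report` with extra fields `parameters`, `labeling`,
#'   `mesh`.
#' @export
run_pipeline <- function(vol, rules, cfg = segmentation_config(),
                         fill_max_mm = 0) {
  masks <- segment_pipeline(vol, cfg)
  mesh <- extract_isosurface(masks$soft_mask)
  fill_report <- NULL
  if (fill_max_mm > 0) {
    filled <- flat_fill_holes(mesh, fill_max_mm)
    mesh <- filled$mesh
    fill_report <- filled$report
  }
  labeling <- partition_regions(mesh, rules)
  rep <- region_areas(mesh, labeling)
  rep$parameters <- list(segmentation = unclass(cfg),
                         fill_max_mm = fill_max_mm,
                         soft_provenance = masks$soft_mask$provenance,
                         bone_provenance = masks$bone_mask$provenance)
  rep$fill_report <- fill_report
  rep$labeling <- labeling
  rep$mesh <- mesh
  rep
}

#' Ground-truth region labels for mesh faces
#'
#' Looks up each face centroid in the phantom's voxel label grid to
#' obtain the true region of the structure the face belongs to. Because
#' surface faces sit at the tissue-air boundary, the lookup searches a
#' small cube of voxels around the centroid and returns the most frequent
#' non-air label.
#'
#' @param mesh a [triangle_mesh()] extracted from the phantom volume.
#' @param truth a `phantom_truth`.
#' @param spacing_mm,origin_mm grid geometry (defaults taken from the
#'   truth grids assume the phantom's own volume).
#' @param search_voxels half-width of the lookup cube, default 3.
#' @return integer vector of truth labels per face (indices into the
#'   label levels; 1 = AIR when no tissue voxel is found nearby).
#' @export
truth_face_labels <- function(mesh, truth, spacing_mm = c(0.3, 0.3, 0.3),
                              origin_mm = c(0, 0, 0), search_voxels = 3L) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(truth,
                                                      "phantom_truth"))
  lab <- truth$voxel_labels
  d <- dim(lab)
  V <- mesh$vertices
  F <- mesh$faces
  C <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3
  idx <- round(sweep(sweep(C, 2, origin_mm), 2, spacing_mm, "/")) + 1
  sr <- -search_voxels:search_voxels
  offs <- as.matrix(expand.grid(sr, sr, sr))
  # nearest offsets first: the first non-air voxel hit decides the label
  offs <- offs[order(rowSums(offs^2)), , drop = FALSE]
  out <- rep(1L, nrow(C))
  for (o in seq_len(nrow(offs))) {
    rem <- which(out == 1L)
    if (!length(rem)) break
    p <- sweep(idx[rem, , drop = FALSE], 2, offs[o, ], "+")
    ok <- p[, 1] >= 1 & p[, 2] >= 1 & p[, 3] >= 1 &
      p[, 1] <= d[1] & p[, 2] <= d[2] & p[, 3] <= d[3]
    if (!any(ok)) next
    li <- lab[p[ok, , drop = FALSE]]
    hit <- li != 1L
    out[rem[ok][hit]] <- li[hit]
  }
  out
}
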