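#' Triangle mesh
#'
#' Minimal indexed triangle mesh: an `n x 3` numeric vertex matrix (world
#' mm) and an `m x 3` integer face matrix of 1-based vertex indices.
#' Degenerate (zero-area) faces are dropped at construction.
#'
#' @param vertices numeric matrix, one vertex per row (mm).
#' @param faces integer matrix, one triangle per row.
#' @param drop_degenerate drop faces with repeated indices or area below
#'   `1e-12` mm^2 (default `TRUE`).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, drop_degenerate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (drop_degenerate) {
      dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
        faces[, 1] == faces[, 3]
      faces <- faces[!dup, , drop = FALSE]
      if (nrow(faces) > 0) {
        a <- face_areas(vertices, faces)
        faces <- faces[a > 1e-12, , drop = FALSE]
      }
    }
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.4f cm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

# per-face areas in mm^2 (vectorised cross product)
face_areas <- function(V, F) {
  if (nrow(F) == 0) return(numeric(0))
  a <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - a
  w <- V[F[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Extract an isosurface mesh from a binary mask
#'
#' Converts the mask to a 0/1 scalar field, smooths it with a Gaussian of
#' fixed physical width (default 0.3 mm, one voxel at the reference CBCT
#' spacing) to suppress the staircase over-estimation of area inherent to
#' voxelized surfaces, pads the field with background so closed masks
#' yield closed (watertight) meshes even at the grid border, and runs a
#' marching-tetrahedra contouring at the requested level. Vertices are
#' emitted in world millimetres via the mask's spacing and origin. The
#' smoothing width is physical (mm, not voxels) so that the rounding it
#' applies to sharp edges does not grow with the voxel size; at coarse
#' spacings curved surfaces retain some staircase over-estimation, which
#' shrinks as the spacing does.
#'
#' @param mask a [binary_mask()].
#' @param level iso level in (0, 1), default 0.5.
#' @param field_sigma_mm Gaussian sigma (mm) applied to the 0/1 field
#'   before contouring; 0 contours the raw staircase field.
#' @return a [triangle_mesh()]; an empty mask yields an empty mesh.
#' @export
extract_isosurface <- function(mask, level = 0.5, field_sigma_mm = 0.3) {
  stopifnot(inherits(mask, "binary_mask"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!any(mask$data))
    return(triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3)))
  d <- dim(mask$data)
  sig_vox <- field_sigma_mm / mask$spacing_mm
  pad <- as.integer(max(2, ceiling(3 * max(sig_vox)) + 1))
  dp <- d + 2L * pad
  field <- array(0, dim = dp)
  field[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]),
        (pad + 1):(pad + d[3])] <- as.numeric(mask$data)
  if (field_sigma_mm > 0)
    field <- array(cpp_gaussian_smooth(as.vector(field), dp, sig_vox),
                   dim = dp)
  org <- mask$origin_mm - pad * mask$spacing_mm
  res <- cpp_marching_tets(as.vector(field), dp, level, mask$spacing_mm,
                           org)
  triangle_mesh(res$vertices, res$faces)
}

#' Mesh surface area
#'
#' Sum of the triangle areas `0.5 * |(v1 - v0) x (v2 - v0)|`, computed in
#' mm^2 and reported in cm^2. With `face_subset`, only the listed faces
#' are summed.
#'
#' @param mesh a [triangle_mesh()].
#' @param face_subset optional integer vector of face indices.
#' @return surface area in cm^2.
#' @export
mesh_area <- function(mesh, face_subset = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  F <- mesh$faces
  if (!is.null(face_subset)) {
    face_subset <- as.integer(face_subset)
    if (length(face_subset) &&
        (min(face_subset) < 1L || max(face_subset) > nrow(F)))
      stop("face subset indices out of range")
    F <- F[face_subset, , drop = FALSE]
  }
  sum(face_areas(mesh$vertices, F)) / 100
}

# boundary edges (appearing in exactly one face) as a 2-column matrix of
# vertex indices, plus the owning face
boundary_edges <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0)
    return(list(edges = matrix(integer(0), ncol = 2), face = integer(0)))
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  face <- rep(seq_len(nrow(F)), 3)
  nv <- max(F)
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  o <- order(key)
  k <- key[o]
  len <- length(k)
  same_next <- c(k[-len] == k[-1], FALSE)
  same_prev <- c(FALSE, k[-len] == k[-1])
  keep <- o[!same_next & !same_prev]
  list(edges = e[keep, , drop = FALSE], face = face[keep])
}

#' Flat-fill open boundary loops of a mesh
#'
#' Detects open boundary loops (edges owned by a single face), and fills
#' every loop whose perimeter does not exceed `max_boundary_mm` with a
#' triangle fan around the loop centroid projected onto the loop's
#' best-fit plane — the mesh-repair analogue of flat-filling a truncated
#' field-of-view defect. Longer loops are left open and reported. Existing
#' faces are never removed. A boundary vertex incident to more than two
#' boundary edges makes the boundary non-manifold and is an error.
#'
#' @param mesh a [triangle_mesh()].
#' @param max_boundary_mm maximum loop perimeter (mm) eligible for filling.
#' @return list with `mesh` (filled [triangle_mesh()]) and `report`, a
#'   data frame with one row per loop (`perimeter_mm`, `n_edges`,
#'   `filled`).
#' @export
flat_fill_holes <- function(mesh, max_boundary_mm = Inf) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  be <- boundary_edges(mesh)$edges
  report <- data.frame(perimeter_mm = numeric(0), n_edges = integer(0),
                       filled = logical(0))
  if (nrow(be) == 0) return(list(mesh = mesh, report = report))

  verts <- sort(unique(as.vector(be)))
  deg <- table(factor(as.vector(be), levels = verts))
  if (any(deg != 2L)) {
    bad <- verts[which(deg != 2L)[1]]
    stop(sprintf("non-manifold boundary at vertex %d (%d boundary edges)",
                 bad, deg[as.character(bad)]))
  }
  # adjacency: each boundary vertex has exactly two neighbours
  nbr <- new.env(hash = TRUE)
  for (r in seq_len(nrow(be))) {
    for (ab in list(c(be[r, 1], be[r, 2]), c(be[r, 2], be[r, 1]))) {
      k <- as.character(ab[1])
      nbr[[k]] <- c(if (!is.null(nbr[[k]])) nbr[[k]], ab[2])
    }
  }
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (v0 in verts) {
    if (!is.null(visited[[as.character(v0)]])) next
    loop <- integer(0)
    prev <- NA_integer_
    cur <- v0
    repeat {
      loop <- c(loop, cur)
      visited[[as.character(cur)]] <- TRUE
      nx <- nbr[[as.character(cur)]]
      nxt <- if (is.na(prev)) nx[1] else nx[nx != prev][1]
      if (is.na(nxt)) stop("boundary walk failed (open chain)")
      prev <- cur
      cur <- nxt
      if (cur == v0) break
    }
    loops[[length(loops) + 1]] <- loop
  }

  V <- mesh$vertices
  newF <- list()
  for (loop in loops) {
    P <- V[loop, , drop = FALSE]
    nl <- nrow(P)
    per <- sum(sqrt(rowSums((P - P[c(2:nl, 1), , drop = FALSE])^2)))
    fill <- per <= max_boundary_mm
    report <- rbind(report, data.frame(perimeter_mm = per, n_edges = nl,
                                       filled = fill))
    if (!fill) next
    ctr <- colMeans(P)
    # project the centroid onto the best-fit plane of the loop
    sv <- svd(sweep(P, 2, ctr))
    nrm <- sv$v[, 3]
    apex <- ctr  # centroid already lies on the best-fit plane through it
    nrm <- nrm / sqrt(sum(nrm^2))
    ai <- nrow(V) + 1L
    V <- rbind(V, apex)
    for (i in seq_len(nl)) {
      j <- if (i == nl) 1L else i + 1L
      newF[[length(newF) + 1]] <- c(ai, loop[i], loop[j])
    }
  }
  F <- mesh$faces
  if (length(newF)) F <- rbind(F, do.call(rbind, newF))
  list(mesh = triangle_mesh(V, F), report = report)
}

#' Write / read STL files
#'
#' Binary STL (default) or ASCII. The binary dialect stores coordinates
#' as 32-bit floats, so a round trip preserves areas to single precision.
#' Reading auto-detects the dialect; malformed or truncated files raise a
#' parse error reporting the byte offset, and no partial mesh is
#' returned.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @param ascii write the ASCII dialect instead of binary.
#' @return `write_stl` returns `path` invisibly; `read_stl` returns a
#'   [triangle_mesh()] (triangle soup: vertices are not re-welded).
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(F)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid oralarea", con)
    for (i in seq_len(n)) {
      tri <- V[F[i, ], , drop = FALSE]
      u <- tri[2, ] - tri[1, ]
      w <- tri[3, ] - tri[1, ]
      nm <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
              u[1] * w[2] - u[2] * w[1])
      len <- sqrt(sum(nm^2))
      if (len > 0) nm <- nm / len
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nm[1], nm[2],
                           nm[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2],
                           tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid oralarea", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("oralarea binary STL", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    for (i in seq_len(n)) {
      tri <- V[F[i, ], , drop = FALSE]
      u <- tri[2, ] - tri[1, ]
      w <- tri[3, ] - tri[1, ]
      nm <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
              u[1] * w[2] - u[2] * w[1])
      len <- sqrt(sum(nm^2))
      if (len > 0) nm <- nm / len
      writeBin(as.numeric(c(nm, t(tri))), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("STL parse error at byte 0: file too short")
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  is_ascii <- grepl("^\\s*solid", rawToChar(head_raw[1:min(80, sz)])) &&
    grepl("facet", tryCatch(rawToChar(head_raw), error = function(e) ""))
  if (!is_ascii && sz >= 84) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    expected <- 84 + 50 * as.numeric(n)
    if (expected != sz)
      stop(sprintf(
        "STL parse error at byte %d: expected %.0f bytes for %d facets, file has %.0f",
        84, expected, n, sz))
    tris <- matrix(NA_real_, nrow = 3 * n, ncol = 3)
    for (i in seq_len(n)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      if (length(rec) < 12)
        stop(sprintf("STL parse error at byte %d: truncated facet %d",
                     84 + 50 * (i - 1), i))
      tris[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], ncol = 3,
                                            byrow = TRUE)
      invisible(readBin(con, "raw", n = 2))
    }
    return(triangle_mesh(tris, matrix(seq_len(3 * n), ncol = 3,
                                      byrow = TRUE),
                         drop_degenerate = FALSE))
  }
  # ASCII
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines)
  if (length(vx) %% 3 != 0)
    stop(sprintf("STL parse error at line %d: vertex count not divisible by 3",
                 if (length(vx)) vx[length(vx)] else 1L))
  if (!length(grep("^\\s*endsolid", lines)))
    stop("STL parse error: missing endsolid (truncated file)")
  coords <- t(vapply(strsplit(trimws(lines[vx]), "\\s+"), function(tok)
    as.numeric(tok[2:4]), numeric(3)))
  if (any(!is.finite(coords)))
    stop("STL parse error: non-numeric vertex coordinates")
  n <- nrow(coords) / 3
  triangle_mesh(coords, matrix(seq_len(3 * n), ncol = 3, byrow = TRUE),
                drop_degenerate = FALSE)
}
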