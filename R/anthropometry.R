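#' Named anatomical landmark set
#'
#' A mapping from landmark names to 3-D points in world millimetres.
#' Recognized names include vertex, gnathion, glabella, subnasale, the
#' chelia, tragus, the external auditory meatus pair, upper/lower lip,
#' back_of_head, the first-molar points (16/26) with their alveolar-ridge
#' substitutes, and the pterygoid hamuli. Unknown names are allowed and
#' simply ignored by the measurements.
#'
#' @param points named list of finite numeric triples (mm).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  if (!is.list(points) || is.null(names(points)) ||
      any(names(points) == ""))
    stop("landmarks must be a fully named list")
  if (anyDuplicated(names(points))) stop("landmark names must be unique")
  points <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p)))
      stop("each landmark must be a finite 3-D point")
    p
  })
  structure(list(points = points), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks: %s\n", length(x$points),
              paste(utils::head(names(x$points), 8), collapse = ", ")))
  invisible(x)
}

# the twelve head measurements: id, descriptive name, endpoints
MEASUREMENTS <- data.frame(
  id = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
         "XI", "palatal_width"),
  name = c("length_of_head", "width_of_head", "depth_of_head",
           "face_height", "lower_face_height", "nose_height",
           "width_of_mouth", "upper_face_height", "upper_lip_height",
           "mandible_height", "mandibular_length", "palatal_width"),
  a = c("vertex", "ext_auditory_meatus_right", "back_of_head", "glabella",
        "subnasale", "glabella", "chelion_right", "glabella", "subnasale",
        "gnathion", "tragus", "molar_16"),
  b = c("gnathion", "ext_auditory_meatus_left", "glabella", "gnathion",
        "gnathion", "subnasale", "chelion_left", "upper_lip", "upper_lip",
        "lower_lip", "gnathion", "molar_26"),
  stringsAsFactors = FALSE)

lm_dist_cm <- function(lm, a, b) {
  pa <- lm$points[[a]]
  pb <- lm$points[[b]]
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  sqrt(sum((pa - pb)^2)) / 10
}

#' Compute the twelve head measurements
#'
#' Straight-line (chord) Euclidean distances between landmark pairs,
#' reported in centimetres; measurements whose landmarks are missing are
#' reported as `NA`, mirroring measurement campaigns where not every
#' distance can be taken on every subject. The palatal width falls back
#' from the first-molar points to the alveolar-ridge estimates (flagged
#' in the provenance column).
#'
#' @param lm a [landmark_set()].
#' @param quantize_cm optional caliper resolution in cm (e.g. `0.05` for
#'   a 0.5 mm caliper); values are rounded to that grid. Default `NULL`,
#'   no quantization.
#' @return object of class `anthropometry_result`: data frame with
#'   columns `id`, `name`, `value_cm`, `provenance`.
#' @export
measure_all <- function(lm, quantize_cm = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  if (!length(lm$points)) stop("empty landmark set")
  vals <- numeric(nrow(MEASUREMENTS))
  prov <- character(nrow(MEASUREMENTS))
  for (i in seq_len(nrow(MEASUREMENTS))) {
    if (MEASUREMENTS$id[i] == "palatal_width") {
      pw <- palatal_width(lm)
      vals[i] <- pw$value_cm
      prov[i] <- pw$provenance
    } else {
      vals[i] <- lm_dist_cm(lm, MEASUREMENTS$a[i], MEASUREMENTS$b[i])
      prov[i] <- if (is.na(vals[i])) "missing" else "direct"
    }
  }
  if (all(is.na(vals))) stop("no measurement is definable from this set")
  if (!is.null(quantize_cm))
    vals <- round(vals / quantize_cm) * quantize_cm
  structure(data.frame(id = MEASUREMENTS$id, name = MEASUREMENTS$name,
                       value_cm = vals, provenance = prov,
                       stringsAsFactors = FALSE),
            class = c("anthropometry_result", "data.frame"))
}

#' Palatal width with alveolar-ridge fallback
#'
#' Distance between the upper first molars (16, 26) when both are
#' present; if one or both were extracted, the distance between the
#' alveolar-ridge estimates of their positions is used and flagged.
#'
#' @param lm a [landmark_set()].
#' @return list with `value_cm` (NA when neither point pair is available)
#'   and `provenance` (`"molars"`, `"ridge-estimate"` or `"missing"`).
#' @export
palatal_width <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  v <- lm_dist_cm(lm, "molar_16", "molar_26")
  if (!is.na(v)) return(list(value_cm = v, provenance = "molars"))
  v <- lm_dist_cm(lm, "ridge_estimate_16", "ridge_estimate_26")
  if (!is.na(v)) return(list(value_cm = v, provenance = "ridge-estimate"))
  list(value_cm = NA_real_, provenance = "missing")
}

#' Pair two measurement sessions into a repeatability table
#'
#' Builds, for each of the twelve measurements, the two-column
#' (measurement A, measurement B) table feeding the intraclass
#' correlation. Both inputs must describe the same subjects in the same
#' order.
#'
#' @param lms_a,lms_b lists of [landmark_set()]s, one per subject, from
#'   two independent measurement sessions.
#' @param quantize_cm optional caliper resolution in cm applied to both
#'   sessions (see [measure_all()]).
#' @return named list of [measurement_table()]s, one per measurement id;
#'   subjects with a missing value in either session keep `NA` cells.
#' @export
repeat_measurements <- function(lms_a, lms_b, quantize_cm = NULL) {
  if (!is.list(lms_a) || !is.list(lms_b) ||
      length(lms_a) != length(lms_b) || !length(lms_a))
    stop("need two equally long, non-empty lists of landmark sets")
  ra <- lapply(lms_a, measure_all, quantize_cm = quantize_cm)
  rb <- lapply(lms_b, measure_all, quantize_cm = quantize_cm)
  out <- list()
  for (i in seq_len(nrow(MEASUREMENTS))) {
    id <- MEASUREMENTS$id[i]
    va <- vapply(ra, function(r) r$value_cm[r$id == id], numeric(1))
    vb <- vapply(rb, function(r) r$value_cm[r$id == id], numeric(1))
    out[[id]] <- measurement_table(cbind(va, vb), column_kind = "repeat")
  }
  out
}
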