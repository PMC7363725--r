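#' Landmark JSON input/output
#'
#' Landmark files are JSON objects mapping landmark names to `[x, y, z]`
#' positions in millimetres, the interchange format shared by the phantom
#' generator, the anthropometry tools and the partition rules.
#'
#' @param lm a [landmark_set()].
#' @param path file path.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  jsonlite::write_json(lm$points, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Serialize an area report
#'
#' Writes the per-region areas as JSON (full report including the total,
#' the excluded area and the stage parameters) and, optionally, as a
#' two-column CSV (`region`, `area_cm2`).
#'
#' @param report an `area_report` from [region_areas()] or
#'   [run_pipeline()].
#' @param path_json JSON output path.
#' @param path_csv optional CSV output path.
#' @return `path_json`, invisibly.
#' @export
write_area_report <- function(report, path_json, path_csv = NULL) {
  stopifnot(inherits(report, "area_report"))
  out <- list(region_area_cm2 = as.list(report$region_area_cm2),
              total_cm2 = report$total_cm2,
              excluded_cm2 = report$excluded_cm2,
              parameters = report$parameters)
  jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv))
    utils::write.csv(data.frame(region = names(report$region_area_cm2),
                                area_cm2 = as.numeric(
                                  report$region_area_cm2)),
                     path_csv, row.names = FALSE)
  invisible(path_json)
}

#' Serialize partition rules
#'
#' @param rules a [partition_rules()].
#' @param path JSON file path.
#' @return `write_partition_rules` returns `path` invisibly;
#'   `read_partition_rules` returns a [partition_rules()].
#' @export
write_partition_rules <- function(rules, path) {
  stopifnot(inherits(rules, "partition_rules"))
  jsonlite::write_json(unclass(rules), path, auto_unbox = FALSE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_partition_rules
#' @export
read_partition_rules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) matrix(as.numeric(t(m)), ncol = 3, byrow = TRUE)
  partition_rules(
    hamulus_left = x$hamulus_left, hamulus_right = x$hamulus_right,
    maxillary_ridge_curve = as_mat(x$maxillary_ridge_curve),
    mandibular_ridge_curve = as_mat(x$mandibular_ridge_curve),
    lip_crease_plane = x$lip_crease_plane,
    occlusal_plane = x$occlusal_plane,
    tooth_seeds = if (length(x$tooth_seeds)) as_mat(x$tooth_seeds)
    else matrix(numeric(0), ncol = 3),
    tooth_radius_mm = x$tooth_radius_mm)
}
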