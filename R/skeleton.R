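## Skeletons as ordered collections of labelled point sets, and the
## per-segment hull volume table that the calibration is built on.

#' Assemble labelled segments into a skeleton
#'
#' A skeleton is an ordered, uniquely named collection of functional units
#' (skull, neck sub-units such as `neck_1`, `neck_2`, trunk, limb elements,
#' feet). Foot segments are flagged explicitly so totals can be reported
#' with and without them: hulls fitted to feet are strongly influenced by
#' toe posture, which the method handles by exclusion, not correction.
#'
#' @param segments named list of point matrices, or a list of [point_set()]s.
#' @param feet_labels character vector of segment names flagged as feet.
#' @param specimen specimen identifier.
#' @return an object of class `skeleton_segments`.
#' @export
skeleton_segments <- function(segments, feet_labels = character(), specimen = "specimen") {
  if (length(segments) == 0L) {
    chm_error("degenerate_geometry", "a skeleton needs at least one segment")
  }
  segs <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    if (inherits(s, "point_set")) s else point_set(names(segments)[i], s)
  })
  labels <- vapply(segs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    chm_error("degenerate_geometry", "segment names must be unique")
  }
  if (!all(feet_labels %in% labels)) {
    chm_error("degenerate_geometry", sprintf(
      "feet labels not present as segments: %s",
      paste(setdiff(feet_labels, labels), collapse = ", ")))
  }
  names(segs) <- labels
  structure(list(specimen = specimen, segments = segs,
                 feet_labels = as.character(feet_labels)),
            class = "skeleton_segments")
}

#' Construct a per-segment hull volume table
#'
#' Usually produced by [segment_hull_volumes()]; the constructor is exported
#' so that synthetic generators can state analytic ground-truth volumes
#' without going through the hull code under test.
#'
#' @param volumes named numeric vector of per-segment volumes (mm^3), all > 0.
#' @param feet_labels segment names whose volumes are excluded from the
#'   minus-feet total.
#' @param specimen specimen identifier.
#' @return object of class `hull_volume_table` with fields `specimen`,
#'   `volumes`, `feet_labels`, `total_with_feet`, `total_minus_feet` (mm^3).
#' @export
hull_volume_table <- function(volumes, feet_labels = character(), specimen = "specimen") {
  if (is.null(names(volumes)) || anyDuplicated(names(volumes))) {
    chm_error("degenerate_geometry", "volumes must be uniquely named by segment")
  }
  if (!all(is.finite(volumes)) || any(volumes <= 0)) {
    chm_error("degenerate_geometry", "all segment volumes must be positive and finite")
  }
  if (!all(feet_labels %in% names(volumes))) {
    chm_error("degenerate_geometry", "feet labels must name segments in the table")
  }
  structure(list(
    specimen = specimen,
    volumes = volumes,
    feet_labels = as.character(feet_labels),
    total_with_feet = sum(volumes),
    total_minus_feet = sum(volumes) - sum(volumes[feet_labels])
  ), class = "hull_volume_table")
}

#' Per-segment convex hull volumes of a skeleton
#'
#' Fits a minimum convex hull to every functional unit independently and
#' sums the segment volumes into whole-body totals with and without the
#' foot segments.
#'
#' @param skeleton a [skeleton_segments()] object.
#' @return a [hull_volume_table()].
#' @export
segment_hull_volumes <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_segments"))
  vols <- vapply(skeleton$segments, function(s) {
    tryCatch(polytope_volume(convex_hull(s)),
             chm_degenerate_geometry = function(e) {
               chm_error("degenerate_geometry", sprintf(
                 "segment '%s': %s", s$label, conditionMessage(e)))
             })
  }, numeric(1))
  hull_volume_table(vols, skeleton$feet_labels, skeleton$specimen)
}

#' @export
print.hull_volume_table <- function(x, ...) {
  cat(sprintf("hull volumes for '%s' (%d segments)\n", x$specimen, length(x$volumes)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.hull_volume_table <- function(x, ...) {
  data.frame(
    specimen = x$specimen,
    segment = c(names(x$volumes), "total_with_feet", "total_minus_feet"),
    volume_mm3 = c(unname(x$volumes), x$total_with_feet, x$total_minus_feet),
    is_foot = c(names(x$volumes) %in% x$feet_labels, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Write a hull volume table to CSV
#'
#' Emits one row per segment plus `total_with_feet` and `total_minus_feet`
#' rows, with columns `specimen,segment,volume_mm3,is_foot`.
#'
#' @param x a `hull_volume_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hull_volumes_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
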