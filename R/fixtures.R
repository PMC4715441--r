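## Packaged reference data: the 20-specimen extant pigeon calibration table
## and the hull volumes of the three mounted composite dodo skeletons. One
## printed typo is corrected on ingestion: the Ptilinopus superbus
## minus-feet volume appears as "7,4691" in the source table and is stored
## as 74,691 mm^3, consistent with its with-feet volume of 77,882 mm^3.

#' Extant pigeon calibration fixture
#'
#' Twenty columbiform specimens (13 eviscerated, 7 intact) spanning a 70 g
#' fruit dove to the 2 kg Victoria crowned pigeon, each with measured body
#' mass and whole-skeleton convex hull volumes with and without feet.
#'
#' @param subset_tag initial subset tag for the returned dataset.
#' @param predictor_variant initial predictor variant.
#' @return a [calibration_dataset()] of 20 specimens.
#' @export
load_pigeon_fixture <- function(subset_tag = "combined",
                                predictor_variant = "minus_feet") {
  path <- system.file("extdata", "pigeon_specimens.csv", package = "chullmass",
                      mustWork = TRUE)
  read_specimens(path, subset_tag = subset_tag, predictor_variant = predictor_variant)
}

#' Dodo hull volume fixture
#'
#' Total convex hull volumes (with and without feet) of the three articulated
#' composite dodo skeletons: the NHMUK Tring and South Kensington mounts and
#' the Edinburgh mount. As composites assembled from multiple individuals,
#' mass estimates from these volumes describe the mounted hypothetical
#' individual rather than a known bird.
#'
#' @return data.frame with columns `specimen`, `accession`, `ch_vol_mm3`,
#'   `ch_vol_minus_feet_mm3`.
#' @export
load_dodo_fixture <- function() {
  path <- system.file("extdata", "dodo_hull_volumes.csv", package = "chullmass",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a fossil hull-volume table from CSV
#'
#' @param path CSV with columns `specimen`, `ch_vol_mm3`,
#'   `ch_vol_minus_feet_mm3`.
#' @return validated data.frame.
#' @export
read_fossils <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "ch_vol_mm3", "ch_vol_minus_feet_mm3")
  if (!all(need %in% names(df))) {
    chm_error("schema", sprintf("fossil table needs columns %s",
                                paste(need, collapse = ", ")))
  }
  if (any(df$ch_vol_minus_feet_mm3 <= 0) ||
      any(df$ch_vol_minus_feet_mm3 > df$ch_vol_mm3)) {
    chm_error("schema", "fossil volumes must be positive with minus_feet <= with_feet")
  }
  df
}
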