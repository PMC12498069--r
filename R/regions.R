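#' The ten-region scheme: three latitudinal zones and seven continents
#'
#' The classification operates on a fixed set of ten regions: three
#' latitudinal zones (north temperate including the frigid zone, tropical,
#' south temperate including the frigid zone) followed by seven continents.
#' Zone membership is a curated input taken from flora descriptions;
#' continent membership is computed from native species counts with the
#' 4 percent rule (see [continent_center_flags()]).
#'
#' The continent set defaults to Asia, Europe, Africa, North America,
#' South America, Oceania/Australasia and Antarctica. The scheme is
#' replaceable, but all shipped signatures and readers assume this default.
#'
#' @return A data frame with columns `code`, `kind` (`"zone"` or
#'   `"continent"`) and `name`, in the fixed column order used by every
#'   distribution matrix in the package.
#' @examples
#' sses_regions()
#' @export
sses_regions <- function() {
  data.frame(
    code = c(
      "z_north_temperate", "z_tropical", "z_south_temperate",
      "asia", "europe", "africa", "north_america", "south_america",
      "oceania", "antarctica"
    ),
    kind = c(rep("zone", 3L), rep("continent", 7L)),
    name = c(
      "North temperate zone (incl. north frigid)",
      "Tropical zone",
      "South temperate zone (incl. south frigid)",
      "Asia", "Europe", "Africa", "North America", "South America",
      "Oceania/Australasia", "Antarctica"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname sses_regions
#' @export
zone_codes <- function() sses_regions()$code[1:3]

#' @rdname sses_regions
#' @export
continent_codes <- function() sses_regions()$code[4:10]

#' @rdname sses_regions
#' @export
region_codes <- function() sses_regions()$code
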