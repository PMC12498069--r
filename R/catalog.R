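#' The built-in SSES catalog: 18 types, 6 supertypes, 3 elements, 10 subtypes
#'
#' Returns the fixed hierarchy of the Spermatophyte Spatial Evolutionary
#' System: 18 distribution types (Roman ids I--XVIII), each belonging to one
#' of 6 distribution supertypes and one of 3 floristic elements
#' (cosmopolitan, tropical, temperate), plus 10 distribution subtypes
#' attached to six of the types. Each type carries the family count reported
#' for the global study (429 families in total) and a binary 10-region
#' distribution signature over the scheme of [sses_regions()]. The
#' signatures encode each type's published range description and are the
#' matching target for automatic cluster labelling
#' ([label_clusters()]); they are returned as plain data so callers can
#' substitute their own encoding.
#'
#' @return An object of class `sses_catalog`: a list with
#'   \describe{
#'     \item{types}{data frame `id`, `name`, `element`, `supertype`,
#'       `n_families` (18 rows).}
#'     \item{subtypes}{data frame `id`, `type`, `name` (10 rows).}
#'     \item{signatures}{18 x 10 binary matrix, rows named by type id,
#'       columns by region code.}
#'   }
#' @examples
#' cat429 <- sses_catalog()
#' sum(cat429$types$n_families)          # 429
#' subset(cat429$types, supertype == 2)  # types II, III, VII, IX
#' @export
sses_catalog <- function() {
  types <- data.frame(
    id = c(
      "I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
      "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII"
    ),
    name = c(
      "Cosmopolitan",
      "Pantropic",
      "Tropical Asia and tropical America disjuncted",
      "Old World tropics",
      "Tropical Asia to tropical Australasia",
      "Tropical Asia to tropical Africa",
      "South Atlantic disjuncted",
      "Tropical Asia",
      "New World tropics",
      "Tropical Australasia",
      "Tropical Africa",
      "North temperate",
      "East Asia and North America disjuncted",
      "Pan-Mediterranean diffused",
      "East Asia",
      "North America",
      "South temperate",
      "North and south temperate disjuncted"
    ),
    element = c(
      "cosmopolitan",
      rep("tropical", 10L),
      rep("temperate", 7L)
    ),
    supertype = c(1L, 2L, 2L, 3L, 3L, 3L, 2L, 3L, 2L, 3L,
                  3L, 5L, 5L, 6L, 5L, 5L, 4L, 6L),
    n_families = c(66L, 99L, 13L, 7L, 14L, 16L, 11L, 8L, 35L, 17L,
                   18L, 20L, 12L, 14L, 11L, 9L, 43L, 16L),
    stringsAsFactors = FALSE
  )

  subtypes <- data.frame(
    id = c("II.I", "II.II", "X.I", "X.II", "XI.I",
           "XIV.I", "XV.I", "XVII.I", "XVII.II", "XVII.III"),
    type = c("II", "II", "X", "X", "XI", "XIV", "XV",
             "XVII", "XVII", "XVII"),
    name = c(
      "Tropical Asia-Australasia and tropical America",
      "Tropical Asia-tropical Africa-tropical America",
      "Endemic to New Caledonia",
      "Endemic to Fiji",
      "Endemic to Madagascar",
      "Mediterranea, West Asia to Central Asia",
      "Endemic to Japan",
      "Temperate South America",
      "Temperate Australasia",
      "Temperate Africa"
    ),
    stringsAsFactors = FALSE
  )

  # region order: z_north_temperate, z_tropical, z_south_temperate,
  #               asia, europe, africa, north_america, south_america,
  #               oceania, antarctica
  sig <- rbind(
    I     = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0),
    II    = c(0, 1, 0, 1, 0, 1, 1, 1, 1, 0),
    III   = c(0, 1, 0, 1, 0, 0, 1, 1, 0, 0),
    IV    = c(0, 1, 0, 1, 0, 1, 0, 0, 1, 0),
    V     = c(0, 1, 0, 1, 0, 0, 0, 0, 1, 0),
    VI    = c(0, 1, 0, 1, 0, 1, 0, 0, 0, 0),
    VII   = c(0, 1, 0, 0, 0, 1, 0, 1, 0, 0),
    VIII  = c(0, 1, 0, 1, 0, 0, 0, 0, 0, 0),
    IX    = c(0, 1, 0, 0, 0, 0, 1, 1, 0, 0),
    X     = c(0, 1, 0, 0, 0, 0, 0, 0, 1, 0),
    XI    = c(0, 1, 0, 0, 0, 1, 0, 0, 0, 0),
    XII   = c(1, 0, 0, 1, 1, 0, 1, 0, 0, 0),
    XIII  = c(1, 0, 0, 1, 0, 0, 1, 0, 0, 0),
    XIV   = c(1, 0, 1, 1, 1, 1, 0, 0, 0, 0),
    XV    = c(1, 0, 0, 1, 0, 0, 0, 0, 0, 0),
    XVI   = c(1, 0, 0, 0, 0, 0, 1, 0, 0, 0),
    XVII  = c(0, 0, 1, 0, 0, 1, 0, 1, 1, 0),
    XVIII = c(1, 0, 1, 1, 1, 0, 1, 1, 1, 0)
  )
  colnames(sig) <- region_codes()
  storage.mode(sig) <- "integer"

  out <- list(types = types, subtypes = subtypes, signatures = sig)
  class(out) <- "sses_catalog"
  out
}

#' @export
print.sses_catalog <- function(x, ...) {
  cat("SSES catalog:", nrow(x$types), "types,",
      length(unique(x$types$supertype)), "supertypes,",
      length(unique(x$types$element)), "elements,",
      nrow(x$subtypes), "subtypes;",
      sum(x$types$n_families), "families\n")
  invisible(x)
}

#' Look up hierarchy parents of a distribution type
#'
#' @param type character vector of type ids (`"I"`..`"XVIII"`).
#' @param catalog an [sses_catalog()].
#' @return Character (element) or integer (supertype) vector aligned with
#'   `type`.
#' @export
catalog_element <- function(type, catalog = sses_catalog()) {
  idx <- match(type, catalog$types$id)
  if (anyNA(idx)) {
    stop("unknown type id(s): ", paste(type[is.na(idx)], collapse = ", "))
  }
  catalog$types$element[idx]
}

#' @rdname catalog_element
#' @export
catalog_supertype <- function(type, catalog = sses_catalog()) {
  idx <- match(type, catalog$types$id)
  if (anyNA(idx)) {
    stop("unknown type id(s): ", paste(type[is.na(idx)], collapse = ", "))
  }
  catalog$types$supertype[idx]
}

#' Export the catalog as JSON
#'
#' @param catalog an [sses_catalog()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "sses_catalog"))
  obj <- list(
    types = catalog$types,
    subtypes = catalog$subtypes,
    signatures = as.data.frame(catalog$signatures)
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
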