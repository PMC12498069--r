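#' Continent distribution-center flags by the 4 percent rule
#'
#' A continent is a distribution center of a family when it holds at least
#' `threshold` (default 4 percent) of the family's total native species.
#' The boundary is inclusive: exactly 4 percent counts as a center.
#'
#' @param counts named non-negative integer vector over the seven
#'   continents ([continent_codes()]).
#' @param total total native species of the family (positive).
#' @param threshold center fraction in (0, 1); default `0.04`.
#' @param family family name used in error messages.
#' @return Named binary integer 7-vector.
#' @examples
#' x <- c(asia = 4, europe = 96, africa = 0, north_america = 0,
#'        south_america = 0, oceania = 0, antarctica = 0)
#' continent_center_flags(x, total = 100)  # asia is exactly 4% -> center
#' @export
continent_center_flags <- function(counts, total, threshold = 0.04,
                                   family = "<family>") {
  stopifnot(threshold > 0, threshold < 1)
  if (is.na(total) || total <= 0) {
    stop("degenerate family '", family, "': total species count is ",
         total)
  }
  counts <- counts[continent_codes()]
  if (anyNA(counts)) {
    stop("family '", family, "': counts must cover all seven continents")
  }
  flags <- as.integer(counts / total >= threshold)
  names(flags) <- continent_codes()
  flags
}

#' Build the binary families x 10-region distribution matrix
#'
#' Each row is the concatenation of the family's three curated zone-center
#' flags and its seven computed continent-center flags (4 percent rule).
#' This matrix is the input to every clustering stage. Families whose
#' continent block is all zero (every continent below the threshold despite
#' a positive total) are retained but reported via a warning and the
#' `"degenerate"` attribute.
#'
#' @param records an `sses_families` table (see [read_family_table()]).
#' @param threshold center fraction, default `0.04`.
#' @return Binary integer matrix of class `sses_matrix` with families as
#'   row names, region codes as column names, and attributes
#'   `threshold_used` and `degenerate` (character vector of family names).
#' @export
build_matrix <- function(records, threshold = 0.04) {
  stopifnot(nrow(records) > 0L)
  records <- as_sses_families(as.data.frame(records))
  zones <- as.matrix(records[zone_codes()])
  cont <- t(vapply(
    seq_len(nrow(records)),
    function(i) {
      continent_center_flags(
        unlist(records[i, continent_codes()]),
        total = records$total_species[i],
        threshold = threshold,
        family = records$family[i]
      )
    },
    integer(7L)
  ))
  m <- cbind(zones, cont)
  rownames(m) <- records$family
  colnames(m) <- region_codes()
  storage.mode(m) <- "integer"
  degenerate <- records$family[rowSums(cont) == 0L]
  if (length(degenerate) > 0L) {
    warning("family/families with no continent center at threshold ",
            threshold, ": ", paste(degenerate, collapse = ", "))
  }
  attr(m, "threshold_used") <- threshold
  attr(m, "degenerate") <- degenerate
  class(m) <- c("sses_matrix", class(m))
  m
}

#' Per-continent species-percentage table and below-threshold tally
#'
#' Computes the fraction of each family's native species on each continent
#' and counts how many of the `n_families * 7` cells fall strictly below a
#' threshold. For the 429-family study this is the 3,003-cell table used to
#' justify the 4 percent cutoff.
#'
#' @param records an `sses_families` table.
#' @param threshold tally cutoff (default `0.04`); cells with
#'   `fraction < threshold` are counted.
#' @return List with `fractions` (families x 7 matrix), `n_cells`,
#'   `n_below`, `fraction_below`.
#' @export
percentage_table <- function(records, threshold = 0.04) {
  records <- as_sses_families(as.data.frame(records))
  if (any(records$total_species <= 0)) {
    stop("degenerate family/families with zero total species: ",
         paste(records$family[records$total_species <= 0], collapse = ", "))
  }
  fr <- as.matrix(records[continent_codes()]) / records$total_species
  rownames(fr) <- records$family
  n_cells <- length(fr)
  n_below <- sum(fr < threshold)
  list(
    fractions = fr,
    n_cells = n_cells,
    n_below = n_below,
    fraction_below = n_below / n_cells
  )
}

#' Export a distribution matrix with its provenance sidecar
#'
#' @param matrix an `sses_matrix`.
#' @param path CSV output path; a JSON sidecar `<path>.json` records the
#'   threshold and degenerate families.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(family = rownames(matrix),
                   as.data.frame(unclass(matrix)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(threshold_used = attr(matrix, "threshold_used"),
         degenerate = as.list(attr(matrix, "degenerate"))),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
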