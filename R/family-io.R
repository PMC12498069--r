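#' Read a family-by-region table
#'
#' Reads the delimited text table that drives the whole pipeline: one row
#' per family with native species counts on the seven continents, the total
#' native species count, and the three curated zone-center flags. Any
#' additional columns (stem age, origin location, formation annotations,
#' life form, dispersal types, ...) are preserved untouched.
#'
#' Required columns: `family`, the seven continent columns of
#' [continent_codes()], `total_species`, and the three zone columns of
#' [zone_codes()]. Missing stem ages are empty cells (read as `NA`),
#' never 0.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A data frame of class `sses_families`, one row per family.
#' @export
read_family_table <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_sses_families(df)
}

#' Validate a raw data frame as a family table
#'
#' @param df a data frame with the columns described in
#'   [read_family_table()].
#' @return `df` with class `sses_families` prepended.
#' @export
as_sses_families <- function(df) {
  required <- c("family", continent_codes(), "total_species", zone_codes())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("family table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  count_cols <- c(continent_codes(), "total_species")
  for (cc in count_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(v))
      if (anyNA(v) && !anyNA(df[[cc]])) {
        stop("column '", cc, "' is not numeric")
      }
    }
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad) > 0L) {
      stop("negative or non-integer count in column '", cc, "' for row(s): ",
           paste(df$family[bad], collapse = ", "))
    }
    df[[cc]] <- as.integer(v)
  }
  for (zc in zone_codes()) {
    v <- df[[zc]]
    if (!all(v %in% c(0L, 1L))) {
      stop("zone flag column '", zc, "' must be binary (0/1)")
    }
    df[[zc]] <- as.integer(v)
  }
  if (anyDuplicated(df$family)) {
    stop("duplicate family name(s): ",
         paste(unique(df$family[duplicated(df$family)]), collapse = ", "))
  }
  cmax <- do.call(pmax, df[continent_codes()])
  bad <- which(df$total_species < cmax)
  if (length(bad) > 0L) {
    stop("total_species below a continent count for row(s): ",
         paste(df$family[bad], collapse = ", "))
  }
  # empty annotation cells mean "not annotated"
  for (col in c("origin_location", "endemic_area", "life_form")) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[!is.na(v) & v == ""] <- NA
      df[[col]] <- v
    }
  }
  if ("stem_age_ma" %in% names(df)) {
    df$stem_age_ma <- as.numeric(df$stem_age_ma)
    neg <- which(!is.na(df$stem_age_ma) & df$stem_age_ma <= 0)
    if (length(neg) > 0L) {
      stop("non-positive stem age for row(s): ",
           paste(df$family[neg], collapse = ", "))
    }
  }
  class(df) <- unique(c("sses_families", class(df)))
  df
}

#' Write a family table
#'
#' @param records an `sses_families` data frame.
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_family_table <- function(records, path, delim = ",") {
  utils::write.table(records, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a dated Newick tree
#'
#' Parses a Newick file, checks tip-label uniqueness, and assesses
#' ultrametricity (all root-to-tip path lengths equal within
#' `tol * tree height`). The tree is returned as an `ape` `phylo` object
#' with an `"ultrametric"` attribute; non-ultrametric trees are accepted
#' but flagged with a warning, since downstream phylogenetic-signal tests
#' assume equal tip depths.
#'
#' @param path Newick file.
#' @param tol relative ultrametricity tolerance (default `1e-6`).
#' @return A `phylo` object with attribute `ultrametric` (logical).
#' @export
read_newick <- function(path, tol = 1e-6) {
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("failed to parse Newick file '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(tree)) stop("failed to parse Newick file '", path, "'")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  ultra <- is_ultrametric_tree(tree, tol = tol)
  if (!ultra) {
    warning("tree is not ultrametric within tolerance ", tol,
            " * tree height")
  }
  attr(tree, "ultrametric") <- ultra
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h == 0) return(TRUE)
  (max(depths) - min(depths)) <= tol * h
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @param digits branch-length precision.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
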