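#' Origin-location vocabulary: 10 sources in 3 groups
#'
#' Origin locations are recorded as one of 10 source labels and rolled up
#' into three groups: Gondwana (southern supercontinent), Laurasia
#' (northern supercontinent), or both.
#'
#' @return Data frame with columns `source` and `group`.
#' @export
origin_sources <- function() {
  data.frame(
    source = c(
      "Africa", "Antarctica", "Australia", "South America",
      "uncertain Southern Hemisphere",
      "Asia", "North America", "uncertain Northern Hemisphere",
      "tropics", "uncertain"
    ),
    group = c(rep("Gondwana", 5L), rep("Laurasia", 3L), rep("both", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Geologic epoch boundary table (ICS 2023)
#'
#' Ages in Ma, `start_ma > end_ma` (older bound first). Shipped as an
#' editable default for [formation_time_rollup()].
#'
#' @return Data frame with columns `epoch`, `start_ma`, `end_ma`.
#' @export
sses_epochs <- function() {
  data.frame(
    epoch = c("Holocene", "Pleistocene", "Pliocene", "Miocene",
              "Oligocene", "Eocene", "Paleocene", "Late Cretaceous",
              "Early Cretaceous", "Jurassic", "Triassic"),
    start_ma = c(0.0117, 2.58, 5.333, 23.03, 33.9, 56, 66, 100.5, 145,
                 201.4, 251.902),
    end_ma = c(0, 0.0117, 2.58, 5.333, 23.03, 33.9, 56, 66, 100.5, 145,
               201.4),
    stringsAsFactors = FALSE
  )
}

group_column <- function(classification, by) {
  switch(by,
         element = classification$element,
         supertype = as.character(classification$supertype),
         type = classification$type,
         stop("by must be element, supertype or type"))
}

#' Origin-time (stem age) summaries on the natural-log scale
#'
#' Summarises ln(stem age in Ma) per group at the requested hierarchy
#' level and reports the group ordering by mean (and median) ln age.
#' Families without a stem age are excluded and counted in `coverage`.
#'
#' @param records an `sses_families` table with a `stem_age_ma` column.
#' @param classification an `sses_classification`.
#' @param by `"element"` (default), `"supertype"` or `"type"`.
#' @return Object of class `sses_origin_summary`: list with `summary`
#'   (data frame per group: `n`, `mean_ln`, `median_ln`, `q25_ln`,
#'   `q75_ln`), `ordering_by_mean` (group names youngest to oldest),
#'   `ordering_by_median`, `coverage` (list `n_aged`, `n_missing`).
#' @export
origin_time_summary <- function(records, classification, by = "element") {
  if (!"stem_age_ma" %in% names(records)) {
    stop("records lack a stem_age_ma column")
  }
  grp <- stats::setNames(group_column(classification, by),
                         classification$family)
  age <- stats::setNames(records$stem_age_ma, records$family)
  age <- age[names(grp)]
  bad <- which(!is.na(age) & age <= 0)
  if (length(bad) > 0L) {
    stop("non-positive stem age for: ",
         paste(names(age)[bad], collapse = ", "))
  }
  keep <- !is.na(age)
  if (!any(keep)) stop("no family has a stem age")
  ln_age <- log(age[keep])
  g <- grp[keep]
  agg <- function(f) tapply(ln_age, g, f)
  summary_df <- data.frame(
    group = names(agg(length)),
    n = as.integer(agg(length)),
    mean_ln = as.numeric(agg(mean)),
    median_ln = as.numeric(agg(stats::median)),
    q25_ln = as.numeric(agg(function(v) stats::quantile(v, 0.25))),
    q75_ln = as.numeric(agg(function(v) stats::quantile(v, 0.75))),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      summary = summary_df,
      ordering_by_mean = summary_df$group[order(summary_df$mean_ln)],
      ordering_by_median = summary_df$group[order(summary_df$median_ln)],
      coverage = list(n_aged = sum(keep), n_missing = sum(!keep))
    ),
    class = "sses_origin_summary"
  )
}

#' Origin-location counts and percentages per group
#'
#' Rolls the 10 origin sources into the Gondwana / Laurasia / both groups
#' and reports, per hierarchy group, the count and percentage of annotated
#' families in each origin group. Only families with an `origin_location`
#' annotation enter the denominators.
#'
#' @param records an `sses_families` table with an `origin_location`
#'   column (source labels from [origin_sources()]; empty/NA = not
#'   annotated).
#' @param classification an `sses_classification`.
#' @param by hierarchy level, default `"element"`.
#' @return List with `counts` (groups x origin-group matrix),
#'   `percentages` (same shape, rows summing to 100 where annotated),
#'   `n_annotated` per group, `source_counts` (tally of the 10 sources).
#' @export
origin_location_percentages <- function(records, classification,
                                        by = "element") {
  if (!"origin_location" %in% names(records)) {
    stop("records lack an origin_location column")
  }
  src <- origin_sources()
  loc <- stats::setNames(as.character(records$origin_location),
                         records$family)
  loc[loc == ""] <- NA
  known <- !is.na(loc)
  bad <- setdiff(unique(loc[known]), src$source)
  if (length(bad) > 0L) {
    stop("unknown origin source label(s): ", paste(bad, collapse = ", "),
         "; valid labels: ", paste(src$source, collapse = ", "))
  }
  grp <- stats::setNames(group_column(classification, by),
                         classification$family)
  loc <- loc[names(grp)]
  ann <- !is.na(loc)
  ogroup <- src$group[match(loc, src$source)]
  groups <- sort(unique(grp))
  ogroups <- c("Gondwana", "Laurasia", "both")
  counts <- matrix(0L, length(groups), 3L,
                   dimnames = list(groups, ogroups))
  if (any(ann)) {
    tab <- table(grp[ann], ogroup[ann])
    counts[rownames(tab), colnames(tab)] <- tab
  }
  n_ann <- rowSums(counts)
  pct <- 100 * counts / ifelse(n_ann > 0, n_ann, NA)
  list(
    counts = counts,
    percentages = pct,
    n_annotated = n_ann,
    source_counts = table(factor(loc[ann], levels = src$source))
  )
}

#' Formation-factor mention percentages per group
#'
#' For each of the four formation-factor categories — climate, land
#' bridge, tectonic movement and long-distance dispersal (LDD) — reports
#' the percentage of investigated families (those with factor annotations)
#' whose literature mentions the factor.
#'
#' @param records an `sses_families` table with logical/0-1 columns
#'   `ff_climate`, `ff_land_bridge`, `ff_tectonic`, `ff_ldd` (NA = family
#'   not investigated).
#' @param classification an `sses_classification`.
#' @param by hierarchy level, default `"element"`.
#' @return Object of class `sses_factor_summary`: data frame per group and
#'   factor with `n_investigated`, `n_mentioned`, `percent`.
#' @export
formation_factor_percentages <- function(records, classification,
                                         by = "element") {
  factor_cols <- c(climate = "ff_climate", land_bridge = "ff_land_bridge",
                   tectonic_movement = "ff_tectonic", LDD = "ff_ldd")
  missing <- setdiff(factor_cols, names(records))
  if (length(missing) > 0L) {
    stop("records lack formation-factor column(s): ",
         paste(missing, collapse = ", "))
  }
  grp <- stats::setNames(group_column(classification, by),
                         classification$family)
  rec <- records[match(names(grp), records$family), , drop = FALSE]
  investigated <- rowSums(!is.na(rec[, factor_cols, drop = FALSE])) > 0
  rows <- list()
  for (g in sort(unique(grp))) {
    in_g <- grp == g & investigated
    for (f in names(factor_cols)) {
      v <- rec[[factor_cols[[f]]]][in_g]
      n_inv <- sum(!is.na(v))
      n_men <- sum(v == 1, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, factor = f, n_investigated = n_inv,
        n_mentioned = n_men,
        percent = if (n_inv > 0) 100 * n_men / n_inv else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sses_factor_summary", class(out))
  out
}

#' Formation-time roll-up and epoch histogram
#'
#' Pools per-family formation times (points, `formation_start_ma ==
#' formation_end_ma` or missing end, or intervals on the age axis with the
#' older bound first) by distribution type; supertype and element
#' summaries are the union of their member types' collections. Epoch
#' counting is any-overlap: an interval contributes to every epoch it
#' intersects.
#'
#' @param records an `sses_families` table with `formation_start_ma` and
#'   optionally `formation_end_ma` columns (Ma; NA = not annotated).
#' @param classification an `sses_classification`.
#' @param epochs boundary table, default [sses_epochs()].
#' @return List with `intervals` (annotated families with group columns),
#'   `epoch_counts` (overall any-overlap histogram), `by_type`,
#'   `by_supertype`, `by_element` (epoch-count matrices), `n_annotated`.
#' @export
formation_time_rollup <- function(records, classification,
                                  epochs = sses_epochs()) {
  if (!"formation_start_ma" %in% names(records)) {
    stop("records lack a formation_start_ma column")
  }
  start <- records$formation_start_ma
  end <- if ("formation_end_ma" %in% names(records)) {
    records$formation_end_ma
  } else {
    rep(NA_real_, nrow(records))
  }
  end <- ifelse(is.na(end), start, end)
  ann <- !is.na(start)
  bad <- which(ann & start < end)
  if (length(bad) > 0L) {
    stop("formation interval younger at its start (start < end on the ",
         "age axis) for: ", paste(records$family[bad], collapse = ", "))
  }
  idx <- match(classification$family, records$family)
  df <- data.frame(
    family = classification$family,
    type = classification$type,
    supertype = as.character(classification$supertype),
    element = classification$element,
    start_ma = start[idx],
    end_ma = end[idx],
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$start_ma), , drop = FALSE]
  overlap <- function(s, e) {
    # any-overlap of [e, s] with each epoch treated as the half-open age
    # band (end_ma, start_ma], so a boundary point counts in exactly one
    # epoch (the older side of the boundary belongs to the younger epoch)
    (s > epochs$end_ma | epochs$end_ma == 0) & e <= epochs$start_ma
  }
  hits <- t(mapply(function(s, e) overlap(s, e), df$start_ma, df$end_ma))
  if (nrow(df) == 0L) hits <- matrix(FALSE, 0L, nrow(epochs))
  colnames(hits) <- epochs$epoch
  count_by <- function(g) {
    if (nrow(df) == 0L) {
      return(matrix(0L, 0L, nrow(epochs),
                    dimnames = list(NULL, epochs$epoch)))
    }
    out <- rowsum(hits + 0L, g)
    out
  }
  list(
    intervals = df,
    epoch_counts = colSums(hits + 0L),
    by_type = count_by(df$type),
    by_supertype = count_by(df$supertype),
    by_element = count_by(df$element),
    n_annotated = nrow(df)
  )
}
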