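#' Configuration for a full pipeline run
#'
#' @param input either a [synth_config()] (a synthetic bundle is generated
#'   in-run) or a list with paths `families` (CSV/TSV) and optionally
#'   `tree` (Newick) and `truth` (CSV).
#' @param center_threshold family-level center fraction (default 0.04).
#' @param type_center_threshold type-level fraction (default 0.56).
#' @param k_list K-means cluster counts (default `c(3, 6, 18)`).
#' @param n_restarts K-means restarts per K (default 50).
#' @param overrides optional [sses_overrides()] for the K = 18 labelling.
#' @param signal_levels hierarchy levels to test for phylogenetic signal
#'   (default all three).
#' @param n_perm permutations for Blomberg's K (default 499).
#' @param seed global seed; per-stage seeds are derived as
#'   `seed + stage index` (matrix/cluster/relationships/signal order), so
#'   stages can be re-run independently yet reproducibly.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input,
                            center_threshold = 0.04,
                            type_center_threshold = 0.56,
                            k_list = c(3L, 6L, 18L),
                            n_restarts = 50L,
                            overrides = NULL,
                            signal_levels = c("element", "supertype",
                                              "type"),
                            n_perm = 499L,
                            seed = 1L) {
  structure(
    list(input = input, center_threshold = center_threshold,
         type_center_threshold = type_center_threshold,
         k_list = as.integer(k_list), n_restarts = as.integer(n_restarts),
         overrides = overrides, signal_levels = signal_levels,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full classification pipeline
#'
#' Stages, in dependency order: load or generate inputs; build the binary
#' distribution matrix (4 percent rule); K-means at each requested K with
#' the elbow diagnostic; label the K = 18 clusters with distribution
#' types, assign subtypes, and roll counts up the hierarchy; build the
#' type-center matrix (56 percent rule) and run linkage selection and
#' NMDS; test phylogenetic signal at the requested levels (when a tree is
#' available); summarise origins and formation annotations. Outputs and a
#' reproducibility manifest are written under `out_dir` when given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return Object of class `sses_pipeline`: list with `records`, `matrix`,
#'   `clusterings`, `elbow`, `classification`, `rollup`, `type_matrix`,
#'   `selection`, `ordination`, `grouping3`, `signal`, `origin_summary`,
#'   `origin_locations`, `factor_summary`, `formation_times`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # stage 0: inputs
  if (inherits(config$input, "synth_config")) {
    bundle <- generate_full_study(config$input)
    records <- bundle$records
    tree <- bundle$tree
    truth <- bundle$truth
  } else {
    records <- read_family_table(config$input$families)
    tree <- if (!is.null(config$input$tree)) {
      read_newick(config$input$tree)
    }
    truth <- if (!is.null(config$input$truth)) {
      utils::read.csv(config$input$truth, stringsAsFactors = FALSE)
    }
  }
  catalog <- sses_catalog()

  # stage 1: distribution matrix
  m <- withCallingHandlers(
    build_matrix(records, threshold = config$center_threshold),
    warning = note
  )

  # stage 2: clustering
  clusterings <- list()
  for (i in seq_along(config$k_list)) {
    k <- config$k_list[i]
    clusterings[[as.character(k)]] <-
      sses_kmeans(m, k, n_restarts = config$n_restarts,
                  seed = config$seed + 2L)
  }
  elbow <- elbow_scan(m, k_range = seq(2L, min(24L, nrow(m))),
                      n_restarts = max(5L, config$n_restarts %/% 10L),
                      seed = config$seed + 2L)

  # stage 3: classification (K = 18 when requested)
  classification <- rollup <- NULL
  if ("18" %in% names(clusterings)) {
    classification <- withCallingHandlers(
      label_clusters(clusterings[["18"]], catalog, config$overrides,
                     on_tie = "catalog-order"),
      warning = note
    )
    classification <- assign_subtypes(classification, m, records, catalog)
    rollup <- rollup_counts(classification, catalog)
  }

  # stage 4: type relationships
  type_matrix <- selection <- ordination <- grouping3 <- NULL
  if (!is.null(classification)) {
    type_matrix <- type_center_matrix(
      classification, m, threshold = config$type_center_threshold
    )
    D <- euclidean_distances(type_matrix)
    selection <- select_algorithm(D)
    ordination <- nmds(D, seed = config$seed + 3L)
    grouping3 <- grouping_from_dendrogram(
      selection$dendrograms[[selection$selected]], 3L
    )
  }

  # stage 5: phylogenetic signal
  signal <- NULL
  if (!is.null(tree) && !is.null(classification)) {
    signal <- lapply(config$signal_levels, function(level) {
      enc <- encode_and_prune(classification, tree, level, catalog)
      list(
        level = level,
        K = blomberg_k(enc$tree, enc$trait, n_perm = config$n_perm,
                       seed = config$seed + 4L),
        lambda = pagel_lambda(enc$tree, enc$trait)
      )
    })
    names(signal) <- config$signal_levels
  }

  # stage 6: origin / formation summaries
  origin_summary <- origin_locations <- factor_summary <-
    formation_times <- NULL
  if (!is.null(classification)) {
    if ("stem_age_ma" %in% names(records)) {
      origin_summary <- origin_time_summary(records, classification)
    }
    if ("origin_location" %in% names(records)) {
      origin_locations <- origin_location_percentages(records,
                                                      classification)
    }
    if (all(c("ff_climate", "ff_land_bridge", "ff_tectonic", "ff_ldd")
            %in% names(records))) {
      factor_summary <- formation_factor_percentages(records,
                                                     classification)
    }
    if ("formation_start_ma" %in% names(records)) {
      formation_times <- formation_time_rollup(records, classification)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sses")),
    seed = config$seed,
    stage_seeds = list(cluster = config$seed + 2L,
                       nmds = config$seed + 3L,
                       signal = config$seed + 4L),
    center_threshold = config$center_threshold,
    type_center_threshold = config$type_center_threshold,
    k_list = config$k_list,
    n_restarts = config$n_restarts,
    n_families = nrow(records),
    warnings = warnings_log
  )

  out <- structure(
    list(records = records, truth = truth, matrix = m,
         clusterings = clusterings, elbow = elbow,
         classification = classification, rollup = rollup,
         type_matrix = type_matrix, selection = selection,
         ordination = ordination, grouping3 = grouping3, signal = signal,
         origin_summary = origin_summary,
         origin_locations = origin_locations,
         factor_summary = factor_summary,
         formation_times = formation_times,
         manifest = manifest),
    class = "sses_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(result$matrix, file.path(out_dir, "matrix.csv"))
  for (k in names(result$clusterings)) {
    cl <- result$clusterings[[k]]
    utils::write.csv(
      data.frame(family = names(cl$assignments),
                 cluster = unname(cl$assignments)),
      file.path(out_dir, paste0("assignments_k", k, ".csv")),
      row.names = FALSE, quote = FALSE
    )
    utils::write.csv(
      as.data.frame(cl$centers),
      file.path(out_dir, paste0("centers_k", k, ".csv")),
      row.names = FALSE, quote = FALSE
    )
  }
  if (!is.null(result$classification)) {
    write_classification(result$classification,
                         file.path(out_dir, "classification.csv"))
  }
  if (!is.null(result$selection)) {
    utils::write.csv(result$selection$table,
                     file.path(out_dir, "linkage_selection.csv"),
                     row.names = FALSE, quote = FALSE)
    dend <- result$selection$dendrograms[[result$selection$selected]]
    ape::write.tree(ape::as.phylo(dend$hclust),
                    file.path(out_dir, "type_dendrogram.nwk"))
  }
  if (!is.null(result$ordination)) {
    utils::write.csv(
      data.frame(type = rownames(result$ordination$coordinates),
                 result$ordination$coordinates),
      file.path(out_dir, "nmds_coordinates.csv"),
      row.names = FALSE, quote = FALSE
    )
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sses_pipeline <- function(x, ...) {
  cat("SSES pipeline run:", x$manifest$n_families, "families; K =",
      paste(x$manifest$k_list, collapse = "/"), "\n")
  if (!is.null(x$rollup)) {
    cat("element counts:",
        paste(names(x$rollup$element), x$rollup$element, sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(x$ordination)) {
    cat("NMDS stress:", format(x$ordination$stress), "\n")
  }
  invisible(x)
}
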