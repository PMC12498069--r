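fixture_classification <- function(n_per_element = c(cosmopolitan = 20,
                                                     tropical = 43,
                                                     temperate = 30)) {
  type_of <- c(cosmopolitan = "I", tropical = "II", temperate = "XII")
  fam <- character(0); type <- character(0)
  for (el in names(n_per_element)) {
    ids <- sprintf("%s%02d", toupper(substr(el, 1, 3)),
                   seq_len(n_per_element[[el]]))
    fam <- c(fam, ids)
    type <- c(type, rep(type_of[[el]], n_per_element[[el]]))
  }
  data.frame(family = fam, type = type,
             supertype = catalog_supertype(type),
             element = catalog_element(type),
             stringsAsFactors = FALSE)
}

test_that("origin-time summary works on the ln scale", {
  cl <- fixture_classification(c(cosmopolitan = 3, tropical = 3,
                                 temperate = 3))
  rec <- data.frame(family = cl$family,
                    stem_age_ma = c(rep(exp(1), 3),
                                    rep(exp(2), 3),
                                    c(exp(3), exp(3), NA)))
  s <- origin_time_summary(rec, cl)
  expect_equal(s$summary$mean_ln[s$summary$group == "cosmopolitan"], 1)
  expect_equal(s$summary$mean_ln[s$summary$group == "tropical"], 2)
  expect_equal(s$ordering_by_mean,
               c("cosmopolitan", "tropical", "temperate"))
  expect_equal(s$coverage$n_aged, 8L)
  expect_equal(s$coverage$n_missing, 1L)
  rec$stem_age_ma[1] <- -1
  expect_error(origin_time_summary(rec, cl), "stem age")
})

test_that("planted element age ordering is recovered from synthetic data", {
  hits <- vapply(1:20, function(s) {
    b <- generate_families(synth_config(seed = 700 + s))
    cl <- classification_from_truth(b$truth)
    o <- origin_time_summary(b$records, cl)
    identical(o$ordering_by_mean,
              c("cosmopolitan", "tropical", "temperate"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("origin locations roll 10 sources into 3 groups with percentages", {
  cl <- fixture_classification()  # 20 cosmopolitan, 43 tropical families
  rec <- data.frame(family = cl$family,
                    origin_location = NA_character_,
                    stringsAsFactors = FALSE)
  gsrc <- c("Africa", "Australia", "South America")
  # tropical: 43 annotated, 28 Gondwanan
  trop <- cl$family[cl$element == "tropical"]
  rec$origin_location[match(trop[1:28], rec$family)] <-
    rep(gsrc, length.out = 28)
  rec$origin_location[match(trop[29:43], rec$family)] <-
    rep(c("Asia", "North America", "tropics"), length.out = 15)
  # cosmopolitan: 20 annotated, 14 Gondwanan
  cos <- cl$family[cl$element == "cosmopolitan"]
  rec$origin_location[match(cos[1:14], rec$family)] <-
    rep(gsrc, length.out = 14)
  rec$origin_location[match(cos[15:20], rec$family)] <-
    rep("uncertain Northern Hemisphere", 6)
  o <- origin_location_percentages(rec, cl)
  expect_equal(round(o$percentages["tropical", "Gondwana"], 2), 65.12)
  expect_equal(o$counts["tropical", "Gondwana"], 28L)
  expect_equal(o$percentages["cosmopolitan", "Gondwana"], 70)
  expect_equal(o$n_annotated[["cosmopolitan"]], 20L)
  # no annotated families in a group: percentages reported absent
  expect_true(all(is.na(o$percentages["temperate", ])))
  expect_equal(sum(o$counts), sum(!is.na(rec$origin_location)))
  rec$origin_location[1] <- "Atlantis"
  expect_error(origin_location_percentages(rec, cl), "Atlantis")
})

test_that("formation factor percentages match tallies", {
  cl <- fixture_classification(c(cosmopolitan = 17, tropical = 5,
                                 temperate = 4))
  rec <- data.frame(family = cl$family, ff_climate = NA_integer_,
                    ff_land_bridge = NA_integer_,
                    ff_tectonic = NA_integer_, ff_ldd = NA_integer_)
  cos <- which(cl$element == "cosmopolitan")
  rec$ff_ldd[cos] <- c(rep(1L, 16), 0L)
  rec$ff_climate[cos] <- 0L
  f <- formation_factor_percentages(rec, cl)
  row_ldd <- subset(f, group == "cosmopolitan" & factor == "LDD")
  expect_equal(round(row_ldd$percent, 2), 94.12)
  expect_equal(row_ldd$n_investigated, 17L)
  row_cli <- subset(f, group == "cosmopolitan" & factor == "climate")
  expect_equal(row_cli$percent, 0)
  # random flag table equals a brute-force tally
  set.seed(15)
  b <- generate_families(synth_config(seed = 900, n_families = 60))
  cl2 <- classification_from_truth(b$truth)
  f2 <- formation_factor_percentages(b$records, cl2)
  for (i in seq_len(nrow(f2))) {
    col <- c(climate = "ff_climate", land_bridge = "ff_land_bridge",
             tectonic_movement = "ff_tectonic", LDD = "ff_ldd")[[
               f2$factor[i]]]
    fams <- cl2$family[cl2$element == f2$group[i]]
    v <- b$records[[col]][match(fams, b$records$family)]
    inv <- rowSums(!is.na(b$records[match(fams, b$records$family),
                                    c("ff_climate", "ff_land_bridge",
                                      "ff_tectonic", "ff_ldd")])) > 0
    expect_equal(f2$n_investigated[i], sum(!is.na(v[inv])))
    expect_equal(f2$n_mentioned[i], sum(v[inv] == 1, na.rm = TRUE))
  }
  # percentages always within [0, 100]
  expect_true(all(is.na(f2$percent) | (f2$percent >= 0 & f2$percent <= 100)))
})

test_that("formation times bin by epoch with any-overlap counting", {
  cl <- fixture_classification(c(cosmopolitan = 3, tropical = 1,
                                 temperate = 1))
  rec <- data.frame(family = cl$family,
                    formation_start_ma = c(20, 60, NA, 10, 150),
                    formation_end_ma = c(20, 40, NA, 2, 150))
  ft <- formation_time_rollup(rec, cl)
  expect_equal(ft$n_annotated, 4L)
  expect_equal(unname(ft$epoch_counts[["Miocene"]]), 2)   # point 20; 10-2
  expect_equal(unname(ft$epoch_counts[["Paleocene"]]), 1) # 60-40
  expect_equal(unname(ft$epoch_counts[["Eocene"]]), 1)    # 60-40
  expect_equal(unname(ft$epoch_counts[["Jurassic"]]), 1)  # point 150
  expect_equal(unname(ft$epoch_counts[["Pliocene"]]), 1)  # 10-2
  # roll-up monotone: element counts >= its types' counts
  expect_true(all(colSums(ft$by_type) == ft$epoch_counts))
  rec$formation_end_ma[1] <- 30
  expect_error(formation_time_rollup(rec, cl), "younger")
})

test_that("synthetic formation tables match brute-force binning", {
  b <- generate_families(synth_config(seed = 1000))
  cl <- classification_from_truth(b$truth)
  ft <- formation_time_rollup(b$records, cl)
  expect_equal(ft$n_annotated, 121L)
  ep <- sses_epochs()
  idx <- match(ft$intervals$family, b$records$family)
  manual <- vapply(seq_len(nrow(ep)), function(j) {
    s <- ft$intervals$start_ma; e <- ft$intervals$end_ma
    sum((s > ep$end_ma[j] | ep$end_ma[j] == 0) & e <= ep$start_ma[j])
  }, numeric(1))
  expect_equal(unname(ft$epoch_counts), manual)
})
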