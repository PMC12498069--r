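# Shared fixtures, all built in code.

# minimal valid 3-family table covering all required columns
toy_family_df <- function() {
  data.frame(
    family = c("Aaceae", "Bbceae", "Ccceae"),
    asia = c(96L, 4L, 0L),
    europe = c(1L, 96L, 0L),
    africa = c(1L, 0L, 50L),
    north_america = c(1L, 0L, 0L),
    south_america = c(1L, 0L, 0L),
    oceania = c(0L, 0L, 0L),
    antarctica = c(0L, 0L, 0L),
    total_species = c(100L, 100L, 50L),
    z_north_temperate = c(1L, 1L, 0L),
    z_tropical = c(1L, 0L, 1L),
    z_south_temperate = c(1L, 0L, 0L),
    stem_age_ma = c(120.5, NA, 60),
    origin_location = c("Africa", NA, "tropics"),
    stringsAsFactors = FALSE
  )
}

# the hand-computed 3-leaf linkage example: d(A,B)=2, d(A,C)=8, d(B,C)=6
tiny_dist3 <- function() {
  D <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D["A", "B"] <- D["B", "A"] <- 2
  D["A", "C"] <- D["C", "A"] <- 8
  D["B", "C"] <- D["C", "B"] <- 6
  D
}

# six planted archetypes with pairwise Hamming distance >= 4, so the
# elbow diagnostic faces a genuinely 6-cluster structure
sep6_archetypes <- function() {
  m <- rbind(
    A1 = c(0, 1, 0, 0, 0, 1, 1, 0, 0, 1),
    A2 = c(1, 0, 0, 0, 0, 1, 0, 1, 1, 1),
    A3 = c(0, 0, 1, 0, 1, 1, 0, 1, 0, 0),
    A4 = c(0, 1, 0, 1, 0, 0, 0, 1, 1, 1),
    A5 = c(1, 0, 0, 1, 1, 0, 0, 1, 0, 1),
    A6 = c(0, 1, 1, 1, 0, 0, 1, 0, 1, 0)
  )
  colnames(m) <- region_codes()
  m
}

# three element-level prototype patterns (widespread / tropical / temperate)
element3_archetypes <- function() {
  m <- rbind(
    cosmopolitan = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0),
    tropical     = c(0, 1, 0, 1, 0, 1, 0, 1, 1, 0),
    temperate    = c(1, 0, 0, 1, 1, 0, 1, 0, 0, 0)
  )
  colnames(m) <- region_codes()
  m
}

# classification data frame straight from a generator's planted truth
classification_from_truth <- function(truth, catalog = sses_catalog()) {
  out <- data.frame(
    family = truth$family,
    type = truth$archetype,
    subtype = NA_character_,
    supertype = catalog_supertype(truth$archetype, catalog),
    element = catalog_element(truth$archetype, catalog),
    provenance = "curated",
    stringsAsFactors = FALSE
  )
  class(out) <- c("sses_classification", class(out))
  out
}

small_bd_tree <- function(n = 100, seed = 7) {
  generate_tree(synth_config(seed = seed, n_families = n),
                n_tips = n, seed = seed)
}
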