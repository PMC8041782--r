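# Shared fixtures, built in code. All divergences well separated unless a
# test says otherwise.

# small two-phylum profile set with non-zero divergence at every locus
# (so clean records are never exact duplicates)
fixture_profiles <- function(seed = 101, n_genera = 4, n_species = 2) {
  generate_species_profiles(
    n_genera, n_species,
    loci = locus_spec(within_divergence = c(0.02, 0.02, 0.01)),
    seed = seed, n_phyla = 2
  )
}

# single-locus profiles for classifier tests: well-separated genera
fixture_coi_profiles <- function(seed = 202, n_genera = 5, n_species = 3) {
  generate_species_profiles(
    n_genera, n_species,
    loci = locus_spec("COI", 300L, 0.02, 0.10, coding = TRUE),
    seed = seed
  )
}

fixture_config <- function(samples, seed = 1, reads = 1e4, s = 0,
                           indexing = "unique_dual") {
  simulation_config(
    seed = seed, reads_per_library = reads,
    locus_share = c(COI = 0.4, `12S` = 0.3, `18S` = 0.3),
    switch_rate = s, indexing = indexing, samples = samples
  )
}

# brute-force pairwise identity of all template pairs at one locus
all_pairs_identity <- function(profiles, locus) {
  p <- profiles[profiles$locus == locus, ]
  n <- nrow(p)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[[length(out) + 1]] <- tibble::tibble(
        a = p$species[i], b = p$species[j],
        same_genus = p$genus[i] == p$genus[j],
        identity = seq_identity(p$sequence[i], p$sequence[j],
                                type = "global")$identity
      )
    }
  }
  dplyr::bind_rows(out)
}
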