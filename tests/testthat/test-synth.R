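# Simulator: species profiles, planted reference databases, library
# read-count generation and index switching.

test_that("profile generation is deterministic and respects the divergence hierarchy", {
  p1 <- generate_species_profiles(3, 2, loci = locus_spec(), seed = 42)
  p2 <- generate_species_profiles(3, 2, loci = locus_spec(), seed = 42)
  expect_identical(p1, p2)

  # brute-force all-pairs identity: every within-genus pair at least as
  # similar as every between-genus pair
  p <- generate_species_profiles(
    3, 2, loci = locus_spec("L1", 300L, 0.02, 0.10, coding = FALSE), seed = 7
  )
  ids <- all_pairs_identity(p, "L1")
  expect_gt(min(ids$identity[ids$same_genus]),
            max(ids$identity[!ids$same_genus]))
})

test_that("zero within-genus divergence leaves congeners identical at that locus", {
  p <- generate_species_profiles(2, 2, loci = locus_spec(), seed = 5)
  s18 <- p[p$locus == "18S", ]
  for (g in unique(s18$genus)) {
    expect_length(unique(s18$sequence[s18$genus == g]), 1)
  }
  # the variable loci still separate congeners
  coi <- p[p$locus == "COI", ]
  expect_length(unique(coi$sequence), nrow(coi))
})

test_that("invalid divergence settings are rejected", {
  expect_error(generate_species_profiles(2, 2, loci = locus_spec("L", 100L, -0.1, 0.2)),
               "divergence")
  expect_error(generate_species_profiles(2, 2, loci = locus_spec("L", 100L, 0.5, 1.2)),
               "divergence")
  expect_error(generate_species_profiles(2, 2, loci = locus_spec("L", 100L, 0.3, 0.1)),
               "exceed")
})

test_that("reference database planting is complete and manifest-accurate", {
  prof <- fixture_profiles()
  # zero planting: clean records only, empty manifest
  db0 <- generate_reference_database(prof, planting_spec(), seed = 3)
  expect_equal(nrow(db0$manifest), 0)
  expect_true(all(grepl("^C", db0$records$record_id)))
  expect_equal(nrow(db0$records), nrow(prof))

  spec <- planting_spec(n_duplicates = 2, n_short = 1, n_long = 1,
                        n_unidentified = 2, n_mislabelled = 2, n_contaminant = 1)
  db <- generate_reference_database(prof, spec, seed = 11)
  tally <- table(db$manifest$defect)
  expect_equal(unname(tally[c("duplicate", "short", "long", "unidentified",
                              "mislabelled", "contaminant")]),
               c(2L, 1L, 1L, 2L, 2L, 1L), ignore_attr = TRUE)
  expect_equal(nrow(db$records), nrow(prof) + sum(unlist(spec)))
  short <- db$records[db$records$record_id %in%
                        db$manifest$record_id[db$manifest$defect == "short"], ]
  expect_true(all(nchar(short$sequence) < 200))

  # mislabelled records cluster (>= 99% global identity) with a clean record
  # of a different phylum than their stated lineage - all-pairs oracle
  mis <- db$records[grepl("^P_MIS", db$records$record_id), ]
  for (i in seq_len(nrow(mis))) {
    cand <- db$records[grepl("^C", db$records$record_id), ]
    idn <- vapply(cand$sequence, function(s) {
      seq_identity(mis$sequence[i], s, type = "global")$identity
    }, numeric(1))
    best <- cand[which.max(idn), ]
    expect_gte(max(idn), 0.99)
    expect_false(best$phylum == mis$phylum[i])
  }

  expect_error(
    generate_reference_database(prof, planting_spec(n_duplicates = 1000)),
    "exceeds"
  )
})

test_that("library simulation follows count-proportional multinomial sampling", {
  prof <- generate_species_profiles(2, 1, loci = locus_spec("COI", 300L, 0.02, 0.1),
                                    seed = 9)
  cfg <- simulation_config(seed = 21, reads_per_library = 1e4,
                           locus_share = c(COI = 1), samples = "X")
  des <- tibble::tibble(pool_id = "X", species = unique(prof$species),
                        count = c(50L, 50L))
  lib <- simulate_library(des, prof, cfg)
  frac <- lib$reads / sum(lib$reads)
  # binomial sd at p = 0.5, n = 1e4 is 0.005
  expect_true(all(abs(frac - 0.5) < 3 * 0.005))

  # degenerate single-species design: everything to that species
  des1 <- des[1, ]
  des1$count <- 10L
  lib1 <- simulate_library(des1, prof, cfg)
  expect_equal(sum(lib1$reads), 1e4)
  expect_true(all(lib1$species == des1$species))
})

test_that("rare species read counts follow the exact binomial tail", {
  prof <- generate_species_profiles(2, 1, loci = locus_spec("COI", 300L, 0.02, 0.1),
                                    seed = 13)
  des <- tibble::tibble(pool_id = "X", species = unique(prof$species),
                        count = c(999L, 1L))
  cfg <- simulation_config(seed = 31, reads_per_library = 1e5,
                           locus_share = c(COI = 1), samples = "X")
  lib <- simulate_library(des, prof, cfg)
  rare <- lib$reads[lib$species == des$species[2]]
  # central 99% interval of Binomial(1e5, 0.001), computed exactly
  bounds <- qbinom(c(0.005, 0.995), 1e5, 0.001)
  expect_gte(rare, bounds[1])
  expect_lte(rare, bounds[2])
})

test_that("a design species missing one locus template contributes nothing there", {
  prof <- generate_species_profiles(
    2, 1, loci = locus_spec(c("L1", "L2"), c(200L, 200L), 0.02, 0.1,
                            coding = FALSE), seed = 9
  )
  sp <- unique(prof$species)
  prof_missing <- prof[!(prof$species == sp[2] & prof$locus == "L2"), ]
  des <- tibble::tibble(pool_id = "X", species = sp, count = c(50L, 50L))
  cfg <- simulation_config(seed = 21, reads_per_library = 1000,
                           locus_share = c(L1 = 0.5, L2 = 0.5), samples = "X")
  expect_warning(lib <- simulate_library(des, prof_missing, cfg), "zero reads")
  expect_equal(sum(lib$reads), 1000)
  expect_false(sp[2] %in% lib$species[lib$locus == "L2"])
  expect_true(sp[2] %in% lib$species[lib$locus == "L1"])
  # a species absent from the profiles entirely violates the precondition
  expect_error(
    simulate_library(des, prof[prof$species == sp[1], ], cfg),
    "without a profile"
  )
})

test_that("index switching conserves reads and vanishes at rate zero", {
  prof <- fixture_profiles()
  des <- default_mock_designs(100L)[1:8, ]
  des$species <- rep(unique(prof$species)[1:4], 2)
  cfg <- fixture_config(unique(des$pool_id), seed = 2, reads = 5000, s = 0)
  libs <- simulate_libraries(des, prof, cfg)
  sw0 <- simulate_index_switching(libs, cfg)
  expect_equal(sw0$undetermined, 0)
  expect_equal(nrow(sw0$cross), 0)
  expect_equal(sum(sw0$table$reads), sum(libs$reads))

  cfg$switch_rate <- 0.02
  sw <- simulate_index_switching(libs, cfg)
  expect_equal(sum(sw$table$reads) + sw$undetermined, sum(libs$reads))
  expect_equal(sum(sw$pairs$reads), sum(libs$reads))
})

test_that("observed invalid-pair fraction matches the enumeration expectation", {
  # two samples, unique dual, s = 0.01, 1e6 reads; the expectation comes
  # from exact enumeration of (switch-i5?, switch-i7?, destination)
  cfg <- simulation_config(seed = 77, reads_per_library = 5e5,
                           locus_share = c(COI = 1), switch_rate = 0.01,
                           samples = c("A", "B"))
  libs <- tibble::tibble(sample = c("A", "B"), asv_id = "COI_ASV001",
                         locus = "COI", sequence = "ACGT", species = "x",
                         reads = 5e5)
  sw <- simulate_index_switching(libs, cfg, seed = 78)
  p_expect <- expected_invalid_fraction(cfg)
  n <- sum(libs$reads)
  obs <- sw$undetermined / n
  sd <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(obs - p_expect), 3 * sd)
})

test_that("determinism: identical seeds give identical simulations", {
  prof <- fixture_profiles()
  des <- default_mock_designs(100L)[1:4, ]
  des$species <- unique(prof$species)[1:4]
  cfg <- fixture_config(unique(des$pool_id), seed = 5, reads = 2000, s = 0.01)
  run <- function() {
    libs <- simulate_libraries(des, prof, cfg)
    simulate_index_switching(libs, cfg)
  }
  expect_identical(run(), run())
})

test_that("mean observed abundance is unbiased when all biases are 1", {
  prof <- generate_species_profiles(3, 1, loci = locus_spec("COI", 300L, 0.02, 0.1),
                                    seed = 17)
  species <- unique(prof$species)
  des <- tibble::tibble(pool_id = "X", species = species, count = c(60L, 30L, 10L))
  expected <- des$count / sum(des$count)
  n_rep <- 100
  reads <- 2000
  fracs <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 1000 + r, reads_per_library = reads,
                             locus_share = c(COI = 1), samples = "X")
    lib <- simulate_library(des, prof, cfg)
    fracs[r, ] <- lib$reads[match(species, lib$species)] / reads
  }
  mc_sd <- sqrt(expected * (1 - expected) / reads) / sqrt(n_rep)
  expect_true(all(abs(colMeans(fracs) - expected) < 3 * mc_sd))
})
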