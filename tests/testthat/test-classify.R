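# Naive-Bayes classification with bootstrap support, exact-match species
# assignment, and table annotation.

test_that("training probabilities match their closed forms and a recount oracle", {
  prof <- fixture_coi_profiles(n_genera = 3, n_species = 2)
  refs <- profiles_to_records(prof)
  mod <- train_classifier(refs, k = 8)
  N <- nrow(refs)

  # single-sequence genus: each of its words has conditional probability
  # (1 + P_i) / 2 with m = 1, M = 1
  one <- refs[1, ]
  mod1 <- train_classifier(one, k = 8)
  w <- canonical_kmers(one$sequence, 8)
  p_i <- (1 + 0.5) / (1 + 1)
  expect_equal(unname(exp(mod1$log_cond[w[1], one$genus])), (1 + p_i) / 2)
  # a word absent everywhere gets the unseen prior 0.5 / (N + 1)
  expect_equal(unname(exp(mod1$default_log)), (0.5 / 2) / 2)

  # recount oracle: per-genus joint log-probability of a query recomputed
  # directly from word counts
  query <- mutate_dna(refs$sequence[3], 4)
  qw <- canonical_kmers(query, 8)
  genera <- sort(unique(refs$genus))
  oracle <- vapply(genera, function(g) {
    in_g <- refs$genus == g
    M <- sum(in_g)
    sum(vapply(qw, function(word) {
      n_i <- sum(vapply(refs$sequence, function(s) {
        word %in% canonical_kmers(s, 8)
      }, logical(1)))
      m_i <- sum(vapply(refs$sequence[in_g], function(s) {
        word %in% canonical_kmers(s, 8)
      }, logical(1)))
      p_i <- (n_i + 0.5) / (N + 1)
      log((m_i + p_i) / (M + 1))
    }, numeric(1)))
  }, numeric(1))
  got <- colSums(trapscreen:::.query_scores(mod, query))
  expect_equal(unname(got), unname(oracle))
})

test_that("an unambiguous query is assigned its genus with full support", {
  prof <- fixture_coi_profiles()
  refs <- profiles_to_records(prof)
  mod <- train_classifier(refs)
  q <- refs[1, ]
  res <- classify_sequence(mod, q$sequence, classifier_params(seed = 9))
  expect_equal(res$genus, q$genus)
  expect_equal(res$support_genus, 1.0)
  expect_equal(res$assigned_rank, "genus")
  # strand invariance through canonical words
  res_rc <- classify_sequence(mod, revcomp(q$sequence),
                              classifier_params(seed = 9))
  expect_equal(res_rc, res)
  expect_error(classify_sequence(mod, "ACGT"), "shorter than word size")
})

test_that("a query splitting evenly between two genera is truncated to their shared rank", {
  # two genera in different families, same order; the query is half of one
  # genus's template joined to half of the other's, so its words split
  # roughly 50/50 and neither genus can reach 80% support, while every
  # bootstrap winner shares the order
  prof <- generate_species_profiles(
    2, 1, loci = locus_spec("COI", 300L, 0, 0.25, coding = FALSE), seed = 31
  )
  prof$family <- paste0("Family", seq_len(nrow(prof)))  # distinct families
  refs <- profiles_to_records(prof)
  mod <- train_classifier(refs)
  q <- paste0(substr(refs$sequence[1], 1, 150), substr(refs$sequence[2], 151, 300))
  res <- classify_sequence(mod, q, classifier_params(seed = 4, n_bootstrap = 400))
  expect_lt(res$support_genus, 0.80)
  expect_lt(res$support_family, 0.80)
  expect_equal(res$support_order, 1.0)
  expect_equal(res$assigned_rank, "order")
  expect_equal(res$assigned_label, prof$order[1])
})

test_that("bootstrap support matches exhaustive enumeration at small word counts", {
  # two one-sequence genera over short templates; a query of W distinct
  # words drawn half from each genus. With draw size d = ceiling(W/8) = 1,
  # each bootstrap draw picks one word uniformly, so the exact support for
  # the best genus is (number of its words) / W, up to binomial noise; we
  # enumerate the one-word outcomes exactly and compare the full
  # distribution mean at large n_bootstrap.
  refs <- dplyr::bind_rows(
    tibble::tibble(record_id = "A", locus = "L", sequence = "ACGTACGTC",
                   phylum = "P", class = "C", order = "O", family = "F1",
                   genus = "GenA", species = "GenA a", source = "in_house",
                   raw_label = "GenA a"),
    tibble::tibble(record_id = "B", locus = "L", sequence = "TTGGCCTTA",
                   phylum = "P", class = "C", order = "O", family = "F2",
                   genus = "GenB", species = "GenB b", source = "in_house",
                   raw_label = "GenB b")
  )
  mod <- train_classifier(refs, k = 8)
  # a 16-base query has W = 9 distinct words and a draw size of
  # ceiling(9/8) = 2, so the bootstrap outcome space has 9^2 equally
  # likely draws; enumerate them all for the exact support expectation
  q <- paste0(substr(refs$sequence[1], 1, 8), substr(refs$sequence[2], 1, 8))
  s <- trapscreen:::.query_scores(mod, q)
  W <- nrow(s)
  expect_equal(W, 9)
  d <- ceiling(W / 8)
  draws <- as.matrix(expand.grid(rep(list(seq_len(W)), d)))
  winners <- apply(draws, 1, function(rows) {
    trapscreen:::.argmax_genus(mod, colSums(s[rows, , drop = FALSE]))
  })
  res <- classify_sequence(mod, q, classifier_params(seed = 12,
                                                     n_bootstrap = 4000))
  p_exact <- mean(winners == res$genus)
  sd <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$support_genus - p_exact), 4 * sd + 1e-12)
  # both genera share phylum/class/order, so support there is exactly 1
  expect_equal(res$support_order, 1.0)
})

test_that("exact matching assigns species, aggregates congeners, and demands identity", {
  prof <- default_community_profiles()
  refs <- profiles_to_records(prof)
  s18 <- refs[refs$locus == "18S", ]
  acizzia <- s18$sequence[s18$genus == "Acizzia"][1]
  expect_equal(assign_species_exact(acizzia, s18),
               "Acizzia alternata/solanicola")
  coi <- refs[refs$locus == "COI", ]
  q <- coi$sequence[coi$species == "Diuraphis noxia"]
  expect_equal(assign_species_exact(q, coi), "Diuraphis noxia")
  expect_equal(assign_species_exact(revcomp(q), coi), "Diuraphis noxia")
  # one substitution away from every reference: no species label
  expect_true(is.na(assign_species_exact(mutate_dna(q, 1), coi)))
})

test_that("table annotation assigns every simulator ASV and tallies ranks", {
  prof <- default_community_profiles()
  refs <- profiles_to_records(prof)
  des <- default_mock_designs(100L)
  cfg <- fixture_config(unique(des$pool_id), seed = 61, reads = 3000)
  libs <- simulate_libraries(des, prof, cfg)
  models <- lapply(split(refs, refs$locus), train_classifier)
  ann <- classify_table(libs, models, refs, classifier_params(seed = 62))
  expect_true(all(!is.na(ann$species_label)))
  expect_true(all(ann$assigned_rank == "genus"))
  # species exact match never disagrees with the naive-Bayes genus
  expect_true(all(mapply(startsWith, ann$species_label, ann$genus)))
  rc <- attr(ann, "rank_counts")
  manual <- ann |>
    dplyr::distinct(asv_id, .keep_all = TRUE) |>
    dplyr::count(locus, assigned_rank)
  expect_equal(dplyr::arrange(rc, locus, assigned_rank)$n_asv,
               dplyr::arrange(manual, locus, assigned_rank)$n)
  expect_error(classify_table(libs, models["COI"], refs, classifier_params()),
               "no classifier model")
})
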