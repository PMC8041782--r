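# Reference curation cascade: the four decontamination rules, primer-region
# trimming, training-set export, and cascade-level invariants.

record <- function(id, seq, locus = "COI", phylum = "Arthropoda",
                   class = "Insecta", order = "Hemiptera",
                   family = "Aphididae", genus = "Diuraphis",
                   species = "Diuraphis noxia", raw_label = species) {
  tibble::tibble(record_id = id, locus = locus, sequence = seq,
                 phylum = phylum, class = class, order = order,
                 family = family, genus = genus, species = species,
                 source = "public", raw_label = raw_label)
}

test_that("rule 1 removes out-of-range lengths strictly and deduplicates stably", {
  base <- strrep("ACGT", 75)  # 300 bases
  recs <- dplyr::bind_rows(
    record("A", base),
    record("B", base),                       # duplicate of A
    record("C", strrep("A", 150)),           # too short
    record("D", strrep("A", 200)),           # exactly min_len: kept
    record("E", strrep("A", 3000)),          # exactly max_len: kept
    record("F", strrep("A", 3001))           # too long
  )
  out <- filter_length_duplicates(recs)
  expect_setequal(out$records$record_id, c("A", "D", "E"))
  expect_setequal(out$log$record_id, c("B", "C", "F"))
  expect_true(all(out$log$rule == "1"))
  # stable order: the lexicographically first id keeps the sequence
  expect_match(out$log$detail[out$log$record_id == "B"], "duplicate of A")
  # empty input
  e <- filter_length_duplicates(recs[0, ])
  expect_equal(nrow(e$records), 0)
  expect_equal(nrow(e$log), 0)
})

test_that("rule 2 removes insufficiently identified labels and non-binomials", {
  recs <- dplyr::bind_rows(
    record("A", strrep("ACGT", 60), species = NA_character_,
           raw_label = "Acizzia sp."),
    record("B", strrep("ACGT", 60), species = "Diuraphis noxia",
           raw_label = "Diuraphis noxia"),
    record("C", strrep("ACGT", 60), species = NA_character_,
           raw_label = "Aphididae"),
    record("D", strrep("ACGT", 60), species = "Aphis aff. craccivora",
           raw_label = "Aphis aff. craccivora")
  )
  out <- filter_unidentified(recs)
  expect_equal(out$records$record_id, "B")
  expect_setequal(out$log$record_id, c("A", "C", "D"))
  expect_true(all(out$log$rule == "2"))
  # "sp01" must not be caught by the delimited token "sp."
  ok <- filter_unidentified(record("E", strrep("ACGT", 60),
                                   species = "Genus01 sp01",
                                   raw_label = "Genus01 sp01"))
  expect_equal(ok$records$record_id, "E")
})

test_that("rule 3 removes matches above, and keeps matches at, 95% identity", {
  set.seed(401)
  wolb <- record("W1", random_dna(1, 300), genus = "Contaminantia",
                 species = "Contaminantia symbiotica")
  same <- record("A", wolb$sequence)
  far <- record("B", random_dna(1, 300))
  # exactly 95 matches over a 100-column gap-free alignment: substitutions
  # at fixed interior positions so no alignment end is clipped
  contam100 <- random_dna(1, 100)
  ch <- strsplit(contam100, NULL)[[1]]
  for (p in c(10, 20, 30, 40, 50)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  at95 <- record("C", paste(ch, collapse = ""))
  w2 <- record("W2", contam100)
  expect_equal(seq_identity(at95$sequence, w2$sequence, type = "overlap")$identity,
               0.95)
  out <- filter_contaminants(dplyr::bind_rows(same, far, at95),
                             dplyr::bind_rows(wolb, w2))
  expect_setequal(out$records$record_id, c("B", "C"))
  expect_equal(out$log$record_id, "A")
  expect_true(all(out$log$rule == "3"))
})

test_that("rule 4 removes minority lineages in mixed clusters", {
  set.seed(402)
  base <- random_dna(1, 300)
  recs <- dplyr::bind_rows(
    record("A", base),
    record("B", mutate_dna(base, 1)),
    record("C", mutate_dna(base, 2), phylum = "Chordata", class = "Mammalia",
           order = "Rodentia", family = "Muridae", genus = "Mus",
           species = "Mus musculus"),
    record("D", random_dna(1, 300), genus = "Acizzia",
           species = "Acizzia solanicola", family = "Psyllidae")
  )
  out <- cluster_and_flag_misannotations(recs)
  expect_equal(out$log$record_id, "C")
  expect_true(all(out$log$rule == "4"))
  expect_setequal(out$records$record_id, c("A", "B", "D"))
  # lineage-homogeneous clusters: nothing removed
  out2 <- cluster_and_flag_misannotations(recs[c(1, 2, 4), ])
  expect_equal(nrow(out2$log), 0)
})

test_that("greedy cluster membership matches an all-pairs replay oracle", {
  set.seed(403)
  base <- random_dna(1, 300)
  seqs <- c(base, mutate_dna(base, 2), mutate_dna(base, 4),
            mutate_dna(base, 40), random_dna(1, 300))
  recs <- dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
    record(sprintf("R%02d", i), seqs[i])
  }))
  got <- trapscreen:::.greedy_clusters(recs, 0.99)
  # oracle: replay the same deterministic order with a brute-force
  # identity matrix computed up front
  n <- nrow(recs)
  idm <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    idm[i, j] <- seq_identity(recs$sequence[i], recs$sequence[j],
                              type = "global")$identity
  }
  ord <- order(-nchar(recs$sequence), recs$record_id)
  centroids <- integer(0)
  expect_cluster <- integer(n)
  for (i in ord) {
    hit <- which(idm[i, centroids] >= 0.99)
    if (length(hit)) {
      expect_cluster[i] <- hit[1]
    } else {
      centroids <- c(centroids, i)
      expect_cluster[i] <- length(centroids)
    }
  }
  expect_equal(got$cluster, expect_cluster)
})

test_that("primer-region trimming recovers the interior and enforces coverage", {
  set.seed(404)
  primers <- primer_set("COI", "ACGTACGTAA", "TTGCAGGCAT")
  interior <- random_dna(1, 200)
  seed_amplicon <- paste0(primers$forward, interior, revcomp(primers$reverse))
  seeds <- record("S1", seed_amplicon)
  seeds$source <- "in_house"

  full <- record("A", seed_amplicon)              # primers attached
  ch <- strsplit(interior, NULL)[[1]]             # 5 interior substitutions
  for (p in c(50, 80, 110, 140, 170)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  sub5 <- record("B", paste(ch, collapse = ""))
  half <- record("C", substr(interior, 1, 100))   # 50% coverage
  out <- trim_to_primer_region(dplyr::bind_rows(full, sub5, half),
                               primers, seeds)
  expect_setequal(out$records$record_id, c("A", "B"))
  expect_equal(out$records$sequence[out$records$record_id == "A"], interior)
  # substitutions must not move the trim coordinates
  expect_equal(out$records$sequence[out$records$record_id == "B"],
               sub5$sequence)
  expect_equal(out$log$action[out$log$record_id == "C"], "removed")
  expect_error(trim_to_primer_region(record("X", interior, locus = "12S"),
                                     primers, seeds), "12S")
})

test_that("training-set export is deterministic and rank-aware", {
  recs <- dplyr::bind_rows(
    record("A", strrep("ACGT", 60)),
    record("B", strrep("GTCA", 60), species = NA_character_),
    record("C", strrep("TTAA", 60), genus = NA_character_,
           species = NA_character_)
  )
  g1 <- tempfile(fileext = ".fasta"); s1 <- tempfile(fileext = ".fasta")
  ex <- export_training_set(recs, g1, s1)
  gl <- Biostrings::readDNAStringSet(g1)
  sl <- Biostrings::readDNAStringSet(s1)
  expect_equal(length(gl), 2)  # C lacks genus
  expect_equal(length(sl), 1)  # only A has a species
  expect_match(names(gl)[1], "Root;Arthropoda;Insecta;Hemiptera;Aphididae;Diuraphis")
  expect_match(names(sl)[1], "A Diuraphis noxia")
  expect_equal(ex$log$record_id, "C")
  g2 <- tempfile(fileext = ".fasta"); s2 <- tempfile(fileext = ".fasta")
  export_training_set(recs, g2, s2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("the cascade conserves records, is idempotent and clears planted defects", {
  prof <- fixture_profiles()
  db <- generate_reference_database(
    prof, planting_spec(1, 1, 1, 1, 1, 1), seed = 55
  )
  cur <- curate_references(db$records, db$contaminants)
  removed <- cur$log$record_id[cur$log$action == "removed"]
  # conservation: kept + removed = input, nothing removed twice
  expect_equal(nrow(cur$records) + length(removed), nrow(db$records))
  expect_equal(anyDuplicated(removed), 0)
  # completeness: every planted defect removed by its own rule, clean kept
  hit <- dplyr::inner_join(db$manifest, cur$log, by = "record_id")
  expect_setequal(hit$record_id, db$manifest$record_id)
  expect_equal(hit$rule.y, as.character(hit$rule.x))
  expect_false(any(grepl("^C", removed)))
  # idempotence: re-running on the curated output removes nothing
  again <- curate_references(cur$records, db$contaminants)
  expect_equal(nrow(again$records), nrow(cur$records))
  expect_equal(sum(again$log$action == "removed"), 0)
})
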