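# Synthetic species profiles and reference databases with planted defects.
#
# Sequences are generated on a two-level hierarchy: one ancestor per locus,
# genus templates mutated away from the ancestor at the between-genus
# divergence, and species templates mutated away from their genus template at
# the within-genus divergence. A locus with within-genus divergence 0 leaves
# congeners identical (the conserved-locus situation in which species cannot
# be told apart and must be aggregated).

.build_profiles <- function(species_tbl, locus_spec, seed) {
  set.seed(seed)
  .check_locus_spec(locus_spec)
  out <- vector("list", nrow(locus_spec))
  for (i in seq_len(nrow(locus_spec))) {
    ls <- locus_spec[i, ]
    coding <- isTRUE(ls$coding)
    ancestor <- if (coding) random_coding_dna(1, ls$length) else
      random_dna(1, ls$length)
    mut <- if (coding) .mutate_coding else mutate_dna
    n_between <- round(ls$between_divergence * ls$length)
    n_within <- round(ls$within_divergence * ls$length)
    genera <- unique(species_tbl$genus)
    genus_template <- stats::setNames(
      vapply(genera, function(g) mut(ancestor, n_between), character(1)),
      genera
    )
    seqs <- vapply(seq_len(nrow(species_tbl)), function(j) {
      mut(genus_template[[species_tbl$genus[j]]], n_within)
    }, character(1))
    out[[i]] <- dplyr::mutate(species_tbl, locus = ls$locus, sequence = seqs, bias = 1)
  }
  dplyr::bind_rows(out)
}

.check_locus_spec <- function(locus_spec) {
  need <- c("locus", "length", "within_divergence", "between_divergence")
  stopifnot(all(need %in% names(locus_spec)))
  d <- c(locus_spec$within_divergence, locus_spec$between_divergence)
  if (any(d < 0 | d > 1)) stop("divergence settings must lie in [0, 1]")
  if (any(locus_spec$within_divergence > locus_spec$between_divergence)) {
    stop("within-genus divergence must not exceed between-genus divergence")
  }
  invisible(locus_spec)
}

#' Locus settings for profile generation
#'
#' @param locus Locus labels.
#' @param length Template length in bases.
#' @param within_divergence,between_divergence Substitution fractions applied
#'   within a genus (species vs genus template) and between genera (genus
#'   template vs locus ancestor). A within-genus divergence of 0 makes
#'   congeners identical at that locus.
#' @return Tibble of locus settings.
#' @export
locus_spec <- function(locus = c("COI", "12S", "18S"),
                       length = c(300L, 250L, 280L),
                       within_divergence = c(0.02, 0.02, 0),
                       between_divergence = c(0.10, 0.10, 0.05),
                       coding = locus == "COI") {
  tibble(locus = locus, length = as.integer(length),
         within_divergence = within_divergence,
         between_divergence = between_divergence,
         coding = coding)
}

#' Generate species profiles on a taxonomic hierarchy
#'
#' Builds `n_genera * n_species_per_genus` species, each with one template
#' per locus and unit amplification bias, on a generic lineage
#' (phylum -> class -> order 1:1, one family per genus). Genera are spread
#' round-robin over `n_phyla` phyla, which lets fixtures plant cross-phylum
#' mislabels.
#'
#' @param n_genera,n_species_per_genus Counts (each at least 1).
#' @param loci A [locus_spec()] tibble.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#' @param n_phyla Number of phyla to spread genera over.
#' @return Tibble with one row per species x locus: lineage columns
#'   (`phylum` ... `genus`, `species`), `locus`, `sequence`, `bias`.
#' @export
generate_species_profiles <- function(n_genera, n_species_per_genus,
                                      loci = locus_spec(), seed = 1,
                                      n_phyla = 1) {
  stopifnot(n_genera >= 1, n_species_per_genus >= 1, n_phyla >= 1,
            n_phyla <= n_genera)
  g <- rep(seq_len(n_genera), each = n_species_per_genus)
  s <- rep(seq_len(n_species_per_genus), times = n_genera)
  p <- ((g - 1) %% n_phyla) + 1
  species_tbl <- tibble(
    phylum = sprintf("Phylum%02d", p),
    class = sprintf("Class%02d", p),
    order = sprintf("Order%02d", p),
    family = sprintf("Family%02d", g),
    genus = sprintf("Genus%02d", g),
    species = sprintf("Genus%02d exemplum%02d", g, s)
  )
  .build_profiles(species_tbl, loci, seed)
}

#' Synthetic stand-in for the study's mock-community taxa
#'
#' Six Hemiptera species mirroring the composition of the reared colonies
#' used for mock communities: two congeneric psyllids (identical at the
#' conserved 18S-like locus, hence only identifiable there as an aggregate),
#' the tomato potato psyllid, and three aphids including Russian wheat
#' aphid. All sequences are synthetic; only the names and hierarchy mirror
#' the real community.
#'
#' @param loci A [locus_spec()] tibble (default has zero within-genus
#'   divergence at 18S).
#' @param seed Integer RNG seed.
#' @return Profile tibble as in [generate_species_profiles()].
#' @export
default_community_profiles <- function(loci = locus_spec(), seed = 20201) {
  species_tbl <- tibble(
    phylum = "Arthropoda", class = "Insecta", order = "Hemiptera",
    family = c("Psyllidae", "Psyllidae", "Triozidae",
               "Aphididae", "Aphididae", "Aphididae"),
    genus = c("Acizzia", "Acizzia", "Bactericera",
              "Rhopalosiphum", "Metopolophium", "Diuraphis"),
    species = c("Acizzia alternata", "Acizzia solanicola",
                "Bactericera cockerelli", "Rhopalosiphum padi",
                "Metopolophium dirhodum", "Diuraphis noxia")
  )
  .build_profiles(species_tbl, loci, seed)
}

#' Planted database defect counts
#'
#' Defect classes mirror the curation cascade: exact duplicates and
#' out-of-range lengths (rule 1), insufficiently identified labels (rule 2),
#' symbiont-like contaminants (rule 3), and cross-phylum mislabels (rule 4).
#'
#' @param n_duplicates,n_short,n_long,n_unidentified,n_mislabelled,n_contaminant
#'   Non-negative counts of each planted defect.
#' @return Named list of counts.
#' @export
planting_spec <- function(n_duplicates = 0, n_short = 0, n_long = 0,
                          n_unidentified = 0, n_mislabelled = 0,
                          n_contaminant = 0) {
  spec <- list(n_duplicates = n_duplicates, n_short = n_short, n_long = n_long,
               n_unidentified = n_unidentified, n_mislabelled = n_mislabelled,
               n_contaminant = n_contaminant)
  if (any(unlist(spec) < 0)) stop("planting counts must be non-negative")
  spec
}

#' Generate a reference database with planted defects
#'
#' Emits one clean record per species per locus plus the defects requested in
#' `planting`, together with a manifest naming every planted record and its
#' defect class, and the symbiont-like contaminant templates against which
#' planted contaminants were built. Planted record ids sort after clean ids
#' (prefix `P_` vs `C`), so the stable keep-first duplicate rule always keeps
#' the clean copy.
#'
#' @param profiles Profile tibble from [generate_species_profiles()].
#' @param planting A [planting_spec()].
#' @param seed Integer RNG seed.
#' @param n_contaminant_templates Number of symbiont-like templates to
#'   generate (labelled with a `Contaminant` lineage).
#' @return List with `records` (clean + planted), `manifest` (tibble
#'   `record_id`, `defect`, `rule`, `donor`), and `contaminants` (template
#'   records).
#' @export
generate_reference_database <- function(profiles, planting = planting_spec(),
                                        seed = 1, n_contaminant_templates = 3) {
  stopifnot(nrow(profiles) > 0)
  set.seed(seed)
  clean <- profiles |>
    dplyr::arrange(.data$species, .data$locus) |>
    dplyr::mutate(
      record_id = sprintf("C%04d", dplyr::row_number()),
      source = "public", raw_label = .data$species
    ) |>
    dplyr::select("record_id", "locus", "sequence", dplyr::all_of(RANKS),
                  "species", "source", "raw_label")

  len0 <- round(mean(nchar(clean$sequence)))
  contaminants <- tibble(
    record_id = sprintf("W%02d", seq_len(n_contaminant_templates)),
    locus = NA_character_,
    sequence = random_dna(n_contaminant_templates, len0),
    phylum = "Contaminant", class = "Contaminant", order = "Contaminant",
    family = "Contaminant", genus = "Contaminantia",
    species = sprintf("Contaminantia symbiotica%02d", seq_len(n_contaminant_templates)),
    source = "contaminant",
    raw_label = sprintf("Contaminantia symbiotica%02d", seq_len(n_contaminant_templates))
  )

  pick_donors <- function(n, what) {
    if (n > nrow(clean)) {
      stop("planting ", n, " ", what, " records exceeds the ", nrow(clean),
           " available clean records")
    }
    clean[sample(nrow(clean), n), ]
  }
  planted <- list()
  manifest <- list()
  add <- function(rec, defect, rule, donor) {
    planted[[length(planted) + 1]] <<- rec
    manifest[[length(manifest) + 1]] <<- tibble(
      record_id = rec$record_id, defect = defect, rule = rule, donor = donor
    )
  }

  if (planting$n_duplicates > 0) {
    d <- pick_donors(planting$n_duplicates, "duplicate")
    for (i in seq_len(nrow(d))) {
      rec <- d[i, ]
      rec$record_id <- sprintf("P_DUP%02d", i)
      add(rec, "duplicate", 1L, d$record_id[i])
    }
  }
  for (i in seq_len(planting$n_short)) {
    d <- pick_donors(1, "short")
    rec <- d
    rec$record_id <- sprintf("P_SHORT%02d", i)
    rec$sequence <- random_dna(1, sample(80:150, 1))
    add(rec, "short", 1L, NA_character_)
  }
  for (i in seq_len(planting$n_long)) {
    d <- pick_donors(1, "long")
    rec <- d
    rec$record_id <- sprintf("P_LONG%02d", i)
    rec$sequence <- random_dna(1, sample(3100:3500, 1))
    add(rec, "long", 1L, NA_character_)
  }
  for (i in seq_len(planting$n_unidentified)) {
    d <- pick_donors(1, "unidentified")
    rec <- d
    rec$record_id <- sprintf("P_UNID%02d", i)
    rec$sequence <- mutate_dna(d$sequence, max(1, round(0.01 * nchar(d$sequence))))
    rec$species <- NA_character_
    rec$raw_label <- paste(d$genus, "sp.")
    add(rec, "unidentified", 2L, d$record_id)
  }
  if (planting$n_mislabelled > 0) {
    if (length(unique(clean$phylum)) < 2) {
      stop("planting mislabelled records requires profiles spanning >= 2 phyla")
    }
    d_all <- pick_donors(planting$n_mislabelled, "mislabelled")
    for (i in seq_len(nrow(d_all))) {
      d <- d_all[i, ]
      other <- clean[clean$phylum != d$phylum, ]
      wrong <- other[sample(nrow(other), 1), ]
      rec <- d
      rec$record_id <- sprintf("P_MIS%02d", i)
      # near-copy of the donor (one substitution, one base shorter): stays
      # within the 99% clustering radius of the donor, and the longer clean
      # donor founds the cluster under the length-descending greedy order
      mut <- mutate_dna(d$sequence, 1)
      rec$sequence <- substr(mut, 1, nchar(mut) - 1)
      rec[RANKS] <- wrong[RANKS]
      rec$species <- paste(wrong$genus, sprintf("impostor%02d", i))
      rec$raw_label <- rec$species
      add(rec, "mislabelled", 4L, d$record_id)
    }
  }
  for (i in seq_len(planting$n_contaminant)) {
    d <- pick_donors(1, "contaminant")
    w <- contaminants[sample(nrow(contaminants), 1), ]
    rec <- d
    rec$record_id <- sprintf("P_CONT%02d", i)
    rec$sequence <- mutate_dna(w$sequence, round(0.02 * nchar(w$sequence)))
    add(rec, "contaminant", 3L, w$record_id)
  }

  records <- dplyr::bind_rows(clean, dplyr::bind_rows(planted))
  list(
    records = records,
    manifest = if (length(manifest)) dplyr::bind_rows(manifest) else
      tibble(record_id = character(), defect = character(),
             rule = integer(), donor = character()),
    contaminants = contaminants
  )
}
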