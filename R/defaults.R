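# Default study conditions: mock-community designs mirroring the reared
# six-species Hemiptera community (pool sizes 100, 250, 500 and 1000, five
# compositions of 3-5 species, rare pest targets down to a single specimen),
# and an end-to-end wrapper running the full pipeline on simulated data.

.largest_remainder <- function(fracs, total) {
  raw <- fracs / sum(fracs) * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  counts
}

#' Default mock-community designs
#'
#' Five compositions crossed with the four pool sizes. The two pest targets
#' (tomato potato psyllid and Russian wheat aphid) appear as single
#' specimens in some compositions regardless of pool size, so the expected
#' abundance of the rarest species runs from 1% (size 100) down to 0.1%
#' (size 1000); each composition omits at least one community species, so
#' cross-sample contamination is observable as false positives.
#'
#' @param sizes Pool sizes (total specimens).
#' @return Tibble `pool_id`, `species`, `count`.
#' @export
default_mock_designs <- function(sizes = c(100L, 250L, 500L, 1000L)) {
  aa <- "Acizzia alternata"; as_ <- "Acizzia solanicola"
  tpp <- "Bactericera cockerelli"; rp <- "Rhopalosiphum padi"
  md <- "Metopolophium dirhodum"; rwa <- "Diuraphis noxia"
  comps <- list(
    P1 = list(frac = c(0.30, 0.30, 0.40), frac_sp = c(aa, as_, rp),
              singleton = tpp),
    P2 = list(frac = c(0.25, 0.25, 0.25, 0.25), frac_sp = c(aa, as_, md, rwa),
              singleton = NULL),
    P3 = list(frac = c(0.45, 0.45, 0.10), frac_sp = c(rp, md, tpp),
              singleton = rwa),
    P4 = list(frac = c(0.30, 0.30, 0.30, 0.10), frac_sp = c(aa, as_, rwa, rp),
              singleton = tpp),
    P5 = list(frac = c(0.34, 0.33, 0.33), frac_sp = c(rp, md, aa),
              singleton = NULL)
  )
  out <- list()
  for (nm in names(comps)) {
    cp <- comps[[nm]]
    for (sz in sizes) {
      n_single <- length(cp$singleton)
      counts <- .largest_remainder(cp$frac, sz - n_single)
      out[[length(out) + 1]] <- tibble(
        pool_id = sprintf("%s_%04d", nm, sz),
        species = c(cp$frac_sp, cp$singleton),
        count = c(counts, rep(1L, n_single))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Default aggregation map for indistinguishable congeners
#'
#' The two congeneric psyllids cannot be told apart at the conserved
#' 18S-like locus, so they are aggregated to one display label throughout,
#' matching how such species pairs are reported.
#'
#' @return Named character vector mapping species to display labels.
#' @export
default_aggregation <- function() {
  c("Acizzia alternata" = "Acizzia alternata/solanicola",
    "Acizzia solanicola" = "Acizzia alternata/solanicola")
}

#' Turn species profiles into reference records
#'
#' One in-house record per species per locus, already trimmed to the
#' amplicon interior (the simulator's templates), usable directly as
#' classifier training data and exact-match species references.
#'
#' @param profiles Species profile tibble.
#' @return Reference-record tibble.
#' @export
profiles_to_records <- function(profiles) {
  profiles |>
    dplyr::arrange(.data$species, .data$locus) |>
    dplyr::mutate(record_id = sprintf("R%04d", dplyr::row_number()),
                  source = "in_house", raw_label = .data$species) |>
    dplyr::select("record_id", "locus", "sequence", dplyr::all_of(RANKS),
                  "species", "source", "raw_label")
}

#' Run the full pipeline on one simulated experiment
#'
#' Simulates libraries for the given designs, applies index switching,
#' classifies the post-switching ASV table against the profiles' own
#' reference records, estimates the switching contamination rate from the
#' index-pair tally, thresholds at the residual rate t = c^2, merges loci
#' and evaluates detections. This is the package's end-to-end path from
#' specimens to a detection report.
#'
#' @param profiles Species profiles (default: the six-species community).
#' @param designs Mock designs (default: [default_mock_designs()]).
#' @param seed Integer seed driving every stochastic step.
#' @param reads_per_library Reads per library.
#' @param locus_share Named per-locus read fractions.
#' @param indexing `"unique_dual"` or `"combinatorial"`.
#' @param target_c Contamination rate the switching rate is calibrated to
#'   (the estimator's expectation equals this value).
#' @param switch_rate Overrides `target_c` with an explicit rate.
#' @param aggregation Species aggregation map.
#' @param classifier Classifier parameters.
#' @return List: `config`, `libraries`, `switched`, `annotated`, `stats`
#'   (contamination), `combined`, `report` (detection report).
#' @export
run_mock_experiment <- function(profiles = default_community_profiles(),
                                designs = default_mock_designs(),
                                seed = 1L,
                                reads_per_library = 5e4,
                                locus_share = c(COI = 0.4, `12S` = 0.3,
                                                `18S` = 0.3),
                                indexing = "unique_dual",
                                target_c = 0.01,
                                switch_rate = NULL,
                                aggregation = default_aggregation(),
                                classifier = classifier_params()) {
  pools <- unique(designs$pool_id)
  config <- simulation_config(
    seed = seed, reads_per_library = reads_per_library,
    locus_share = locus_share, indexing = indexing, samples = pools
  )
  config$switch_rate <- switch_rate %||%
    switch_rate_for_contamination(target_c, config)
  libs <- simulate_libraries(designs, profiles, config, seed = seed)
  sw <- simulate_index_switching(libs, config, seed = seed + 1L)
  refs <- profiles_to_records(profiles)
  models <- lapply(split(refs, refs$locus), train_classifier)
  classifier$seed <- seed + 2L
  annotated <- classify_table(sw$table, models, refs, classifier)
  stats <- estimate_contamination(sw$pairs)
  combined <- combine_loci(annotated)
  report <- evaluate_detections(combined, designs, t = stats$t,
                                aggregation = aggregation)
  list(config = config, libraries = libs, switched = sw,
       annotated = annotated, stats = stats, combined = combined,
       report = report)
}
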