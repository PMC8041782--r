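# Detection logic: merge per-locus relative abundances (mean across loci
# with reads), call detections against mock-community designs at a relative
# abundance threshold, and summarise locus overlap and group read
# proportions.

#' Combine per-locus abundances into a per-library mean
#'
#' Relative abundance is computed per library per locus (taxon reads over
#' locus reads), then averaged arithmetically across the loci that have
#' reads in that library; loci without reads are excluded from the mean.
#' Libraries with no reads at any locus are dropped with a warning.
#'
#' @param annotated Long tibble with columns `sample`, `locus`, `taxon`,
#'   `reads` (several ASVs of one taxon are pooled).
#' @return Tibble `sample`, `taxon`, `abundance` (combined mean fraction),
#'   `n_loci` (loci detecting the taxon), `loci` (comma-joined labels).
#' @export
combine_loci <- function(annotated) {
  totals <- annotated |>
    dplyr::group_by(.data$sample, .data$locus) |>
    dplyr::summarise(locus_total = sum(.data$reads), .groups = "drop")
  empty <- totals |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(any_reads = any(.data$locus_total > 0), .groups = "drop")
  if (any(!empty$any_reads)) {
    warning("libraries with no reads at any locus dropped: ",
            paste(empty$sample[!empty$any_reads], collapse = ", "))
  }
  n_active <- totals |>
    dplyr::filter(.data$locus_total > 0) |>
    dplyr::count(.data$sample, name = "n_active_loci")
  per_locus <- annotated |>
    dplyr::group_by(.data$sample, .data$locus, .data$taxon) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop") |>
    dplyr::inner_join(totals, by = c("sample", "locus")) |>
    dplyr::filter(.data$locus_total > 0) |>
    dplyr::mutate(rel = .data$reads / .data$locus_total)
  per_locus |>
    dplyr::group_by(.data$sample, .data$taxon) |>
    dplyr::summarise(
      sum_rel = sum(.data$rel),
      max_locus_abundance = max(.data$rel),
      n_loci = sum(.data$reads > 0),
      loci = paste(sort(.data$locus[.data$reads > 0]), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::inner_join(n_active, by = "sample") |>
    dplyr::mutate(abundance = .data$sum_rel / .data$n_active_loci) |>
    dplyr::select("sample", "taxon", "abundance", "max_locus_abundance",
                  "n_loci", "loci")
}

.apply_aggregation <- function(labels, aggregation) {
  if (is.null(aggregation)) return(labels)
  if (is.data.frame(aggregation)) {
    aggregation <- stats::setNames(aggregation$label, aggregation$species)
  }
  mapped <- aggregation[labels]
  ifelse(is.na(mapped), labels, mapped)
}

#' Evaluate detections against mock-community designs
#'
#' A taxon is detected when its post-threshold combined abundance is
#' strictly positive. False positives are detected taxa absent from the
#' design; false negatives are designed taxa not detected. Expected
#' abundance is specimen count over pool size (specimens of similar size are
#' assumed, so counts stand in for biomass). The aggregation map (e.g. two
#' congeners indistinguishable at a conserved locus mapping to one display
#' label) is applied identically to designs and observations.
#'
#' @param combined Tibble from [combine_loci()].
#' @param designs Tibble `pool_id`, `species`, `count`.
#' @param t Optional threshold fraction (or `contamination_stats`); when
#'   supplied, [apply_threshold()] is applied here, otherwise `combined` is
#'   assumed already thresholded.
#' @param aggregation Optional species-to-display-label map (named character
#'   vector or tibble with columns `species`, `label`).
#' @param any_locus When `TRUE`, a taxon also counts as detected if any
#'   single locus observed it (after thresholding the combined value);
#'   default uses the combined mean only.
#' @return A `detection_report`: list with `results` (per pool and taxon:
#'   expected and observed abundance, status, locus support), `pools`
#'   (per-pool tallies and the all-species-detected flag) and
#'   `frac_pools_all_detected`.
#' @export
evaluate_detections <- function(combined, designs, t = NULL,
                                aggregation = NULL, any_locus = FALSE) {
  if (inherits(t, "contamination_stats")) t <- t$t
  if (any_locus && !"max_locus_abundance" %in% names(combined)) {
    stop("any_locus mode needs the max_locus_abundance column from combine_loci()")
  }
  obs <- combined |>
    dplyr::mutate(taxon = .apply_aggregation(.data$taxon, aggregation)) |>
    dplyr::group_by(.data$sample, .data$taxon) |>
    dplyr::summarise(
      abundance = sum(.data$abundance),
      call_value = if (any_locus) sum(.data$max_locus_abundance) else
        sum(.data$abundance),
      n_loci = max(.data$n_loci),
      loci = paste(sort(unique(unlist(strsplit(.data$loci, ",")))),
                   collapse = ","),
      .groups = "drop"
    )
  if (!is.null(t)) {
    # strict rule: strictly below the threshold is zeroed, exactly at it kept
    obs$abundance[obs$call_value < t] <- 0
    obs$call_value[obs$call_value < t] <- 0
  }
  obs$abundance[obs$call_value == 0] <- 0
  exp_tbl <- designs |>
    dplyr::mutate(taxon = .apply_aggregation(.data$species, aggregation)) |>
    dplyr::group_by(pool_id = .data$pool_id, taxon = .data$taxon) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$pool_id) |>
    dplyr::mutate(expected_abundance = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$count > 0)
  res <- dplyr::full_join(
    exp_tbl,
    dplyr::rename(obs, pool_id = "sample", observed_abundance = "abundance"),
    by = c("pool_id", "taxon")
  ) |>
    dplyr::mutate(
      expected_abundance = dplyr::coalesce(.data$expected_abundance, 0),
      observed_abundance = dplyr::coalesce(.data$observed_abundance, 0),
      detected = .data$observed_abundance > 0,
      status = dplyr::case_when(
        .data$expected_abundance > 0 & .data$detected ~ "detected",
        .data$expected_abundance > 0 & !.data$detected ~ "false_negative",
        .data$expected_abundance == 0 & .data$detected ~ "false_positive"
      )
    ) |>
    dplyr::filter(!is.na(.data$status)) |>
    dplyr::select("pool_id", "taxon", "expected_abundance",
                  "observed_abundance", "status", "n_loci", "loci") |>
    dplyr::arrange(.data$pool_id, dplyr::desc(.data$expected_abundance))
  pools <- res |>
    dplyr::group_by(.data$pool_id) |>
    dplyr::summarise(
      n_expected = sum(.data$status != "false_positive"),
      n_detected = sum(.data$status == "detected"),
      n_false_positive = sum(.data$status == "false_positive"),
      n_false_negative = sum(.data$status == "false_negative"),
      all_detected = .data$n_false_negative == 0,
      .groups = "drop"
    )
  structure(
    list(results = res, pools = pools,
         frac_pools_all_detected = mean(pools$all_detected)),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("Detection report: %d pools, %.0f%% with all species detected\n",
              nrow(x$pools), 100 * x$frac_pools_all_detected))
  cat(sprintf("  false positives: %d, false negatives: %d\n",
              sum(x$pools$n_false_positive), sum(x$pools$n_false_negative)))
  print(x$pools)
  invisible(x)
}

#' Taxonomic overlap between loci
#'
#' For each non-empty subset of loci, counts the distinct rank labels
#' detected by exactly that subset of loci (read count > 0). Counts over all
#' subsets sum to the total number of distinct labels.
#'
#' @param annotated Annotated ASV tibble with `locus`, `reads` and lineage
#'   columns.
#' @param rank Rank column to compare at (`"family"`, `"genus"`,
#'   `"species_label"`, or any label column).
#' @return Tibble `loci` (comma-joined subset), `n` (label count).
#' @export
locus_overlap <- function(annotated, rank = "genus") {
  if (!rank %in% names(annotated)) stop("unknown rank column: ", rank)
  annotated |>
    dplyr::filter(.data$reads > 0, !is.na(.data[[rank]])) |>
    dplyr::distinct(label = .data[[rank]], .data$locus) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(loci = paste(sort(unique(.data$locus)), collapse = ","),
                     .groups = "drop") |>
    dplyr::count(.data$loci, name = "n")
}

#' Read proportion of a taxonomic group
#'
#' Fraction of classified reads (pooled across loci) carrying a given label
#' at a given rank, per library; the morphology-vs-metabarcoding comparison
#' for bulk samples is made on exactly this quantity.
#'
#' @param annotated Annotated ASV tibble.
#' @param rank Rank column (e.g. `"order"`).
#' @param group Label to tally (e.g. `"Hemiptera"`).
#' @return Tibble `sample`, `n_reads` (classified reads), `fraction`
#'   (`NA` for libraries with zero classified reads).
#' @export
group_read_proportion <- function(annotated, rank, group) {
  if (!rank %in% names(annotated)) stop("unknown rank column: ", rank)
  annotated |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_reads = sum(.data$reads),
      fraction = ifelse(.data$n_reads > 0,
                        sum(.data$reads[.data[[rank]] == group]) / .data$n_reads,
                        NA_real_),
      .groups = "drop"
    )
}
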