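# File formats: reference FASTA with semicolon-delimited lineage headers,
# ASV tables as wide TSV, index-pair tallies as long TSV, designs/configs as
# YAML, reads as FASTQ. All readers return tibbles.

.lineage_string <- function(records, to_species = TRUE) {
  lin <- paste("Root", records$phylum, records$class, records$order,
               records$family, records$genus, sep = ";")
  if (to_species) {
    sp <- ifelse(is.na(records$species), "",
                 paste0(";", gsub(" ", "_", records$species)))
    lin <- paste0(lin, sp)
  }
  lin
}

#' Write reference records as FASTA with lineage headers
#'
#' Headers follow `>ID Root;Phylum;Class;Order;Family;Genus;Genus_species`
#' (the species element is omitted for records without a species rank).
#' Records are written in `record_id` order, so re-export of identical input
#' is byte-identical.
#'
#' @param records Tibble of reference records (see [generate_reference_database()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(records, path) {
  records <- dplyr::arrange(records, .data$record_id)
  seqs <- Biostrings::DNAStringSet(records$sequence)
  names(seqs) <- paste(records$record_id, .lineage_string(records))
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' Read a lineage-header reference FASTA
#'
#' @param path FASTA file written by [write_reference_fasta()] (or following
#'   the same header convention).
#' @param locus Locus label to attach to the records.
#' @param source Provenance label (default `"public"`).
#' @return Tibble of reference records.
#' @export
read_reference_fasta <- function(path, locus = NA_character_, source = "public") {
  seqs <- Biostrings::readDNAStringSet(path)
  id <- unname(sub(" .*", "", names(seqs)))
  lin <- unname(sub("^\\S+ ?", "", names(seqs)))
  parts <- strsplit(lin, ";", fixed = TRUE)
  get <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, character(1))
  species <- gsub("_", " ", get(7))
  tibble(
    record_id = id, locus = locus, sequence = unname(as.character(seqs)),
    phylum = get(2), class = get(3), order = get(4),
    family = get(5), genus = get(6), species = species,
    source = source,
    raw_label = dplyr::coalesce(species, get(6), id)
  )
}

#' Write / read an ASV count table as wide TSV
#'
#' Rows are ASVs (`asv_id`, `locus`, `sequence`), columns are samples,
#' values are integer read counts.
#'
#' @param asv_table Long tibble with columns `asv_id`, `locus`, `sequence`,
#'   `sample`, `reads`.
#' @param path TSV file path.
#' @return `write_asv_table()` returns `path` invisibly; `read_asv_table()`
#'   returns the long tibble.
#' @export
write_asv_table <- function(asv_table, path) {
  wide <- asv_table |>
    dplyr::group_by(.data$asv_id, .data$locus, .data$sequence, .data$sample) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "reads", values_fill = 0L) |>
    dplyr::arrange(.data$asv_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_asv_table
#' @export
read_asv_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  tidyr::pivot_longer(wide, cols = -c("asv_id", "locus", "sequence"),
                      names_to = "sample", values_to = "reads") |>
    dplyr::mutate(reads = as.integer(.data$reads))
}

#' Write / read index-pair tallies as long TSV
#'
#' The tally file has columns `i5`, `i7`, `reads`; the companion valid-pair
#' file has columns `i5`, `i7`.
#'
#' @param pairs Tibble with columns `i5`, `i7`, `reads` (and optionally
#'   `valid`).
#' @param path,valid_path TSV paths for the tally and the valid-pair list.
#' @return Paths invisibly (writers); tibbles (readers).
#' @export
write_index_pairs <- function(pairs, path, valid_path = NULL) {
  readr::write_tsv(dplyr::select(pairs, "i5", "i7", "reads"), path)
  if (!is.null(valid_path)) {
    valid <- dplyr::filter(pairs, .data$valid)
    readr::write_tsv(dplyr::select(valid, "i5", "i7"), valid_path)
  }
  invisible(path)
}

#' @rdname write_index_pairs
#' @export
read_index_pairs <- function(path, valid_path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE)
  valid <- readr::read_tsv(valid_path, show_col_types = FALSE)
  tally_index_pairs(obs, valid)
}

#' Write / read mock-community designs as YAML
#'
#' @param designs Tibble with columns `pool_id`, `species`, `count`.
#' @param path YAML file path.
#' @return `path` invisibly (writer); the designs tibble (reader).
#' @export
write_mock_designs <- function(designs, path) {
  pools <- split(designs, designs$pool_id)
  out <- lapply(pools, function(p) {
    counts <- as.list(stats::setNames(as.integer(p$count), p$species))
    list(pool_id = p$pool_id[1], counts = counts)
  })
  yaml::write_yaml(list(pools = unname(out)), path)
  invisible(path)
}

#' @rdname write_mock_designs
#' @export
read_mock_designs <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw$pools, function(p) {
    tibble(pool_id = p$pool_id, species = names(p$counts),
           count = as.integer(unlist(p$counts)))
  })
}

#' Read / write a simulation configuration as YAML
#'
#' @param config A list created by [simulation_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a validated config (reader).
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$locus_share <- as.list(config$locus_share)  # keep locus names in YAML
  out$sample_index_map <- purrr::pmap(config$sample_index_map,
                                      function(sample, i5, i7) list(sample = sample, i5 = i5, i7 = i7))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- purrr::map_dfr(raw$sample_index_map, as_tibble)
  simulation_config(
    seed = raw$seed, reads_per_library = raw$reads_per_library,
    locus_share = unlist(raw$locus_share), switch_rate = raw$switch_rate,
    indexing = raw$indexing, i5 = unlist(raw$i5), i7 = unlist(raw$i7),
    sample_index_map = map
  )
}

#' Read a primer set from YAML
#'
#' The file holds a `loci` list with `locus`, `forward`, `reverse` (reverse
#' primer given 5'->3' on the reverse strand) and optional `amplicon_min` /
#' `amplicon_max`.
#'
#' @param path YAML file path.
#' @return A primer-set tibble (see [primer_set()]).
#' @export
read_primer_set <- function(path) {
  raw <- yaml::read_yaml(path)
  tbl <- purrr::map_dfr(raw$loci, as_tibble)
  primer_set(tbl$locus, tbl$forward, tbl$reverse,
             amplicon_min = tbl$amplicon_min %||% NA_integer_,
             amplicon_max = tbl$amplicon_max %||% NA_integer_)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path FASTQ file path.
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`
#'   (ASCII-encoded Phred+33 string).
#' @return `read_fastq()` returns a reads tibble; `write_fastq()` returns
#'   `path` invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
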