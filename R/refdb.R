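# Reference-database curation: a fixed four-rule decontamination cascade
# (1 length/duplicates -> 2 insufficient identification -> 3 symbiont
# contaminants -> 4 cross-lineage cluster misannotations), followed by
# trimming to the primer-bounded region and export of classifier training
# sets. The first matching rule removes a record and is the one logged, so
# the audit trail is reproducible.

.log_entry <- function(record_id, rule, action, detail) {
  tibble(record_id = as.character(record_id), rule = as.character(rule),
         action = as.character(action), detail = as.character(detail))
}

.empty_log <- function() {
  tibble(record_id = character(), rule = character(),
         action = character(), detail = character())
}

#' Curation parameters
#'
#' @param min_len,max_len Length bounds in bases. Removal is strict
#'   ("larger than" / "smaller than"), so records of exactly `min_len` or
#'   `max_len` bases are kept.
#' @param exclusion_terms Label tokens indicating insufficient
#'   identification. The default list is a configurable superset of the
#'   usual open-nomenclature qualifiers.
#' @param contaminant_identity Identity fraction above which (strictly) a
#'   record matching the contaminant set is removed.
#' @param contaminant_min_coverage Minimum fraction of the shorter sequence
#'   that a contaminant alignment must cover before its identity counts
#'   (guards against spuriously short perfect overlaps under end-gap-free
#'   alignment).
#' @param cluster_identity Identity threshold for greedy centroid clustering
#'   (records join a centroid at identity >= this value).
#' @return Named list of parameters.
#' @export
curation_params <- function(min_len = 200L, max_len = 3000L,
                            exclusion_terms = c("sp.", "nr.", "aff.", "cf.",
                                                "gen.", "complex", "hybrid",
                                                "environmental", "uncultured",
                                                "undescribed"),
                            contaminant_identity = 0.95,
                            contaminant_min_coverage = 0.5,
                            cluster_identity = 0.99) {
  stopifnot(min_len > 0, min_len < max_len,
            contaminant_identity > 0, contaminant_identity <= 1,
            cluster_identity > 0, cluster_identity <= 1)
  list(min_len = min_len, max_len = max_len, exclusion_terms = exclusion_terms,
       contaminant_identity = contaminant_identity,
       contaminant_min_coverage = contaminant_min_coverage,
       cluster_identity = cluster_identity)
}

#' Rule 1: length bounds and exact duplicates
#'
#' Removes records strictly shorter than `min_len` or strictly longer than
#' `max_len`, then exact-sequence duplicates within each locus, keeping the
#' first record by ascending `record_id`.
#'
#' @param records Reference-record tibble.
#' @param params [curation_params()].
#' @return List with `records` (kept) and `log`.
#' @export
filter_length_duplicates <- function(records, params = curation_params()) {
  if (nrow(records) == 0) return(list(records = records, log = .empty_log()))
  len <- nchar(records$sequence)
  bad_len <- len < params$min_len | len > params$max_len
  log <- .log_entry(records$record_id[bad_len], "1", "removed",
                    sprintf("length %d outside (%d, %d) keep range",
                            len[bad_len], params$min_len, params$max_len))
  kept <- records[!bad_len, ]
  kept <- dplyr::arrange(kept, .data$record_id)
  dup <- duplicated(paste(kept$locus, kept$sequence))
  if (any(dup)) {
    first_id <- kept |>
      dplyr::group_by(.data$locus, .data$sequence) |>
      dplyr::mutate(keeper = min(.data$record_id)) |>
      dplyr::ungroup()
    log <- dplyr::bind_rows(log, .log_entry(
      kept$record_id[dup], "1", "removed",
      sprintf("duplicate of %s", first_id$keeper[dup])
    ))
    kept <- kept[!dup, ]
  }
  list(records = kept, log = log)
}

#' Rule 2: insufficient identification
#'
#' Removes records whose label contains an exclusion term as a delimited
#' token (e.g. "Acizzia sp.") and records lacking a complete binomial
#' species name.
#'
#' @inheritParams filter_length_duplicates
#' @return List with `records` and `log`.
#' @export
filter_unidentified <- function(records, params = curation_params()) {
  if (nrow(records) == 0) return(list(records = records, log = .empty_log()))
  terms <- tolower(params$exclusion_terms)
  has_term <- vapply(seq_len(nrow(records)), function(i) {
    label <- paste(records$raw_label[i],
                   ifelse(is.na(records$species[i]), "", records$species[i]))
    any(tolower(strsplit(label, "\\s+")[[1]]) %in% terms)
  }, logical(1))
  binomial <- !is.na(records$species) & grepl("^\\S+\\s+\\S+", records$species)
  drop <- has_term | !binomial
  detail <- ifelse(has_term[drop], "label contains an exclusion term",
                   "no complete binomial species name")
  list(
    records = records[!drop, ],
    log = .log_entry(records$record_id[drop], "2", "removed", detail)
  )
}

#' Rule 3: symbiont contaminant screen
#'
#' Removes records whose best identity against the contaminant set exceeds
#' (strictly) `contaminant_identity`. Identity is matches over alignment
#' columns under an end-gap-free alignment; an alignment only counts when it
#' covers at least `contaminant_min_coverage` of the shorter sequence.
#'
#' @inheritParams filter_length_duplicates
#' @param contaminant_records Tibble of contaminant reference sequences
#'   (non-empty).
#' @return List with `records` and `log`.
#' @export
filter_contaminants <- function(records, contaminant_records,
                                params = curation_params()) {
  stopifnot(nrow(contaminant_records) > 0)
  if (nrow(records) == 0) return(list(records = records, log = .empty_log()))
  best <- rep(0, nrow(records))
  best_hit <- rep(NA_character_, nrow(records))
  for (j in seq_len(nrow(contaminant_records))) {
    idn <- seq_identity(records$sequence, contaminant_records$sequence[j],
                        type = "overlap")
    min_cov <- params$contaminant_min_coverage *
      pmin(nchar(records$sequence), nchar(contaminant_records$sequence[j]))
    idn$identity[idn$columns < min_cov] <- 0
    upd <- idn$identity > best
    best[upd] <- idn$identity[upd]
    best_hit[upd] <- contaminant_records$record_id[j]
  }
  drop <- best > params$contaminant_identity
  list(
    records = records[!drop, ],
    log = .log_entry(records$record_id[drop], "3", "removed",
                     sprintf("%.4f identity to contaminant %s",
                             best[drop], best_hit[drop]))
  )
}

# Greedy centroid clustering at `threshold` identity (global alignment, end
# gaps penalised). Records are processed in length-descending order (ties by
# record_id); each joins the first centroid, in founding order, with
# identity >= threshold, else founds a new cluster.
.greedy_clusters <- function(records, threshold) {
  ord <- order(-nchar(records$sequence), records$record_id)
  centroids <- integer(0)  # row indices (in `records`) of centroid records
  cluster <- integer(nrow(records))
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(centroids)) {
      idn <- seq_identity(records$sequence[i],
                          records$sequence[centroids[ci]], type = "global")
      if (idn$identity >= threshold) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, i)
      cluster[i] <- length(centroids)
    }
  }
  list(cluster = cluster, centroids = centroids)
}

#' Rule 4: cross-lineage cluster misannotations
#'
#' Clusters records per locus by greedy centroid clustering at
#' `cluster_identity`. A cluster whose members span more than one phylum,
#' class or order is mixed; at the highest mixed rank the minority-lineage
#' members are removed. When the vote ties, members whose lineage differs
#' from the cluster centroid's are removed (the centroid is the cluster's
#' reference by construction).
#'
#' @inheritParams filter_length_duplicates
#' @return List with `records`, `log`, and `flagged` (the removed records,
#'   for manual review).
#' @export
cluster_and_flag_misannotations <- function(records, params = curation_params()) {
  if (nrow(records) == 0) {
    return(list(records = records, log = .empty_log(), flagged = records))
  }
  drop_all <- logical(nrow(records))
  detail_all <- character(nrow(records))
  for (loc in unique(records$locus)) {
    rows <- which(records$locus %in% loc)
    cl <- .greedy_clusters(records[rows, ], params$cluster_identity)
    for (ci in unique(cl$cluster)) {
      members <- rows[cl$cluster == ci]
      if (length(members) < 2) next
      centroid <- rows[cl$centroids[ci]]
      for (rank in c("phylum", "class", "order")) {
        vals <- records[[rank]][members]
        if (length(unique(vals)) <= 1) next
        counts <- table(vals)
        top <- names(counts)[counts == max(counts)]
        majority <- if (length(top) == 1) top else records[[rank]][centroid]
        bad <- members[vals != majority]
        drop_all[bad] <- TRUE
        detail_all[bad] <- sprintf(
          "%s %s disagrees with cluster %s (%s) at %s",
          rank, records[[rank]][bad], ci,
          if (length(top) == 1) "majority" else "centroid", majority
        )
        break
      }
    }
  }
  list(
    records = records[!drop_all, ],
    log = .log_entry(records$record_id[drop_all], "4", "removed",
                     detail_all[drop_all]),
    flagged = records[drop_all, ]
  )
}

#' Trim records to the primer-bounded region
#'
#' Each record is aligned (end gaps free) to the best-matching seed amplicon
#' of its locus; the record is cut to the alignment columns spanning the
#' seed's interior region between (and excluding) the primer binding sites.
#' Records covering less than `min_coverage` of that region are removed.
#' Logged positions are 1-based inclusive.
#'
#' @param records Reference-record tibble.
#' @param primers Primer-set tibble ([primer_set()]).
#' @param seed_records In-house seed amplicons, one or more per locus, whose
#'   sequences are full amplicons (primer + interior + primer).
#' @param min_coverage Minimum fraction of the seed interior that a record
#'   must cover to be retained.
#' @return List with `records` (trimmed) and `log`.
#' @export
trim_to_primer_region <- function(records, primers, seed_records,
                                  min_coverage = 0.8) {
  if (nrow(records) == 0) return(list(records = records, log = .empty_log()))
  miss <- setdiff(unique(records$locus), unique(seed_records$locus))
  if (length(miss)) stop("no seed amplicon for locus: ", paste(miss, collapse = ", "))
  out <- records
  logs <- list()
  drop <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    loc <- records$locus[i]
    seeds <- seed_records[seed_records$locus == loc, ]
    pr <- primers[primers$locus == loc, ]
    if (nrow(pr) != 1) stop("primer set must contain exactly one row for locus ", loc)
    # best-matching seed by overlap identity
    ids <- vapply(seq_len(nrow(seeds)), function(j) {
      seq_identity(records$sequence[i], seeds$sequence[j], type = "overlap")$identity
    }, numeric(1))
    seed <- seeds[which.max(ids), ]
    region_start <- nchar(pr$forward) + 1L
    region_end <- nchar(seed$sequence) - nchar(pr$reverse)
    al <- .align(records$sequence[i], seed$sequence, type = "overlap")
    m <- .alignment_map(al)
    inside <- !is.na(m$s_pos) & m$s_pos >= region_start & m$s_pos <= region_end
    covered <- inside & m$p_char != "-"
    coverage <- sum(covered) / (region_end - region_start + 1L)
    if (coverage < min_coverage) {
      drop[i] <- TRUE
      logs[[length(logs) + 1]] <- .log_entry(
        records$record_id[i], "trim", "removed",
        sprintf("covers %.0f%% of the %s primer-bounded region (floor %.0f%%)",
                100 * coverage, loc, 100 * min_coverage))
      next
    }
    p_in <- m$p_pos[covered]
    from <- min(p_in)
    to <- max(p_in)
    out$sequence[i] <- substr(records$sequence[i], from, to)
    logs[[length(logs) + 1]] <- .log_entry(
      records$record_id[i], "trim", "trimmed",
      sprintf("kept bases %d-%d (1-based inclusive)", from, to))
  }
  list(records = out[!drop, ], log = dplyr::bind_rows(logs))
}

#' Run the full curation cascade
#'
#' Applies rules 1 to 4 in order, then (when primers and seed amplicons are
#' supplied) trims records to the primer-bounded region. Every removal is
#' logged once, under the first rule that matched.
#'
#' @inheritParams filter_contaminants
#' @param primers,seed_records Optional; passed to [trim_to_primer_region()].
#' @return List with `records` (curated) and `log` (the concatenated
#'   curation log).
#' @export
curate_references <- function(records, contaminant_records,
                              params = curation_params(),
                              primers = NULL, seed_records = NULL) {
  s1 <- filter_length_duplicates(records, params)
  s2 <- filter_unidentified(s1$records, params)
  s3 <- filter_contaminants(s2$records, contaminant_records, params)
  s4 <- cluster_and_flag_misannotations(s3$records, params)
  log <- dplyr::bind_rows(s1$log, s2$log, s3$log, s4$log)
  records <- s4$records
  if (!is.null(primers) && !is.null(seed_records)) {
    tr <- trim_to_primer_region(records, primers, seed_records)
    records <- tr$records
    log <- dplyr::bind_rows(log, tr$log)
  }
  list(records = records, log = log)
}

#' Export classifier training sets
#'
#' Writes two FASTA files from curated records: a genus-level lineage-string
#' file (`Root;Phylum;...;Genus`) for the naive-Bayes classifier, and a
#' species-assignment file (`ID Genus species`) for exact matching. Records
#' without a genus rank are excluded from the genus-level file and logged;
#' records without a species rank are absent from the species file. Output
#' order is by `record_id`, so re-export is byte-identical.
#'
#' @param records Curated reference-record tibble.
#' @param genus_path,species_path Output FASTA paths.
#' @return List with the two paths and a `log` of exclusions.
#' @export
export_training_set <- function(records, genus_path, species_path) {
  records <- dplyr::arrange(records, .data$record_id)
  no_genus <- is.na(records$genus)
  g <- records[!no_genus, ]
  gs <- Biostrings::DNAStringSet(g$sequence)
  names(gs) <- paste(g$record_id, .lineage_string(g, to_species = FALSE))
  Biostrings::writeXStringSet(gs, genus_path, width = 80)
  s <- records[!is.na(records$species), ]
  ss <- Biostrings::DNAStringSet(s$sequence)
  names(ss) <- paste(s$record_id, s$species)
  Biostrings::writeXStringSet(ss, species_path, width = 80)
  list(
    genus_path = genus_path, species_path = species_path,
    log = .log_entry(records$record_id[no_genus], "export", "excluded",
                     "missing genus rank")
  )
}
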