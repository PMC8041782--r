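# Taxonomic assignment: a word-based naive-Bayes classifier with bootstrap
# confidence in the style of the RDP classifier, plus exact-match species
# assignment with aggregation of indistinguishable species.
#
# Words are 8-mers, canonicalised (lexicographic min of word and reverse
# complement) so classification is strand-independent. Scoring uses the set
# of distinct query words. Word prior P_i = (n_i + 0.5) / (N + 1) over N
# training sequences; genus-conditional word probability
# (m_i + P_i) / (M + 1) for m_i occurrences among the M sequences of the
# genus.

#' Classifier parameters
#'
#' @param n_bootstrap Number of bootstrap iterations.
#' @param bootstrap_fraction Fraction of the query's distinct words drawn
#'   (with replacement) per iteration; the classic subsample is 1/8.
#' @param min_support Minimum bootstrap support for a rank to be reported;
#'   assignments are truncated at the lowest rank meeting it, and queries
#'   below it at phylum are reported unassigned.
#' @param seed Optional RNG seed for the bootstrap.
#' @return Named list of parameters.
#' @export
classifier_params <- function(n_bootstrap = 100L, bootstrap_fraction = 1 / 8,
                              min_support = 0.80, seed = NULL) {
  stopifnot(bootstrap_fraction > 0, bootstrap_fraction <= 1,
            min_support >= 0, min_support <= 1, n_bootstrap >= 1)
  list(n_bootstrap = as.integer(n_bootstrap),
       bootstrap_fraction = bootstrap_fraction,
       min_support = min_support, seed = seed)
}

#' Train the naive-Bayes classifier for one locus
#'
#' @param records Curated reference records for a single locus, with
#'   lineage columns `phylum` ... `genus`.
#' @param k Word size in bases.
#' @return An `rdp_classifier` object.
#' @export
train_classifier <- function(records, k = 8L) {
  records <- records[!is.na(records$genus), ]
  if (nrow(records) == 0) stop("no training records with a genus rank")
  if (length(unique(records$locus)) > 1) {
    stop("train one classifier per locus; records span several loci")
  }
  words_per_seq <- lapply(records$sequence, canonical_kmers, k = k)
  genera <- sort(unique(records$genus))
  taxonomy <- records |>
    dplyr::distinct(.data$genus, .keep_all = TRUE) |>
    dplyr::arrange(.data$genus) |>
    dplyr::select(dplyr::all_of(rev(RANKS)))
  n_train <- nrow(records)
  all_words <- sort(unique(unlist(words_per_seq)))
  widx <- stats::setNames(seq_along(all_words), all_words)
  # n_i: number of training sequences containing word i
  n_i <- numeric(length(all_words))
  m <- matrix(0, nrow = length(all_words), ncol = length(genera),
              dimnames = list(all_words, genera))
  for (j in seq_len(n_train)) {
    w <- widx[words_per_seq[[j]]]
    n_i[w] <- n_i[w] + 1
    m[w, records$genus[j]] <- m[w, records$genus[j]] + 1
  }
  prior <- (n_i + 0.5) / (n_train + 1)
  m_g <- as.integer(table(factor(records$genus, levels = genera)))
  log_cond <- log(sweep(m + outer(prior, rep(1, length(genera))), 2,
                        m_g + 1, "/"))
  # conditional log-probability of a word never seen in training
  unseen_prior <- 0.5 / (n_train + 1)
  default_log <- log(unseen_prior / (m_g + 1))
  structure(
    list(k = as.integer(k), genera = genera, taxonomy = taxonomy,
         log_cond = log_cond, default_log = default_log,
         n_train = n_train, m_g = m_g,
         locus = records$locus[1]),
    class = "rdp_classifier"
  )
}

#' @export
print.rdp_classifier <- function(x, ...) {
  cat(sprintf("Naive-Bayes classifier (%s): %d sequences, %d genera, %d %d-mers\n",
              x$locus, x$n_train, length(x$genera), nrow(x$log_cond), x$k))
  invisible(x)
}

# Score matrix of a query: rows = distinct canonical query words,
# columns = genera (log conditional probabilities; unseen words get the
# default row).
.query_scores <- function(model, query) {
  w <- canonical_kmers(query, model$k)
  known <- w %in% rownames(model$log_cond)
  s <- matrix(rep(model$default_log, each = length(w)),
              nrow = length(w), ncol = length(model$genera))
  s[known, ] <- model$log_cond[w[known], , drop = FALSE]
  s
}

.argmax_genus <- function(model, score) {
  # ties broken by alphabetical genus label; genera are stored sorted, so
  # the first maximum is the alphabetical winner
  model$genera[which.max(score)]
}

#' Classify one sequence with bootstrap support
#'
#' The best genus maximises the summed log conditional probabilities of the
#' query's distinct words. Support at each rank is the fraction of bootstrap
#' draws (subsamples of the word set) whose winning genus carries the same
#' label at that rank; the assignment is truncated at the lowest rank with
#' support at least `min_support`, and queries below that cutoff at phylum
#' are reported unassigned.
#'
#' @param model An [train_classifier()] model.
#' @param query A DNA sequence of at least `k` bases.
#' @param params [classifier_params()].
#' @return One-row tibble: rank labels, per-rank supports, `assigned_rank`
#'   and `assigned_label`.
#' @export
classify_sequence <- function(model, query, params = classifier_params()) {
  if (nchar(query) < model$k) stop("query shorter than word size k = ", model$k)
  if (!is.null(params$seed)) set.seed(params$seed)
  s <- .query_scores(model, query)
  best <- .argmax_genus(model, colSums(s))
  best_row <- model$taxonomy[match(best, model$genera), ]
  n_draw <- ceiling(nrow(s) * params$bootstrap_fraction)
  winners <- vapply(seq_len(params$n_bootstrap), function(b) {
    rows <- sample.int(nrow(s), n_draw, replace = TRUE)
    .argmax_genus(model, colSums(s[rows, , drop = FALSE]))
  }, character(1))
  win_rows <- model$taxonomy[match(winners, model$genera), ]
  support <- vapply(rev(RANKS), function(r) {
    mean(win_rows[[r]] == best_row[[r]])
  }, numeric(1))  # genus -> phylum order
  ok <- support >= params$min_support
  # lowest rank such that it and every higher rank meet the cutoff
  run <- cumprod(ok[RANKS]) == 1  # phylum -> genus
  assigned_rank <- if (!run[["phylum"]]) "unassigned" else RANKS[max(which(run))]
  tibble(
    phylum = best_row$phylum, class = best_row$class, order = best_row$order,
    family = best_row$family, genus = best_row$genus,
    support_phylum = support[["phylum"]], support_class = support[["class"]],
    support_order = support[["order"]], support_family = support[["family"]],
    support_genus = support[["genus"]],
    assigned_rank = assigned_rank,
    assigned_label = if (assigned_rank == "unassigned") NA_character_ else
      best_row[[assigned_rank]]
  )
}

#' Exact-match species assignment
#'
#' The query must equal a species reference exactly (or equal its reverse
#' complement). One matching species gives that label; several distinct
#' species (e.g. congeners identical at a conserved locus) give an
#' aggregated slash-joined label, sorted alphabetically; no match gives
#' `NA`.
#'
#' @param query A DNA sequence.
#' @param species_records Reference records trimmed to the same region as
#'   the query, with a `species` column.
#' @return A species label, an aggregate label, or `NA_character_`.
#' @export
assign_species_exact <- function(query, species_records) {
  recs <- species_records[!is.na(species_records$species), ]
  hit <- recs$sequence == query | recs$sequence == revcomp(query)
  sp <- sort(unique(recs$species[hit]))
  if (length(sp) == 0) return(NA_character_)
  if (length(sp) == 1) return(sp)
  genus <- sub(" .*", "", sp)
  if (length(unique(genus)) == 1) {
    paste0(genus[1], " ", paste(sub("^\\S+ ", "", sp), collapse = "/"))
  } else {
    paste(sp, collapse = "/")
  }
}

#' Annotate an ASV table with taxonomy
#'
#' Classifies each distinct ASV sequence with its locus's model, attaches
#' exact-match species labels, drops ASVs that cannot be assigned at phylum
#' (the training sets cover a single phylum, so anything below the cutoff
#' there is out of scope), and reports per-rank assignment counts per locus.
#' The `taxon` column holds the display label: the species (or aggregate)
#' label when available, otherwise the genus suffixed with "spp.", otherwise
#' the label at the assigned rank.
#'
#' @param asv_table Long ASV tibble (`sample`, `asv_id`, `locus`,
#'   `sequence`, `reads`).
#' @param models Named list of [train_classifier()] models, one per locus.
#' @param species_records Reference records for exact matching (all loci;
#'   filtered by locus internally).
#' @param params [classifier_params()]. The bootstrap seed is set once for
#'   the whole table.
#' @return The annotated table (unassigned ASVs removed), with the
#'   assignment-count report in `attr(, "rank_counts")` and the unassigned
#'   ASV ids in `attr(, "unassigned")`.
#' @export
classify_table <- function(asv_table, models, species_records,
                           params = classifier_params()) {
  miss <- setdiff(unique(asv_table$locus), names(models))
  if (length(miss)) stop("no classifier model for locus: ",
                         paste(miss, collapse = ", "))
  if (!is.null(params$seed)) set.seed(params$seed)
  inner <- params
  inner$seed <- NULL
  distinct_asv <- dplyr::distinct(asv_table, .data$asv_id, .data$locus,
                                  .data$sequence)
  ann <- purrr::pmap_dfr(distinct_asv, function(asv_id, locus, sequence) {
    cls <- classify_sequence(models[[locus]], sequence, inner)
    sp_recs <- species_records[species_records$locus == locus, ]
    cls$species_label <- assign_species_exact(sequence, sp_recs)
    cls$asv_id <- asv_id
    cls$locus <- locus
    cls
  })
  ann <- ann |>
    dplyr::mutate(taxon = dplyr::case_when(
      !is.na(.data$species_label) & .data$assigned_rank != "unassigned" ~
        .data$species_label,
      .data$assigned_rank == "genus" ~ paste(.data$genus, "spp."),
      .data$assigned_rank == "unassigned" ~ NA_character_,
      .default = .data$assigned_label
    ))
  rank_counts <- ann |>
    dplyr::count(.data$locus, .data$assigned_rank, name = "n_asv")
  unassigned <- ann$asv_id[ann$assigned_rank == "unassigned"]
  out <- asv_table |>
    dplyr::inner_join(
      dplyr::filter(ann, .data$assigned_rank != "unassigned") |>
        dplyr::select(-"locus"),
      by = "asv_id"
    )
  attr(out, "rank_counts") <- rank_counts
  attr(out, "unassigned") <- unassigned
  out
}
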