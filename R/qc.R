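# Read-level quality control: primer trimming with IUPAC-aware matching,
# expected-error filtering, and COI pseudogene screening by frame and stop
# codon checks against an in-house amplicon of known reading frame.

#' Quality-control parameters
#'
#' @param max_expected_errors Reads with expected errors
#'   `EE = sum(10^(-Q/10))` above this value are discarded.
#' @param disallow_ambiguous Discard reads containing an `N`.
#' @param min_len Length floor in bases, exclusive: reads of exactly
#'   `min_len` bases are discarded, reads longer are kept.
#' @return Named list of parameters.
#' @export
qc_params <- function(max_expected_errors = 2.0, disallow_ambiguous = TRUE,
                      min_len = 100L) {
  stopifnot(max_expected_errors >= 0, min_len >= 0)
  list(max_expected_errors = max_expected_errors,
       disallow_ambiguous = disallow_ambiguous, min_len = min_len)
}

#' Expected errors of Phred-scaled quality strings
#'
#' `EE = sum over bases of 10^(-Q/10)` (Phred+33 encoding), the expectation
#' of the number of erroneous bases in the read.
#'
#' @param quality Character vector of ASCII-encoded quality strings.
#' @return Numeric vector of expected errors.
#' @export
expected_errors <- function(quality) {
  vapply(quality, function(q) {
    if (is.na(q) || !nzchar(q)) stop("missing quality string")
    sum(10^(-(utf8ToInt(q) - 33) / 10))
  }, numeric(1), USE.NAMES = FALSE)
}

# IUPAC-aware ungapped prefix match of `primer` against `read` starting at
# position `start`: TRUE when at most `max_mismatch` primer positions fail
# to cover the read base.
.primer_match_at <- function(primer, read, start, max_mismatch) {
  if (start < 1 || start + nchar(primer) - 1 > nchar(read)) return(FALSE)
  p <- Biostrings::DNAString(primer)
  Biostrings::isMatchingAt(p, Biostrings::DNAString(read), at = start,
                           max.mismatch = max_mismatch, with.indels = FALSE,
                           fixed = "subject")
}

#' Assign reads to loci and trim primers
#'
#' A read is assigned to the locus whose forward primer matches its 5' end
#' (IUPAC-aware, at most `max_mismatch` mismatches, no indels). The matched
#' primer is removed; if the reverse-complemented reverse primer is found
#' towards the 3' end it is removed too. Reads matching no forward primer
#' are discarded (`no_primer`); reads matching more than one locus are
#' discarded (`ambiguous`).
#'
#' @param reads Tibble with columns `read_id`, `sequence`, and optionally
#'   `quality` (trimmed alongside the sequence).
#' @param primers Primer-set tibble.
#' @param max_mismatch Mismatch tolerance for primer matching.
#' @return List with `reads` (trimmed, plus a `locus` column) and
#'   `discarded` (tibble `read_id`, `reason`).
#' @export
trim_primers <- function(reads, primers, max_mismatch = 1L) {
  has_qual <- "quality" %in% names(reads)
  kept <- vector("list", nrow(reads))
  disc <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    sq <- reads$sequence[i]
    hit <- which(vapply(seq_len(nrow(primers)), function(j) {
      .primer_match_at(primers$forward[j], sq, 1L, max_mismatch)
    }, logical(1)))
    if (length(hit) == 0) {
      disc[[i]] <- tibble(read_id = reads$read_id[i], reason = "no_primer")
      next
    }
    if (length(hit) > 1) {
      disc[[i]] <- tibble(read_id = reads$read_id[i], reason = "ambiguous")
      next
    }
    pr <- primers[hit, ]
    from <- nchar(pr$forward) + 1L
    to <- nchar(sq)
    rc_rev <- revcomp(pr$reverse)
    # reverse primer sits at the 3' end; search the tail for its rc
    tail_start <- to - nchar(rc_rev) + 1L
    if (.primer_match_at(rc_rev, sq, tail_start, max_mismatch)) {
      to <- tail_start - 1L
    }
    row <- tibble(read_id = reads$read_id[i], locus = pr$locus,
                  sequence = substr(sq, from, to))
    if (has_qual) row$quality <- substr(reads$quality[i], from, to)
    kept[[i]] <- row
  }
  list(reads = dplyr::bind_rows(kept), discarded = dplyr::bind_rows(disc))
}

#' Filter reads on expected errors, ambiguity and length
#'
#' Discards reads whose expected errors exceed `max_expected_errors`, that
#' contain an `N` (when disallowed), or whose length is not strictly greater
#' than `min_len`. When several rules apply, the recorded reason follows the
#' order expected-errors, ambiguity, length.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param params [qc_params()].
#' @return List with `reads` (kept), `discarded` (tibble `read_id`,
#'   `reason`), and `counts` (named discard tallies).
#' @export
filter_reads <- function(reads, params = qc_params()) {
  if (!"quality" %in% names(reads) || anyNA(reads$quality)) {
    stop("reads must carry Phred-scaled quality strings")
  }
  ee <- expected_errors(reads$quality)
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  short <- nchar(reads$sequence) <= params$min_len
  reason <- dplyr::case_when(
    ee > params$max_expected_errors ~ "expected_errors",
    params$disallow_ambiguous & has_n ~ "ambiguous_base",
    short ~ "too_short",
    .default = NA_character_
  )
  drop <- !is.na(reason)
  list(
    reads = reads[!drop, ],
    discarded = tibble(read_id = reads$read_id[drop], reason = reason[drop]),
    counts = c(
      kept = sum(!drop),
      expected_errors = sum(reason == "expected_errors", na.rm = TRUE),
      ambiguous_base = sum(reason == "ambiguous_base", na.rm = TRUE),
      too_short = sum(reason == "too_short", na.rm = TRUE)
    )
  )
}

#' Screen COI sequences for pseudogene signatures
#'
#' Each sequence is aligned (end gaps free) to an in-house COI amplicon of
#' known reading frame. A sequence is discarded when (a) the net interior
#' indel length is not a multiple of 3 (frame shift), or (b) its translation
#' in the frame inherited from the reference contains a stop codon under the
#' invertebrate mitochondrial genetic code. Nuclear copies of COI commonly
#' carry exactly these signatures.
#'
#' @param sequences Tibble with columns `asv_id` (or `record_id`), `locus`,
#'   `sequence`; every row must be COI.
#' @param frame_ref A single reference amplicon sequence that translates
#'   stop-free in its stated frame.
#' @param codon_start 1-based position in `frame_ref` of the first complete
#'   codon.
#' @param genetic_code A Biostrings genetic code; defaults to invertebrate
#'   mitochondrial (translation table 5).
#' @return Tibble with `asv_id`, `keep`, `reason` (`NA`, `frame_shift` or
#'   `stop_codon`).
#' @export
screen_coi_pseudogenes <- function(sequences, frame_ref, codon_start = 1L,
                                   genetic_code = Biostrings::getGeneticCode("SGC4")) {
  id_col <- if ("asv_id" %in% names(sequences)) "asv_id" else "record_id"
  if ("locus" %in% names(sequences) && any(sequences$locus != "COI")) {
    stop("pseudogene screening is COI-only; non-COI locus in input")
  }
  ref_aa <- .translate_in_frame(frame_ref, codon_start, codon_start, genetic_code)
  if (grepl("*", ref_aa, fixed = TRUE)) {
    stop("frame reference contains a stop codon in its stated frame")
  }
  res <- lapply(seq_len(nrow(sequences)), function(i) {
    sq <- sequences$sequence[i]
    al <- .align(sq, frame_ref, type = "overlap")
    ins <- sum(BiocGenerics::width(unlist(Biostrings::insertion(al))))
    del <- sum(BiocGenerics::width(unlist(Biostrings::deletion(al))))
    if ((ins - del) %% 3 != 0) {
      return(tibble(keep = FALSE, reason = "frame_shift"))
    }
    q_start <- BiocGenerics::start(Biostrings::pattern(al))
    r_start <- BiocGenerics::start(Biostrings::subject(al))
    # frame offset of the query's first aligned base, inherited from the
    # reference position it aligns to
    offset <- (r_start - codon_start) %% 3
    first_codon <- q_start + ((3 - offset) %% 3)
    aa <- .translate_in_frame(sq, first_codon, first_codon, genetic_code)
    if (grepl("*", aa, fixed = TRUE)) {
      return(tibble(keep = FALSE, reason = "stop_codon"))
    }
    tibble(keep = TRUE, reason = NA_character_)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(asv_id = sequences[[id_col]], .before = 1)
}

.translate_in_frame <- function(x, from, codon_start, genetic_code) {
  n_codons <- (nchar(x) - from + 1) %/% 3
  if (n_codons < 1) return("")
  sub <- substr(x, from, from + 3 * n_codons - 1)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     genetic.code = genetic_code,
                                     if.fuzzy.codon = "X"))
}
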