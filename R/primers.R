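#' Define a multi-locus primer set
#'
#' One row per locus: forward and reverse primer (both written 5'->3', the
#' reverse primer on the reverse strand, as primers are ordered), and an
#' optional expected amplicon length range.
#'
#' @param locus Locus labels.
#' @param forward,reverse Primer sequences over the IUPAC alphabet.
#' @param amplicon_min,amplicon_max Optional expected amplicon length range
#'   in bases.
#' @return Tibble with columns `locus`, `forward`, `reverse`,
#'   `amplicon_min`, `amplicon_max`.
#' @export
primer_set <- function(locus, forward, reverse,
                       amplicon_min = NA_integer_, amplicon_max = NA_integer_) {
  stopifnot(length(locus) == length(forward), length(locus) == length(reverse))
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", toupper(c(forward, reverse)))
  if (!all(ok)) stop("primers must be non-empty IUPAC DNA sequences")
  tibble(
    locus = locus, forward = toupper(forward), reverse = toupper(reverse),
    amplicon_min = as.integer(amplicon_min), amplicon_max = as.integer(amplicon_max)
  )
}

#' Default synthetic primer set for the three marker loci
#'
#' Degenerate 20-mers for COI-, 12S- and 18S-like loci, with degeneracies
#' placed towards the 3' end in the style of multiplexed metabarcoding
#' primers. These primers flank the simulator's templates when amplicons or
#' FASTQ reads are emitted.
#'
#' @return A primer-set tibble.
#' @export
default_primer_set <- function() {
  primer_set(
    locus = c("COI", "12S", "18S"),
    forward = c("GGTCAACAAATCATAAAGAYAT", "AAACTAGGATTAGATACCCYA", "GGTGGTGCATGGCCGTYCTT"),
    reverse = c("TAAACTTCAGGGTGACCAAARA", "TTTACGACTTATCTCCYCT", "GATCCTTCYGCAGGTTCACC"),
    amplicon_min = c(337L, 337L, 337L),
    amplicon_max = c(398L, 398L, 398L)
  )
}
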