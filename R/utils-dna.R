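#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

RANKS <- c("phylum", "class", "order", "family", "genus")

#' Random DNA sequences
#'
#' Draws uniform-composition DNA strings. Used by the simulator for locus
#' ancestors, planted out-of-range records and symbiont-like contaminant
#' templates.
#'
#' @param n Number of sequences.
#' @param length Length of each sequence in bases (recycled to `n`).
#' @return Character vector of `n` sequences over A/C/G/T.
#' @export
random_dna <- function(n, length) {
  length <- rep_len(length, n)
  vapply(length, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Substitute bases at randomly chosen positions
#'
#' Each chosen position is replaced by one of the three other bases, so every
#' substitution is a real difference. Positions are sampled without
#' replacement.
#'
#' @param x A single DNA string.
#' @param n_sub Number of positions to substitute (0 returns `x` unchanged).
#' @return The mutated sequence.
#' @export
mutate_dna <- function(x, n_sub) {
  stopifnot(length(x) == 1, n_sub >= 0)
  if (n_sub == 0) return(x)
  bases <- strsplit(x, NULL)[[1]]
  n_sub <- min(n_sub, length(bases))
  pos <- sample(length(bases), n_sub)
  alt <- c("A", "C", "G", "T")
  bases[pos] <- vapply(bases[pos], function(b) sample(setdiff(alt, b), 1), character(1))
  paste(bases, collapse = "")
}

.STOPS <- c("TAA", "TAG")  # invertebrate mitochondrial code (table 5)

#' Random coding DNA without stop codons
#'
#' Draws random codons in frame 1, excluding the stop codons of the
#' invertebrate mitochondrial code, so the result translates stop-free.
#' Used for COI-like templates that must pass pseudogene screening.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bases (rounded down to codons).
#' @return Character vector of stop-free coding sequences.
#' @export
random_coding_dna <- function(n, length) {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, .STOPS)
  n_codon <- length %/% 3
  vapply(seq_len(n), function(i) {
    paste(sample(codons, n_codon, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitutions that never create a frame-1 stop codon.
.mutate_coding <- function(x, n_sub) {
  if (n_sub == 0) return(x)
  bases <- strsplit(x, NULL)[[1]]
  pos <- sample(length(bases), min(n_sub, length(bases)))
  alt <- c("A", "C", "G", "T")
  for (p in pos) {
    ci <- (p - 1) %/% 3
    frame_pos <- p - 3 * ci
    codon <- bases[(3 * ci + 1):(3 * ci + 3)]
    for (b in sample(setdiff(alt, bases[p]))) {
      cand <- codon
      cand[frame_pos] <- b
      if (!(paste(cand, collapse = "") %in% .STOPS)) {
        bases[p] <- b
        break
      }
    }
  }
  paste(bases, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Distinct canonical k-mers of a sequence
#'
#' A word is canonicalised as the lexicographic minimum of itself and its
#' reverse complement, making downstream classification strand-independent.
#'
#' @param x A single DNA string.
#' @param k Word size in bases.
#' @return Character vector of distinct canonical k-mers, in order of first
#'   occurrence.
#' @export
canonical_kmers <- function(x, k) {
  l <- nchar(x)
  if (l < k) stop("sequence shorter than word size k = ", k)
  starts <- seq_len(l - k + 1)
  fwd <- substring(x, starts, starts + k - 1)
  rcx <- revcomp(x)
  rev <- substring(rcx, l - starts - k + 2, l - starts + 1)
  unique(pmin(fwd, rev))
}
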