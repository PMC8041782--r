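# Pairwise alignment conventions used throughout the package.
#
# Identity is defined as matches / alignment columns, gaps counting as
# columns. Two modes are used:
#   * "global"  - end gaps penalised (Needleman-Wunsch); used for 99%
#                 similarity clustering, where full-length agreement matters.
#   * "overlap" - end gaps free; used for the contaminant screen and for
#                 mapping records onto seed amplicons, where records may be
#                 fragments or carry flanking sequence.
# An overlap alignment of unrelated sequences can be a short, spuriously
# perfect match, so overlap-mode callers additionally require a minimum
# aligned coverage of the shorter sequence before an identity counts.

#' @import methods
#' @importMethodsFrom Biostrings nchar as.character unlist
NULL

.sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
}

.align <- function(pattern, subject, type) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(pattern), Biostrings::DNAString(subject),
    type = type, substitutionMatrix = .sub_matrix(),
    gapOpening = 4, gapExtension = 1
  )
}

#' Pairwise identity of sequences against one subject
#'
#' @param x Character vector of query sequences.
#' @param subject A single subject sequence.
#' @param type `"global"` (end gaps penalised) or `"overlap"` (end gaps free).
#' @return Tibble with one row per query: `identity` (matches over alignment
#'   columns, gaps counted) and `columns` (alignment length; for
#'   `"overlap"`, the aligned region only).
#' @export
seq_identity <- function(x, subject, type = c("global", "overlap")) {
  type <- match.arg(type)
  al <- .align(x, subject, type)
  tibble(
    identity = Biostrings::nmatch(al) / nchar(al),
    columns = nchar(al)
  )
}

# Column-by-column map of an alignment: for each alignment column, the
# 1-based position in pattern and subject (NA where gapped).
.alignment_map <- function(al) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), NULL)[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), NULL)[[1]]
  p_pos <- cumsum(p != "-") + BiocGenerics::start(Biostrings::pattern(al)) - 1L
  s_pos <- cumsum(s != "-") + BiocGenerics::start(Biostrings::subject(al)) - 1L
  p_pos[p == "-"] <- NA_integer_
  s_pos[s == "-"] <- NA_integer_
  tibble(column = seq_along(p), p_char = p, s_char = s, p_pos = p_pos, s_pos = s_pos)
}
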