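# Index-switching contamination: tally index pairs over the full i5 x i7
# grid, estimate the single-end switching contamination rate c from reads on
# invalid pairs, and derive the residual misidentification threshold t = c^2
# (a read is only misassigned to a *valid* foreign pair when both of its
# indexes switch, so the double-switch rate bounds what per-library relative
# abundance can be trusted).

# Cells reachable from any valid pair by switching exactly one end.
.switch_cells <- function(i5_pool, i7_pool, valid_pairs) {
  valid_key <- paste(valid_pairs$i5, valid_pairs$i7)
  reach <- character(0)
  for (r in seq_len(nrow(valid_pairs))) {
    reach <- c(reach,
               paste(setdiff(i5_pool, valid_pairs$i5[r]), valid_pairs$i7[r]),
               paste(valid_pairs$i5[r], setdiff(i7_pool, valid_pairs$i7[r])))
  }
  reach <- unique(reach)
  list(offdiag = length(reach), invalid = sum(!(reach %in% valid_key)))
}

#' Tally reads over the full index-pair grid
#'
#' Accepts either per-read observations (columns `i5`, `i7`) or pre-tallied
#' counts (an additional `reads` column); pre-tallied input is passed through
#' unchanged (idempotence). The result covers the complete i5 x i7 grid with
#' zeros for unobserved pairs, and flags the valid (applied) pairs.
#'
#' @param observations Tibble with columns `i5`, `i7` and optionally `reads`.
#' @param valid_pairs Tibble with columns `i5`, `i7`: pairs applied during
#'   library preparation.
#' @param i5_pool,i7_pool Declared index pools; default to the values seen in
#'   observations and valid pairs. Observed values outside a declared pool
#'   are an error.
#' @return Tibble `i5`, `i7`, `reads`, `valid` over the full grid.
#' @export
tally_index_pairs <- function(observations, valid_pairs,
                              i5_pool = NULL, i7_pool = NULL) {
  if (!"reads" %in% names(observations)) observations$reads <- 1
  i5_pool <- i5_pool %||% sort(unique(c(observations$i5, valid_pairs$i5)))
  i7_pool <- i7_pool %||% sort(unique(c(observations$i7, valid_pairs$i7)))
  bad <- c(setdiff(observations$i5, i5_pool), setdiff(observations$i7, i7_pool))
  if (length(bad)) {
    stop("observed index values outside the declared pools: ",
         paste(unique(bad), collapse = ", "))
  }
  tallied <- observations |>
    dplyr::group_by(.data$i5, .data$i7) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  grid <- tidyr::expand_grid(i5 = i5_pool, i7 = i7_pool)
  grid |>
    dplyr::left_join(tallied, by = c("i5", "i7")) |>
    dplyr::mutate(
      reads = dplyr::coalesce(.data$reads, 0),
      valid = paste(.data$i5, .data$i7) %in% paste(valid_pairs$i5, valid_pairs$i7)
    )
}

#' Estimate the index-switching contamination rate
#'
#' The single-end contamination rate is estimated from the read mass on
#' invalid pairs:
#' `c = (R_invalid / R_total) * (C_offdiag / C_invalid)`,
#' where `C_offdiag` counts grid cells reachable from a valid pair by a
#' single-end switch and `C_invalid` counts those that are invalid. Under
#' unique dual indexing every single-switch destination is invalid and the
#' correction factor is 1, so `c` reduces to the invalid-read fraction;
#' under combinatorial indexing some destinations are valid and the factor
#' scales up for the unobservable share (uniform-destination assumption).
#' The residual misidentification threshold is `t = c^2`: both ends must
#' switch for a read to land undetectably on another sample's valid pair.
#'
#' @param pairs Grid tibble from [tally_index_pairs()] (columns `i5`, `i7`,
#'   `reads`, `valid`).
#' @return A `contamination_stats` object with fields `c`, `t`, `r_total`,
#'   `r_invalid`, `c_offdiag`, `c_invalid`.
#' @export
estimate_contamination <- function(pairs) {
  stopifnot(all(c("i5", "i7", "reads", "valid") %in% names(pairs)))
  r_total <- sum(pairs$reads)
  if (r_total <= 0) stop("no reads in the index-pair tally")
  valid_pairs <- pairs[pairs$valid, c("i5", "i7")]
  cc <- .switch_cells(unique(pairs$i5), unique(pairs$i7), valid_pairs)
  if (cc$invalid == 0) {
    stop("every single-switch destination is a valid pair (saturated ",
         "combinatorial grid): contamination rate not identifiable")
  }
  r_invalid <- sum(pairs$reads[!pairs$valid])
  c_hat <- (r_invalid / r_total) * (cc$offdiag / cc$invalid)
  structure(
    list(c = c_hat, t = c_hat^2, r_total = r_total, r_invalid = r_invalid,
         c_offdiag = cc$offdiag, c_invalid = cc$invalid),
    class = "contamination_stats"
  )
}

#' @export
print.contamination_stats <- function(x, ...) {
  cat("Index-switching contamination\n")
  cat(sprintf("  contamination rate c: %.4g%% (%g of %g reads on invalid pairs)\n",
              100 * x$c, x$r_invalid, x$r_total))
  cat(sprintf("  residual threshold t = c^2: %.4g%%\n", 100 * x$t))
  cat(sprintf("  single-switch cells: %d reachable, %d invalid\n",
              x$c_offdiag, x$c_invalid))
  invisible(x)
}

#' Filter a taxon table by per-library relative abundance
#'
#' Any taxon with per-library relative abundance strictly below `t` is
#' zeroed ("below this threshold"); a taxon at exactly `t` is retained.
#' Remaining abundances are deliberately not renormalised, so they stay
#' interpretable against the original library depth.
#'
#' @param taxon_table Tibble with columns `sample`, `taxon`, `abundance`
#'   (per-library relative abundance; per-sample sums should be 1 before
#'   filtering).
#' @param t Threshold as a fraction in `[0, 1]` (e.g. `1e-4` for 0.01%), or
#'   a `contamination_stats` object whose `t` is used.
#' @return List with `table` (abundances zeroed where below threshold) and
#'   `removed` (tibble of zeroed taxa with their original abundances).
#' @export
apply_threshold <- function(taxon_table, t) {
  if (inherits(t, "contamination_stats")) t <- t$t
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    stop("threshold t must be a single fraction in [0, 1]")
  }
  sums <- tapply(taxon_table$abundance, taxon_table$sample, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    warning("per-library abundances do not sum to 1 before filtering")
  }
  drop <- taxon_table$abundance < t & taxon_table$abundance > 0
  removed <- taxon_table[drop, ]
  out <- taxon_table
  out$abundance[drop] <- 0
  list(table = out, removed = removed)
}
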