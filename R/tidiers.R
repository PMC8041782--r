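#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted classifier
#'
#' @param x An `rdp_classifier`.
#' @param ... Unused.
#' @return One row per genus: lineage and training-sequence count.
#' @method tidy rdp_classifier
#' @export
tidy.rdp_classifier <- function(x, ...) {
  dplyr::mutate(x$taxonomy, n_sequences = x$m_g, .after = "genus") |>
    as_tibble()
}

#' @rdname tidy.rdp_classifier
#' @method glance rdp_classifier
#' @export
glance.rdp_classifier <- function(x, ...) {
  tibble(locus = x$locus, k = x$k, n_sequences = x$n_train,
         n_genera = length(x$genera), n_words = nrow(x$log_cond))
}

#' Tidy contamination statistics
#'
#' @param x A `contamination_stats` object.
#' @param ... Unused.
#' @return `tidy()`: one row per component (rate, threshold, read and cell
#'   counts). `glance()`: a one-row summary.
#' @method tidy contamination_stats
#' @export
tidy.contamination_stats <- function(x, ...) {
  tibble(
    statistic = c("contamination_rate", "residual_threshold", "reads_total",
                  "reads_invalid", "cells_single_switch", "cells_invalid"),
    value = c(x$c, x$t, x$r_total, x$r_invalid, x$c_offdiag, x$c_invalid)
  )
}

#' @rdname tidy.contamination_stats
#' @method glance contamination_stats
#' @export
glance.contamination_stats <- function(x, ...) {
  tibble(c = x$c, t = x$t, r_total = x$r_total, r_invalid = x$r_invalid,
         c_offdiag = x$c_offdiag, c_invalid = x$c_invalid)
}

#' Tidy a detection report
#'
#' @param x A `detection_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-pool, per-taxon results table. `glance()`: a
#'   one-row summary with pool counts, FP/FN totals and the fraction of
#'   pools with every designed species detected.
#' @method tidy detection_report
#' @export
tidy.detection_report <- function(x, ...) x$results

#' @rdname tidy.detection_report
#' @method glance detection_report
#' @export
glance.detection_report <- function(x, ...) {
  tibble(
    n_pools = nrow(x$pools),
    n_false_positive = sum(x$pools$n_false_positive),
    n_false_negative = sum(x$pools$n_false_negative),
    frac_pools_all_detected = x$frac_pools_all_detected
  )
}
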