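# Mock-community library simulation and index switching.
#
# Reads are simulated as counts: per locus a multinomial draw with species
# probability proportional to specimen count x amplification bias. One ASV
# per distinct template per locus (the pipeline starts post-denoising;
# sequencing error and intraspecific variation are not modelled). Index
# switching replaces each read's i5 and i7 independently with probability
# `switch_rate` by a uniform draw from the in-use pool (the draw may return
# the original value, a silent non-event).

#' Simulation configuration
#'
#' @param seed Integer RNG seed.
#' @param reads_per_library Total reads generated per library.
#' @param locus_share Named per-locus fractions summing to 1.
#' @param switch_rate Per-end, per-read probability `s` that an index is
#'   replaced by a uniform draw from its pool.
#' @param indexing `"unique_dual"` (no i5 or i7 reused across samples) or
#'   `"combinatorial"` (index values reused in different pairings).
#' @param samples Sample labels; used with `indexing` to build a default
#'   index map when `sample_index_map` is not given.
#' @param i5,i7 Ordered index value pools. Defaults are derived from the map.
#' @param sample_index_map Tibble `sample`, `i5`, `i7`; pairs must be
#'   distinct, and in unique-dual mode no value may be reused.
#' @return A validated config (class `sim_config`).
#' @export
simulation_config <- function(seed, reads_per_library, locus_share,
                              switch_rate = 0,
                              indexing = c("unique_dual", "combinatorial"),
                              samples = NULL, i5 = NULL, i7 = NULL,
                              sample_index_map = NULL) {
  indexing <- match.arg(indexing)
  if (is.null(sample_index_map)) {
    if (is.null(samples)) stop("supply either `samples` or `sample_index_map`")
    sample_index_map <- make_index_map(samples, indexing)
  }
  i5 <- i5 %||% sort(unique(sample_index_map$i5))
  i7 <- i7 %||% sort(unique(sample_index_map$i7))
  if (abs(sum(locus_share) - 1) > 1e-9) stop("locus_share must sum to 1")
  if (is.null(names(locus_share))) stop("locus_share must be named by locus")
  if (switch_rate < 0 || switch_rate > 1) stop("switch_rate must lie in [0, 1]")
  if (anyDuplicated(paste(sample_index_map$i5, sample_index_map$i7))) {
    stop("sample index pairs must be distinct")
  }
  if (!all(sample_index_map$i5 %in% i5) || !all(sample_index_map$i7 %in% i7)) {
    stop("index map uses values outside the declared pools")
  }
  if (indexing == "unique_dual" &&
      (anyDuplicated(sample_index_map$i5) || anyDuplicated(sample_index_map$i7))) {
    stop("unique dual indexing must not reuse an i5 or i7 value across samples")
  }
  structure(
    list(seed = as.integer(seed), reads_per_library = reads_per_library,
         locus_share = locus_share, switch_rate = switch_rate,
         indexing = indexing, i5 = i5, i7 = i7,
         sample_index_map = sample_index_map),
    class = "sim_config"
  )
}

#' Build a sample-to-index-pair map
#'
#' Unique dual: sample k gets the k-th i5 and k-th i7, used by no other
#' sample. Combinatorial: values are reused on a near-square grid, so a
#' single-end switch can land on another sample's valid pair.
#'
#' @param samples Sample labels.
#' @param indexing `"unique_dual"` or `"combinatorial"`.
#' @return Tibble `sample`, `i5`, `i7`.
#' @export
make_index_map <- function(samples, indexing = c("unique_dual", "combinatorial")) {
  indexing <- match.arg(indexing)
  n <- length(samples)
  if (indexing == "unique_dual") {
    tibble(sample = samples,
           i5 = sprintf("i5_%02d", seq_len(n)),
           i7 = sprintf("i7_%02d", seq_len(n)))
  } else {
    k5 <- ceiling(sqrt(n))
    k7 <- ceiling(n / k5)
    idx <- seq_len(n) - 1
    tibble(sample = samples,
           i5 = sprintf("i5_%02d", idx %/% k7 + 1),
           i7 = sprintf("i7_%02d", idx %% k7 + 1))
  }
}

.sim_one_library <- function(design, profiles, config) {
  pool <- design$pool_id[1]
  missing <- setdiff(design$species, profiles$species)
  if (length(missing)) {
    stop("design species without a profile: ", paste(missing, collapse = ", "))
  }
  loci <- names(config$locus_share)
  n_locus <- as.vector(stats::rmultinom(1, config$reads_per_library,
                                        config$locus_share))
  out <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    lp <- profiles[profiles$locus == loci[i] & profiles$species %in% design$species, ]
    lp <- dplyr::left_join(lp, design[, c("species", "count")], by = "species")
    absent <- setdiff(design$species, lp$species)
    if (length(absent)) {
      warning("no ", loci[i], " template for ", paste(absent, collapse = ", "),
              " in pool ", pool, "; contributing zero reads at this locus")
    }
    w <- lp$count * lp$bias
    if (nrow(lp) == 0 || sum(w) == 0) next
    reads <- as.vector(stats::rmultinom(1, n_locus[i], w / sum(w)))
    tab <- tibble(sample = pool, locus = loci[i], sequence = lp$sequence,
                  species = lp$species, reads = reads)
    # one ASV per distinct denoised sequence: identical templates (e.g.
    # congeners at a conserved locus) collapse into one ASV
    out[[i]] <- tab |>
      dplyr::group_by(.data$sample, .data$locus, .data$sequence) |>
      dplyr::summarise(species = paste(sort(unique(.data$species)), collapse = "/"),
                       reads = sum(.data$reads), .groups = "drop")
  }
  dplyr::bind_rows(out)
}

.label_asvs <- function(tab) {
  key <- tab |>
    dplyr::distinct(.data$locus, .data$sequence) |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(asv_id = sprintf("%s_ASV%03d", .data$locus, dplyr::row_number())) |>
    dplyr::ungroup()
  dplyr::left_join(tab, key, by = c("locus", "sequence")) |>
    dplyr::select("sample", "asv_id", "locus", "sequence", "species", "reads")
}

#' Simulate one mock-community library
#'
#' For each locus, total reads follow the configured locus share and species
#' reads are drawn multinomially with probability proportional to
#' specimen count x per-locus bias. Deterministic for a fixed seed.
#'
#' @param design Tibble `pool_id`, `species`, `count` for a single pool.
#' @param profiles Species profile tibble.
#' @param config A [simulation_config()].
#' @param seed RNG seed (defaults to the config seed); `NULL` leaves the RNG
#'   state untouched.
#' @return Long ASV tibble: `sample`, `asv_id`, `locus`, `sequence`,
#'   `species`, `reads`.
#' @export
simulate_library <- function(design, profiles, config, seed = config$seed) {
  stopifnot(length(unique(design$pool_id)) == 1)
  if (!is.null(seed)) set.seed(seed)
  .label_asvs(.sim_one_library(design, profiles, config))
}

#' Simulate all libraries of a mock-community experiment
#'
#' @param designs Tibble `pool_id`, `species`, `count` over all pools.
#' @param profiles Species profile tibble.
#' @param config A [simulation_config()]; every pool must appear in its
#'   `sample_index_map`.
#' @param seed RNG seed (defaults to the config seed).
#' @return Long ASV tibble over all libraries.
#' @export
simulate_libraries <- function(designs, profiles, config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  pools <- unique(designs$pool_id)
  miss <- setdiff(pools, config$sample_index_map$sample)
  if (length(miss)) stop("pools missing from sample_index_map: ",
                         paste(miss, collapse = ", "))
  tab <- dplyr::bind_rows(lapply(pools, function(p) {
    .sim_one_library(designs[designs$pool_id == p, ], profiles, config)
  }))
  .label_asvs(tab)
}

#' Simulate index switching across libraries
#'
#' Each read's i5 is replaced with probability `switch_rate` by a uniform
#' draw from the i5 pool, and its i7 likewise (independent ends; a redraw of
#' the original value is a silent non-event). Reads landing on another
#' sample's valid pair are cross-assigned to that sample; reads landing on
#' invalid pairs become undetermined. Reads are conserved exactly:
#' assigned + undetermined = generated.
#'
#' @param libraries Long ASV tibble from [simulate_libraries()].
#' @param config A [simulation_config()].
#' @param seed RNG seed (defaults to config seed + 1 so that library
#'   generation and switching use distinct streams); `NULL` leaves the RNG
#'   state untouched.
#' @return List with `pairs` (tibble `i5`, `i7`, `reads`, `valid` over the
#'   full index grid), `table` (post-switching ASV tibble), `cross` (tibble
#'   of cross-assigned reads: `origin`, `sample`, `asv_id`, `locus`,
#'   `species`, `reads`), and `undetermined` (total invalid-pair reads).
#' @export
simulate_index_switching <- function(libraries, config,
                                     seed = config$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  map <- config$sample_index_map
  grid <- tidyr::expand_grid(i5 = config$i5, i7 = config$i7)
  grid_key <- paste(grid$i5, grid$i7)
  valid_key <- paste(map$i5, map$i7)
  dest_sample <- map$sample[match(grid_key, valid_key)]  # NA = invalid cell

  s <- config$switch_rate
  k5 <- length(config$i5)
  k7 <- length(config$i7)
  dest_rows <- vector("list", nrow(libraries))
  grid_reads <- stats::setNames(numeric(length(grid_key)), grid_key)
  # outer(p5, p7) flattens column-major, so cell (a, b) sits at
  # index (b - 1) * k5 + a; key_order matches that layout
  key_order <- paste(rep(config$i5, times = k7), rep(config$i7, each = k5))
  for (r in seq_len(nrow(libraries))) {
    orig <- map[map$sample == libraries$sample[r], ]
    p5 <- (1 - s) * (config$i5 == orig$i5) + s / k5
    p7 <- (1 - s) * (config$i7 == orig$i7) + s / k7
    p <- as.vector(outer(p5, p7))
    n <- stats::rmultinom(1, libraries$reads[r], p)[, 1]
    names(n) <- key_order
    grid_reads[names(n)] <- grid_reads[names(n)] + n
    hit <- n > 0
    if (any(hit)) {
      ds <- dest_sample[match(names(n)[hit], grid_key)]
      dest_rows[[r]] <- tibble(
        origin = libraries$sample[r], sample = ds,
        asv_id = libraries$asv_id[r], locus = libraries$locus[r],
        sequence = libraries$sequence[r], species = libraries$species[r],
        reads = as.numeric(n[hit])
      )
    }
  }
  flows <- dplyr::bind_rows(dest_rows)
  assigned <- flows |>
    dplyr::filter(!is.na(.data$sample)) |>
    dplyr::group_by(.data$sample, .data$asv_id, .data$locus, .data$sequence,
                    .data$species) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  cross <- flows |>
    dplyr::filter(!is.na(.data$sample), .data$sample != .data$origin) |>
    dplyr::select("origin", "sample", "asv_id", "locus", "species", "reads")
  pairs <- tibble(i5 = grid$i5, i7 = grid$i7,
                  reads = as.numeric(grid_reads[grid_key]),
                  valid = grid_key %in% valid_key)
  list(pairs = pairs, table = assigned, cross = cross,
       undetermined = sum(pairs$reads[!pairs$valid]))
}

#' Model-expected invalid-pair fraction and contamination rate
#'
#' Closed-form expectation under the switching model, obtained by
#' enumerating the (switch i5?, switch i7?, destination) outcome space for
#' every library: the probability that a read lands on a pair outside the
#' valid set, averaged over libraries (equal depths). `expected_contamination()`
#' multiplies by the estimator's cell-count correction so it is directly
#' comparable with [estimate_contamination()].
#'
#' @param config A [simulation_config()].
#' @param switch_rate Switching rate to evaluate (defaults to the config's).
#' @return A single fraction.
#' @export
expected_invalid_fraction <- function(config, switch_rate = config$switch_rate) {
  map <- config$sample_index_map
  s <- switch_rate
  k5 <- length(config$i5)
  k7 <- length(config$i7)
  valid_key <- paste(map$i5, map$i7)
  frac <- vapply(seq_len(nrow(map)), function(r) {
    p5 <- (1 - s) * (config$i5 == map$i5[r]) + s / k5
    p7 <- (1 - s) * (config$i7 == map$i7[r]) + s / k7
    key <- paste(rep(config$i5, times = k7), rep(config$i7, each = k5))
    p <- as.vector(outer(p5, p7))
    sum(p[!(key %in% valid_key)])
  }, numeric(1))
  mean(frac)
}

#' @rdname expected_invalid_fraction
#' @export
expected_contamination <- function(config, switch_rate = config$switch_rate) {
  cc <- .switch_cells(config$i5, config$i7, config$sample_index_map)
  expected_invalid_fraction(config, switch_rate) * cc$offdiag / cc$invalid
}

#' Switching rate that yields a target contamination estimate
#'
#' Inverts [expected_contamination()] numerically, giving the per-end
#' switching rate `s` at which the contamination estimator's expectation
#' equals `target_c`.
#'
#' @param target_c Target contamination rate (fraction, e.g. 0.01).
#' @param config A [simulation_config()].
#' @return The switching rate `s`.
#' @export
switch_rate_for_contamination <- function(target_c, config) {
  f <- function(s) expected_contamination(config, s) - target_c
  stats::uniroot(f, c(0, 0.999), tol = 1e-12)$root
}

#' Emit simulated reads as FASTQ
#'
#' Expands an ASV count table into individual reads with a constant quality
#' (default Q35), optionally flanked by locus primers so the quality-control
#' module can be exercised on primer trimming.
#'
#' @param asv_table Long ASV tibble.
#' @param path Output FASTQ path.
#' @param primers Optional primer-set tibble; when given, each read is
#'   `forward + template + reverse-complemented reverse primer`.
#' @param quality Phred quality applied to every base.
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(asv_table, path, primers = NULL, quality = 35L) {
  qc <- rawToChar(as.raw(quality + 33L))
  rows <- asv_table[rep(seq_len(nrow(asv_table)), asv_table$reads), ]
  seqs <- rows$sequence
  if (!is.null(primers)) {
    pr <- primers[match(rows$locus, primers$locus), ]
    # reads carry concrete bases: degenerate primer positions are fixed to
    # one base of the code's set (still matched by the IUPAC-aware trimmer)
    fix <- function(x) chartr("RYSWKMBDHVN", "ACCAGACAAAA", x)
    seqs <- paste0(fix(pr$forward), seqs, fix(revcomp(pr$reverse)))
  }
  reads <- tibble(
    read_id = sprintf("%s:%s:%06d", rows$sample, rows$asv_id,
                      seq_len(nrow(rows))),
    sequence = seqs,
    quality = strrep(qc, nchar(seqs))
  )
  write_fastq(reads, path)
}
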