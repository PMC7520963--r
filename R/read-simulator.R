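# Perfect paired-end read simulation: evenly spaced sliding windows over
# each component, mixed at a genome:chloroplast coverage ratio, with
# optional fixed-size subsampling. Reads are error-free; read names carry
# the true origin so downstream evaluation needs no alignment.

#' Specification of a read simulation
#'
#' @param read_len Read length in bp (the study design uses 150 and 250).
#' @param fragment_len Fragment (insert) length in bp; defaults to
#'   `2 * read_len` so the two mates tile the fragment without overlap.
#' @param nuclear_cov Nuclear fold coverage at ratio weight 1 (default 30).
#' @param mito_cov Mitochondrial fold coverage at ratio weight 1
#'   (default 300).
#' @param ratio Genome:chloroplast coverage ratio as a numeric pair
#'   `c(g, c)` or a string `"g:c"`; the standard series is `0:1`, `1:10`,
#'   `1:100`, `1:1000`. The nuclear component is simulated at
#'   `nuclear_cov * g`, the mitochondrial one at `mito_cov * g`, and the
#'   plastid one at `nuclear_cov * c` (so `1:100` means 3000x plastid).
#' @param subsample_pairs Optional exact number of pairs to keep after
#'   mixing (the study design uses 2,000,000).
#' @param seed Integer seed for shuffling and subsampling.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(read_len = 150, fragment_len = 2 * read_len,
                            nuclear_cov = 30, mito_cov = 300,
                            ratio = c(1, 10), subsample_pairs = NULL,
                            seed = 1) {
  if (is.character(ratio)) {
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  }
  stopifnot(
    read_len >= 1, fragment_len >= read_len,
    nuclear_cov >= 0, mito_cov >= 0,
    length(ratio) == 2, ratio[1] >= 0, ratio[2] >= 1
  )
  structure(
    list(
      read_len = read_len, fragment_len = fragment_len,
      nuclear_cov = nuclear_cov, mito_cov = mito_cov, ratio = ratio,
      subsample_pairs = subsample_pairs, seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' Simulate perfect read pairs from one sequence component
#'
#' Fragments of `fragment_len` bp are placed at evenly spaced start
#' positions; the forward read is the first `read_len` bases of the
#' fragment and the reverse read is the reverse complement of its last
#' `read_len` bases. The number of fragments is `round(coverage * n /
#' (2 * read_len))`, so the realized coverage (emitted read bases divided
#' by component length) is always within one fragment's worth of the
#' target; when more fragments than distinct start positions are needed,
#' full passes over every position are made and the remainder is spread
#' evenly. Circular sequences wrap across the origin; linear sequences do
#' not. No randomness is involved.
#'
#' @param record One-row sequence table.
#' @param coverage Target fold coverage (> 0).
#' @param spec A [simulation_spec()].
#' @return A read-pair tibble with columns `pair_id`, `component`,
#'   `frag_start`, `pass`, `fwd_seq`, `rev_seq`, `fwd_qual`, `rev_qual`.
#'   `pair_id` encodes `component:frag_start:pass`. Qualities are constant
#'   Phred 40 (`I`): the reads are perfect.
#' @export
simulate_component <- function(record, coverage, spec = simulation_spec()) {
  record <- validate_seq_tbl(record)
  stopifnot(nrow(record) == 1, coverage > 0)
  n <- nchar(record$seq)
  fl <- spec$fragment_len
  rl <- spec$read_len
  if (n < fl) {
    abort(paste0(
      "Sequence '", record$id, "' (", n, " bp) is shorter than the ",
      fl, " bp fragment length."
    ))
  }
  circular <- record$topology == "circular"
  n_frag <- max(1, round(coverage * n / (2 * rl)))
  max_starts <- if (circular) n else n - fl + 1
  full <- n_frag %/% max_starts
  rem <- n_frag %% max_starts
  spread <- function(m) {
    if (m == 0) {
      return(integer(0))
    }
    if (circular) {
      as.integer(floor((0:(m - 1)) * n / m))
    } else {
      as.integer(round(seq(0, n - fl, length.out = m)))
    }
  }
  starts <- c(rep(0:(max_starts - 1), times = full), spread(rem))
  pass <- c(rep(seq_len(full), each = max_starts), rep(full + 1L, rem))
  frag <- if (circular) {
    substring(paste0(record$seq, record$seq), starts + 1, starts + fl)
  } else {
    substring(record$seq, starts + 1, starts + fl)
  }
  qual <- strrep("I", rl)
  tibble(
    pair_id = sprintf("%s:%d:%d", record$id, starts, pass),
    component = record$id,
    frag_start = starts,
    pass = pass,
    fwd_seq = substring(frag, 1, rl),
    rev_seq = revcomp(substring(frag, fl - rl + 1, fl)),
    fwd_qual = qual,
    rev_qual = qual
  )
}

#' Simulate an organelle-enriched read mixture
#'
#' Combines nuclear, mitochondrial and plastid components at the coverage
#' implied by the spec's genome:chloroplast ratio `(g, c)`: nuclear at
#' `nuclear_cov * g`, mitochondrial at `mito_cov * g` (both omitted when
#' `g = 0`), plastid at `nuclear_cov * c`. Pairs are shuffled
#' deterministically by the spec seed; `pair_id` retains the true origin.
#'
#' @param plastid One-row circular sequence table (the chloroplast).
#' @param nuclear,mito Optional one-row sequence tables; required when the
#'   ratio's genome weight is positive.
#' @param spec A [simulation_spec()].
#' @return A read-pair tibble (see [simulate_component()]).
#' @export
simulate_mixture <- function(plastid, nuclear = NULL, mito = NULL,
                             spec = simulation_spec()) {
  g <- spec$ratio[1]
  cc <- spec$ratio[2]
  covs <- list()
  if (g > 0) {
    if (spec$nuclear_cov * g > 0) {
      if (is.null(nuclear)) abort("ratio has genome weight but no nuclear component given.")
      covs <- c(covs, list(list(rec = nuclear, cov = spec$nuclear_cov * g)))
    }
    if (spec$mito_cov * g > 0) {
      if (is.null(mito)) abort("ratio has genome weight but no mitochondrial component given.")
      covs <- c(covs, list(list(rec = mito, cov = spec$mito_cov * g)))
    }
  }
  plast_cov <- spec$nuclear_cov * cc
  if (plast_cov <= 0 && length(covs) == 0) abort("all component coverages are zero.")
  if (plast_cov > 0) {
    covs <- c(covs, list(list(rec = plastid, cov = plast_cov)))
  }
  pairs <- purrr::map(covs, function(x) {
    simulate_component(x$rec, x$cov, spec)
  }) |> bind_rows()
  set.seed(spec$seed)
  pairs <- pairs[sample.int(nrow(pairs)), ]
  if (!is.null(spec$subsample_pairs)) {
    pairs <- subsample_pairs(pairs, spec$subsample_pairs, seed = spec$seed + 1L)
  }
  pairs
}

#' Subsample read pairs to an exact count
#'
#' Draws exactly `n` pairs uniformly without replacement and shuffles the
#' order, deterministically per seed.
#'
#' @param pairs Read-pair tibble.
#' @param n Number of pairs to keep (`n <= nrow(pairs)`).
#' @param seed Integer seed.
#' @return A read-pair tibble with `n` rows.
#' @export
subsample_pairs <- function(pairs, n, seed = 1) {
  stopifnot(is.data.frame(pairs))
  if (n > nrow(pairs)) {
    abort(paste0(
      "Requested ", n, " pairs but only ", nrow(pairs), " are available."
    ))
  }
  set.seed(seed)
  pairs[sample.int(nrow(pairs), n), ]
}

#' Realized fold coverage per origin component
#'
#' Uses the truth tags in `pair_id`/`component` to compute emitted read
#' bases per component divided by component length.
#'
#' @param pairs Read-pair tibble from [simulate_component()] or
#'   [simulate_mixture()].
#' @param lengths_by_id Named numeric vector of component lengths in bp.
#' @return A tibble with columns `component`, `n_pairs`, `read_bases`,
#'   `coverage`.
#' @export
realized_coverage <- function(pairs, lengths_by_id) {
  stopifnot(all(pairs$component %in% names(lengths_by_id)))
  pairs |>
    group_by(.data$component) |>
    summarise(
      n_pairs = dplyr::n(),
      read_bases = sum(nchar(.data$fwd_seq) + nchar(.data$rev_seq)),
      .groups = "drop"
    ) |>
    mutate(
      coverage = unname(.data$read_bases / lengths_by_id[.data$component])
    )
}
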