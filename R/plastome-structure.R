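# Inverted-repeat detection, quadripartite partitioning and canonical
# rotation of circular plastome sequences.

#' Quadripartite region map of a plastome
#'
#' Chloroplast genomes carry two identical, oppositely oriented repeat
#' copies (IRa, IRb) that divide the circle into a large (LSC) and a small
#' (SSC) single-copy region. A `quadripartite` object records the four
#' intervals as 0-based half-open coordinates on the circle; an interval
#' whose `end` exceeds `total_len` wraps across the origin.
#'
#' @param regions Tibble with columns `region` (`lsc`, `ira`, `ssc`,
#'   `irb`), `start`, `end`, `length`. May be omitted when the three
#'   lengths are given, in which case the canonical LSC-first layout is
#'   assumed.
#' @param lsc_len,ssc_len,ir_len Region lengths for the canonical layout.
#' @return An object of class `quadripartite` with elements `regions`,
#'   `ir_len` and `total_len`.
#' @export
new_quadripartite <- function(regions = NULL, lsc_len = NULL, ssc_len = NULL,
                              ir_len = NULL) {
  if (is.null(regions)) {
    stopifnot(!is.null(lsc_len), !is.null(ssc_len), !is.null(ir_len))
    bounds <- cumsum(unname(c(0, lsc_len, ir_len, ssc_len, ir_len)))
    regions <- tibble(
      region = c("lsc", "ira", "ssc", "irb"),
      start = bounds[1:4], end = bounds[2:5],
      length = diff(bounds)
    )
  }
  regions <- as_tibble(regions)
  stopifnot(
    setequal(regions$region, c("lsc", "ira", "ssc", "irb")),
    nrow(regions) == 4, all(regions$length == regions$end - regions$start)
  )
  total_len <- sum(regions$length)
  ir_len <- regions$length[regions$region == "ira"]
  stopifnot(ir_len == regions$length[regions$region == "irb"])
  structure(
    list(regions = regions, ir_len = ir_len, total_len = total_len),
    class = "quadripartite"
  )
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(
    "Quadripartite structure:", x$total_len, "bp circle, IR", x$ir_len,
    "bp\n"
  )
  print(x$regions)
  invisible(x)
}

#' @rdname new_quadripartite
#' @param x A `quadripartite` object.
#' @param ... Unused.
#' @method tidy quadripartite
#' @export
tidy.quadripartite <- function(x, ...) {
  x$regions
}

#' Detect the inverted-repeat pair and quadripartite structure
#'
#' Searches a circular sequence for the maximal pair of disjoint blocks
#' where one block equals the reverse complement of the other. Candidate
#' blocks are seeded by k-mers shared between the doubled sequence and its
#' doubled reverse complement, collapsed per diagonal into maximal exact
#' runs, so detection is independent of where the circle was opened. The
#' single-copy gaps between the two repeat copies are labelled LSC
#' (longer) and SSC (shorter); IRa is the copy that follows the LSC.
#'
#' @param record One-row sequence table with `topology == "circular"`.
#' @param min_ir_len Minimum repeat length in bp to report; the default is
#'   the 17 kbp cutoff used for reference-free success classification.
#' @param k Anchor k-mer size (>= 11, <= `min_ir_len`).
#' @return A [quadripartite][new_quadripartite] object, or `NULL` when no
#'   inverted repeat of at least `min_ir_len` exists.
#' @examples
#' p <- make_plastome(lsc_len = 3000, ssc_len = 800, ir_len = 600, seed = 2)
#' find_ir(p$genome, min_ir_len = 500, k = 11)$ir_len
#' @export
find_ir <- function(record, min_ir_len = 17000, k = 31) {
  record <- validate_seq_tbl(record)
  stopifnot(nrow(record) == 1)
  if (record$topology != "circular") {
    abort("find_ir needs a circular sequence; declare the topology.")
  }
  if (k < 11) abort("k must be >= 11.")
  if (k > min_ir_len) abort("k must not exceed min_ir_len.")
  cand <- ir_candidates(record$seq, k)
  cand <- cand[cand$len >= min_ir_len, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  best <- cand[order(-cand$len, pmin(cand$i, cand$j), pmax(cand$i, cand$j)), ][1, ]
  partition_circle(nchar(record$seq), best$i, best$j, best$len)
}

# All maximal disjoint inverted-repeat block pairs (i, j, len) on the
# circle, 0-based starts, deduplicated across the doubling and the (i,j)
# symmetry.
#' @keywords internal
ir_candidates <- function(s, k) {
  n <- nchar(s)
  if (2 * n < k) {
    return(tibble(i = integer(), j = integer(), len = integer()))
  }
  rc <- revcomp(s)
  m <- max_exact_matches(paste0(s, s), paste0(rc, rc), k)
  if (nrow(m) == 0) {
    return(tibble(i = integer(), j = integer(), len = integer()))
  }
  len <- pmin(m$len, n)
  i <- m$a_start %% n
  j <- (((n - m$b_start - len) %% n) + n) %% n
  keep <- !duplicated(paste(pmin(i, j), pmax(i, j), len))
  i <- i[keep]; j <- j[keep]; len <- len[keep]
  # disjoint on the circle: each block must start at least `len` after the
  # other, going forward
  disjoint <- i != j & ((j - i) %% n) >= len & ((i - j) %% n) >= len &
    2 * len <= n
  tibble(i = i[disjoint], j = j[disjoint], len = len[disjoint])
}

# Partition the circle given the two IR block starts and their length.
#' @keywords internal
partition_circle <- function(n, i1, i2, len) {
  gap_after_1 <- (i2 - (i1 + len)) %% n
  gap_after_2 <- (i1 - (i2 + len)) %% n
  if (gap_after_1 >= gap_after_2) {
    lsc_start <- (i1 + len) %% n
    ira_start <- i2
    ssc_start <- (i2 + len) %% n
    irb_start <- i1
    lsc_len <- gap_after_1
    ssc_len <- gap_after_2
  } else {
    lsc_start <- (i2 + len) %% n
    ira_start <- i1
    ssc_start <- (i1 + len) %% n
    irb_start <- i2
    lsc_len <- gap_after_2
    ssc_len <- gap_after_1
  }
  starts <- c(lsc_start, ira_start, ssc_start, irb_start)
  lens <- c(lsc_len, len, ssc_len, len)
  new_quadripartite(tibble(
    region = c("lsc", "ira", "ssc", "irb"),
    start = starts, end = starts + lens, length = lens
  ))
}

#' Rotate and orient a circular plastome into canonical layout
#'
#' A circular molecule has no intrinsic start point or strand, and the SSC
#' orientation is a biologically valid degree of freedom, so the same
#' plastome can be presented in many equivalent ways. `canonicalize`
#' rewrites the sequence as `LSC + IRa + SSC + IRb` starting at the first
#' LSC base and resolves the residual symmetries (global reverse
#' complement; SSC orientation) by picking the lexicographically smallest
#' of the four equivalent layouts. The result is a fixed point:
#' canonicalizing twice changes nothing.
#'
#' @param record One-row circular sequence table.
#' @param structure Optional precomputed [quadripartite][new_quadripartite]
#'   map; detected with [find_ir()] when omitted.
#' @param min_ir_len,k Passed to [find_ir()] when `structure` is missing.
#' @return A one-row circular sequence table in canonical layout.
#' @export
canonicalize <- function(record, structure = NULL, min_ir_len = 17000,
                         k = 31) {
  record <- validate_seq_tbl(record)
  stopifnot(nrow(record) == 1)
  if (is.null(structure)) {
    structure <- find_ir(record, min_ir_len = min_ir_len, k = k)
    if (is.null(structure)) {
      abort("No inverted repeat found; cannot canonicalize.")
    }
  }
  if (structure$total_len != nchar(record$seq)) {
    abort("structure/sequence length mismatch.")
  }
  reg <- structure$regions
  part <- function(name) {
    r <- reg[reg$region == name, ]
    circ_substr(record$seq, r$start, r$length)
  }
  lsc <- part("lsc")
  ira <- part("ira")
  ssc <- part("ssc")
  candidates <- c(
    paste0(lsc, ira, ssc, revcomp(ira)),
    paste0(lsc, ira, revcomp(ssc), revcomp(ira)),
    paste0(revcomp(lsc), ira, ssc, revcomp(ira)),
    paste0(revcomp(lsc), ira, revcomp(ssc), revcomp(ira))
  )
  seq_record(record$id, sort(candidates)[1], topology = "circular")
}
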