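# From pairwise alignments to the two coverage fractions the composite
# score consumes. Alignments either come from an external aligner as PAF
# (minimap2 in practice) or from the internal exact k-mer anchor aligner,
# which is complete for sequences that are exact substrings,
# rearrangements or reverse complements of each other.

#' Align two sequences by maximal exact matches
#'
#' An intentionally simple aligner: maximal exact match blocks between
#' query and target are found on both strands via shared k-mer anchors
#' collapsed per diagonal, and each query base is then assigned to at most
#' one block (primary-only semantics, longest block first). There is no
#' gapped extension: the aligner is exact-match only, which is complete
#' for assemblies that are rotations, rearrangements, fragments,
#' duplications or reverse complements of the reference.
#'
#' @param query,target One-row sequence tables.
#' @param k Anchor k-mer size (>= 11).
#' @return An alignment tibble in PAF column layout (see [parse_paf()]);
#'   blocks not selected as primary are kept with `is_primary = FALSE`.
#' @export
exact_anchor_align <- function(query, target, k = 31) {
  query <- validate_seq_tbl(query)
  target <- validate_seq_tbl(target)
  stopifnot(nrow(query) == 1, nrow(target) == 1)
  if (k < 11) abort("k must be >= 11.")
  if (k > nchar(query$seq) || k > nchar(target$seq)) {
    abort("k exceeds a sequence length.")
  }
  select_primary(anchor_blocks(query, target, k))
}

# Raw maximal exact match blocks (both strands) between one query and one
# target, as an alignment tibble without primary selection.
#' @keywords internal
anchor_blocks <- function(query, target, k) {
  nq <- nchar(query$seq)
  nt <- nchar(target$seq)
  if (k > nq || k > nt) {
    return(empty_alignment_tbl())
  }
  fwd <- max_exact_matches(query$seq, target$seq, k)
  rev <- max_exact_matches(query$seq, revcomp(target$seq), k)
  as_rec <- function(m, strand) {
    if (nrow(m) == 0) {
      return(empty_alignment_tbl())
    }
    t_start <- if (strand == "+") m$b_start else nt - m$b_start - m$len
    tibble(
      query_id = query$id, query_len = nq,
      query_start = m$a_start, query_end = m$a_start + m$len,
      strand = strand,
      target_id = target$id, target_len = nt,
      target_start = t_start, target_end = t_start + m$len,
      n_matches = m$len, block_len = m$len, is_primary = NA
    )
  }
  bind_rows(as_rec(fwd, "+"), as_rec(rev, "-"))
}

# Primary selection with chaining: blocks sharing (query, target, strand,
# diagonal) are colinear and form one chain; chains are taken greedily by
# total matched length, and each block is trimmed to the query intervals
# not yet assigned to an earlier chain. Trimming an exact-match block
# keeps query and target coordinates consistent (strand-aware), so every
# query base ends up in at most one primary record. Blocks contributing
# nothing are kept as secondary records.
#' @keywords internal
select_primary <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(blocks)
  }
  # diagonal in the coordinate space the exact match lives in: for minus
  # blocks that is the reverse-complemented target
  diag <- ifelse(
    blocks$strand == "+",
    blocks$query_start - blocks$target_start,
    blocks$query_start - (blocks$target_len - blocks$target_end)
  )
  blocks$chain <- paste(
    blocks$query_id, blocks$target_id, blocks$strand, diag
  )
  chains <- blocks |>
    group_by(.data$query_id, .data$chain) |>
    summarise(
      chain_len = sum(.data$block_len), q0 = min(.data$query_start),
      .groups = "drop"
    ) |>
    arrange(.data$query_id, desc(.data$chain_len), .data$q0, .data$chain)
  out <- vector("list", nrow(blocks))
  secondary <- rep(FALSE, nrow(blocks))
  for (qid in unique(chains$query_id)) {
    kept <- IRanges::IRanges()
    for (ch in chains$chain[chains$query_id == qid]) {
      idx <- which(blocks$chain == ch)
      for (i in idx[order(blocks$query_start[idx])]) {
        b <- blocks[i, ]
        novel <- IRanges::setdiff(
          IRanges::IRanges(b$query_start + 1, b$query_end), kept
        )
        if (length(novel) == 0) {
          secondary[i] <- TRUE
          next
        }
        kept <- IRanges::reduce(c(kept, novel))
        qs <- IRanges::start(novel) - 1
        qe <- IRanges::end(novel)
        trimmed <- b[rep(1, length(novel)), ]
        trimmed$query_start <- qs
        trimmed$query_end <- qe
        if (b$strand == "+") {
          trimmed$target_start <- b$target_start + (qs - b$query_start)
          trimmed$target_end <- b$target_start + (qe - b$query_start)
        } else {
          trimmed$target_start <- b$target_start + (b$query_end - qe)
          trimmed$target_end <- b$target_start + (b$query_end - qs)
        }
        trimmed$n_matches <- trimmed$block_len <- qe - qs
        trimmed$is_primary <- TRUE
        out[[i]] <- trimmed
      }
    }
  }
  sec <- blocks[secondary, ]
  if (nrow(sec) > 0) sec$is_primary <- FALSE
  res <- bind_rows(c(out, list(sec)))
  res$chain <- NULL
  arrange(res, .data$query_id, .data$query_start, desc(.data$is_primary))
}

#' Fraction of sequence bases covered by alignments
#'
#' Forms the union of the chosen side's intervals per sequence (merging
#' overlaps) and divides the summed union length by the summed sequence
#' lengths. Only primary alignments count.
#'
#' @param alignments Alignment tibble ([parse_paf()] or
#'   [exact_anchor_align()]).
#' @param side `"query"` or `"target"`: which side's intervals to union.
#' @param total_len_by_id Named numeric vector of sequence lengths; every
#'   id on the chosen side must be present, and ids with no alignments
#'   still contribute length to the denominator.
#' @return A fraction in `[0, 1]`.
#' @examples
#' aln <- tibble::tibble(
#'   query_id = "q", query_len = 100, query_start = c(0, 25),
#'   query_end = c(50, 75), strand = "+", target_id = "t",
#'   target_len = 100, target_start = c(0, 25), target_end = c(50, 75),
#'   n_matches = 50, block_len = 50, is_primary = TRUE
#' )
#' covered_fraction(aln, "target", c(t = 100)) # 0.75
#' @export
covered_fraction <- function(alignments, side = c("query", "target"),
                             total_len_by_id) {
  side <- match.arg(side)
  al <- dplyr::filter(alignments, .data$is_primary)
  id_col <- paste0(side, "_id")
  s_col <- paste0(side, "_start")
  e_col <- paste0(side, "_end")
  if (nrow(al) > 0) {
    if (!all(al[[id_col]] %in% names(total_len_by_id))) {
      abort("alignment ids missing from total_len_by_id.")
    }
    if (any(al[[s_col]] < 0) ||
        any(al[[e_col]] > total_len_by_id[al[[id_col]]])) {
      abort("alignment interval out of sequence bounds.")
    }
  }
  covered <- 0
  for (id in unique(al[[id_col]])) {
    rows <- al[[id_col]] == id
    ir <- IRanges::reduce(IRanges::IRanges(
      al[[s_col]][rows] + 1, al[[e_col]][rows]
    ))
    covered <- covered + sum(IRanges::width(ir))
  }
  covered / sum(total_len_by_id)
}

#' Bidirectional coverage of an assembly against a reference
#'
#' Maps the assembly onto the reference to obtain `cov_ref` (the fraction
#' of reference bases covered: completeness) and the reference onto the
#' assembly to obtain `cov_qry` (the fraction of assembly bases covered,
#' summed over contigs: correctness). Primary-only counting makes
#' `cov_qry` fall below 1 when the assembly carries surplus copies of the
#' genome, which is what lets the score's repeat-resolution term see size
#' mismatches. Either direction can be supplied as parsed PAF from an
#' external aligner; otherwise the internal exact anchor aligner is used.
#'
#' @param assembly Sequence table, one row per contig.
#' @param reference One-row sequence table.
#' @param k Anchor k-mer size for the internal aligner.
#' @param aln_ref Optional alignment tibble for the assembly-to-reference
#'   direction (assembly contigs as query).
#' @param aln_qry Optional alignment tibble for the reference-to-assembly
#'   direction (reference as query).
#' @return A `coverage_result` list with `cov_ref`, `cov_qry` and the two
#'   alignment tibbles.
#' @export
bidirectional_coverage <- function(assembly, reference, k = 31,
                                   aln_ref = NULL, aln_qry = NULL) {
  assembly <- validate_seq_tbl(assembly, "assembly")
  reference <- validate_seq_tbl(reference, "reference")
  stopifnot(nrow(reference) == 1)
  contigs <- split(assembly, seq_len(nrow(assembly)))
  if (is.null(aln_ref)) {
    aln_ref <- purrr::map(contigs, anchor_blocks, target = reference, k = k) |>
      bind_rows() |>
      select_primary()
  }
  if (is.null(aln_qry)) {
    aln_qry <- purrr::map(contigs, function(ct) {
      anchor_blocks(reference, ct, k)
    }) |>
      bind_rows() |>
      select_primary()
  }
  ref_len <- stats::setNames(nchar(reference$seq), reference$id)
  asm_len <- stats::setNames(nchar(assembly$seq), assembly$id)
  structure(
    list(
      cov_ref = covered_fraction(aln_ref, "target", ref_len),
      cov_qry = covered_fraction(aln_qry, "target", asm_len),
      aln_ref = aln_ref, aln_qry = aln_qry
    ),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "Coverage: cov_ref = %.4f, cov_qry = %.4f\n", x$cov_ref, x$cov_qry
  ))
  invisible(x)
}
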