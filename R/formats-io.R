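#' Read a FASTA file into a sequence table
#'
#' Wrapped sequence lines are concatenated, lowercase and `U` are
#' normalised, and IUPAC ambiguity codes are mapped to `N` with a warning.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology recorded for every sequence (`"linear"` or
#'   `"circular"`); FASTA itself carries no topology.
#' @return A tibble with columns `id`, `seq`, `topology` (see
#'   [seq_record()]).
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  check_fasta_characters(path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) abort(paste0("Empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seq_record(ids, as.character(set), topology = topology)
}

# Locate illegal sequence characters so errors can name the line.
#' @keywords internal
check_fasta_characters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("Empty FASTA file: ", path))
  is_seq <- !startsWith(lines, ">") & nzchar(lines)
  bad <- regexpr("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", lines)
  hit <- which(is_seq & bad > 0)
  if (length(hit) > 0) {
    ch <- substr(lines[hit[1]], bad[hit[1]], bad[hit[1]])
    abort(paste0(
      "Illegal character '", ch, "' in ", path, " at line ", hit[1], "."
    ))
  }
  invisible(TRUE)
}

#' Write a sequence table to FASTA
#'
#' @param records Sequence table (see [seq_record()]).
#' @param path Output path.
#' @param line_width Maximum sequence characters per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  records <- validate_seq_tbl(records)
  stopifnot(line_width >= 1)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = line_width)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' Mates are paired positionally: record *i* of the forward file pairs with
#' record *i* of the reverse file; `/1` and `/2` id suffixes are ignored.
#'
#' @param fwd_path,rev_path Paths to the forward and reverse FASTQ files.
#' @return A tibble of read pairs with columns `pair_id`, `fwd_seq`,
#'   `rev_seq`, `fwd_qual`, `rev_qual`.
#' @export
read_paired_fastq <- function(fwd_path, rev_path) {
  fwd <- read_fastq_one(fwd_path)
  rev <- read_fastq_one(rev_path)
  if (nrow(fwd) != nrow(rev)) {
    abort(paste0(
      "Mate-count mismatch: ", nrow(fwd), " forward vs ",
      nrow(rev), " reverse records."
    ))
  }
  tibble(
    pair_id = sub("/[12]$", "", fwd$id),
    fwd_seq = fwd$seq, rev_seq = rev$seq,
    fwd_qual = fwd$qual, rev_qual = rev$qual
  )
}

#' @keywords internal
read_fastq_one <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(paste0(path, ": truncated FASTQ (", length(lines), " lines)."))
  }
  n <- length(lines) / 4
  if (n == 0) abort(paste0("Empty FASTQ file: ", path))
  heads <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  if (!all(startsWith(heads, "@")) || !all(startsWith(plus, "+"))) {
    bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))[1]
    abort(paste0(path, ": malformed FASTQ record ", bad, "."))
  }
  if (any(nchar(quals) != nchar(seqs))) {
    bad <- which(nchar(quals) != nchar(seqs))[1]
    abort(paste0(
      path, ": quality/sequence length mismatch in record ", bad, "."
    ))
  }
  tibble(
    id = sub("\\s.*$", "", substring(heads, 2)),
    seq = normalize_seq(seqs),
    qual = quals
  )
}

#' Write read pairs as paired FASTQ files
#'
#' @param pairs Read-pair tibble (`pair_id`, `fwd_seq`, `rev_seq`,
#'   `fwd_qual`, `rev_qual`), as produced by [simulate_mixture()] or
#'   [read_paired_fastq()].
#' @param fwd_path,rev_path Output paths for the forward and reverse files.
#' @return `c(fwd_path, rev_path)`, invisibly.
#' @export
write_paired_fastq <- function(pairs, fwd_path, rev_path) {
  need <- c("pair_id", "fwd_seq", "rev_seq", "fwd_qual", "rev_qual")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  if (nrow(pairs) == 0) abort("No read pairs to write.")
  if (any(nchar(pairs$fwd_qual) != nchar(pairs$fwd_seq)) ||
      any(nchar(pairs$rev_qual) != nchar(pairs$rev_seq))) {
    abort("Quality/sequence length mismatch.")
  }
  write_fastq_one <- function(id, s, q, suffix, path) {
    out <- character(4 * length(id))
    out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", id, suffix)
    out[c(FALSE, TRUE, FALSE, FALSE)] <- s
    out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    out[c(FALSE, FALSE, FALSE, TRUE)] <- q
    writeLines(out, path)
  }
  write_fastq_one(pairs$pair_id, pairs$fwd_seq, pairs$fwd_qual, "/1", fwd_path)
  write_fastq_one(pairs$pair_id, pairs$rev_seq, pairs$rev_qual, "/2", rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Parse a PAF pairwise-alignment file
#'
#' Reads the 12 mandatory tab-separated PAF columns plus optional SAM-style
#' tags. Coordinates are kept 0-based half-open as in PAF itself. The
#' `tp:A:` tag sets `is_primary` (`P` and `I` are primary, `S` secondary;
#' records without the tag count as primary).
#'
#' @param path Path to a PAF file (e.g. minimap2 output).
#' @return A tibble of alignment records with columns `query_id`,
#'   `query_len`, `query_start`, `query_end`, `strand`, `target_id`,
#'   `target_len`, `target_start`, `target_end`, `n_matches`, `block_len`,
#'   `is_primary`.
#' @export
parse_paf <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_alignment_tbl())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    bad <- which(nf < 12)[1]
    abort(paste0(
      path, " line ", bad, ": expected >= 12 PAF columns, found ", nf[bad], "."
    ))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what, ln = seq_along(fields)) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(paste0(path, " line ", bad, ": non-numeric ", what, "."))
    }
    v
  }
  rec <- tibble(
    query_id = col(1), query_len = num(2, "query length"),
    query_start = num(3, "query start"), query_end = num(4, "query end"),
    strand = col(5),
    target_id = col(6), target_len = num(7, "target length"),
    target_start = num(8, "target start"), target_end = num(9, "target end"),
    n_matches = num(10, "match count"), block_len = num(11, "block length"),
    is_primary = vapply(fields, function(f) {
      tp <- grep("^tp:A:", f[-(1:12)], value = TRUE)
      if (length(tp) == 0) TRUE else substring(tp[1], 6, 6) %in% c("P", "I")
    }, logical(1))
  )
  bad <- which(
    !(rec$strand %in% c("+", "-")) |
      rec$query_start < 0 | rec$query_start >= rec$query_end |
      rec$query_end > rec$query_len |
      rec$target_start < 0 | rec$target_start >= rec$target_end |
      rec$target_end > rec$target_len |
      rec$n_matches > rec$block_len
  )
  if (length(bad) > 0) {
    abort(paste0(path, " line ", bad[1], ": invalid PAF record."))
  }
  rec
}

#' @keywords internal
empty_alignment_tbl <- function() {
  tibble(
    query_id = character(), query_len = numeric(),
    query_start = numeric(), query_end = numeric(), strand = character(),
    target_id = character(), target_len = numeric(),
    target_start = numeric(), target_end = numeric(),
    n_matches = numeric(), block_len = numeric(), is_primary = logical()
  )
}
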