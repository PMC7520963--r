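#' Construct a sequence table
#'
#' Sequences are carried through the package as tibbles with one row per
#' sequence and columns `id`, `seq` and `topology`. A plastome is a single
#' circular row; a fragmented assembly is several linear rows.
#'
#' @param id Character vector of sequence identifiers (no whitespace).
#' @param seq Character vector of nucleotide sequences over `A,C,G,T,N`.
#'   Lowercase and `U` are normalised; other IUPAC ambiguity codes become
#'   `N` with a warning.
#' @param topology `"linear"` or `"circular"`, recycled along `id`.
#' @return A tibble with columns `id`, `seq`, `topology`.
#' @examples
#' seq_record("chr", "acgu")  # normalised to ACGT
#' @export
seq_record <- function(id, seq, topology = "linear") {
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have the same length.")
  }
  topology <- rep_len(topology, length(id))
  validate_seq_tbl(tibble(
    id = as.character(id),
    seq = normalize_seq(as.character(seq)),
    topology = topology
  ))
}

#' @keywords internal
validate_seq_tbl <- function(x, arg = "sequence table") {
  stopifnot(is.data.frame(x), all(c("id", "seq", "topology") %in% names(x)))
  x <- as_tibble(x)
  if (nrow(x) == 0) abort(paste0(arg, " has no sequences."))
  if (any(is.na(x$id)) || any(x$id == "") || any(grepl("\\s", x$id))) {
    abort(paste0(arg, ": ids must be non-empty and contain no whitespace."))
  }
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    abort(paste0(arg, ": duplicate id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(nchar(x$seq) < 1)) abort(paste0(arg, ": empty sequence."))
  bad <- grepl("[^ACGTN]", x$seq)
  if (any(bad)) {
    abort(paste0(
      arg, ": illegal characters in sequence '", x$id[which(bad)[1]], "'."
    ))
  }
  if (!all(x$topology %in% c("linear", "circular"))) {
    abort(paste0(arg, ": topology must be 'linear' or 'circular'."))
  }
  x
}

# Uppercase, U->T, other IUPAC ambiguity codes -> N (with a warning).
#' @keywords internal
normalize_seq <- function(seq) {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  amb <- grepl("[RYSWKMBDHV]", seq)
  if (any(amb)) {
    warn("IUPAC ambiguity codes mapped to N.")
    seq[amb] <- gsub("[RYSWKMBDHV]", "N", seq[amb])
  }
  seq
}

#' Reverse complement
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Substring of a circular sequence, 0-based start, arbitrary length <= 2n.
#' @keywords internal
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len <= 2 * n)
  start <- ((start %% n) + n) %% n
  d <- paste0(seq, seq)
  substr(d, start + 1, start + len)
}

# Uniform random DNA string of length n using the current RNG stream.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}
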