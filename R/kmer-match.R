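# Exact-match machinery shared by the internal aligner and the
# inverted-repeat finder: seed with shared k-mers, then collapse seeds on
# each diagonal into maximal exact match runs.

# All k-mers of a string as a character vector; element i is the k-mer at
# 0-based position i - 1.
#' @keywords internal
kmer_vector <- function(s, k) {
  n <- nchar(s)
  stopifnot(k >= 1, k <= n)
  substring(s, 1:(n - k + 1), k:n)
}

# Maximal exact match blocks between strings a and b, found via shared
# k-mers grouped by diagonal (a_pos - b_pos). Returns a tibble with
# 0-based `a_start`, `b_start` and `len` (>= k). Maximality holds because
# any extension of a run would contribute a further matching k-mer on the
# same diagonal.
#' @keywords internal
max_exact_matches <- function(a, b, k) {
  na <- nchar(a)
  nb <- nchar(b)
  if (k > na || k > nb) {
    abort("k exceeds a sequence length.")
  }
  da <- tibble(kmer = kmer_vector(a, k), a = 0:(na - k))
  db <- tibble(kmer = kmer_vector(b, k), b = 0:(nb - k))
  m <- inner_join(da, db, by = "kmer", relationship = "many-to-many")
  if (nrow(m) == 0) {
    return(tibble(a_start = integer(), b_start = integer(), len = integer()))
  }
  m <- m |>
    mutate(d = .data$a - .data$b) |>
    arrange(.data$d, .data$a)
  new_run <- c(TRUE, diff(m$a) != 1L | diff(m$d) != 0L)
  m$run <- cumsum(new_run)
  m |>
    group_by(.data$run) |>
    summarise(
      a_start = min(.data$a), b_start = min(.data$b),
      len = dplyr::n() + k - 1L, .groups = "drop"
    ) |>
    select("a_start", "b_start", "len")
}
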