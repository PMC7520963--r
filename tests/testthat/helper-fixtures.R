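# Shared fixtures and independent oracles.

# Small plastome used across suites: 8 kb LSC, 2 kb IRs, 1.5 kb SSC.
small_plastome <- function(seed = 1, lsc = 8000, ssc = 1500, ir = 2000) {
  make_plastome(lsc_len = lsc, ssc_len = ssc, ir_len = ir, seed = seed)
}

# Maximal-run positions on all diagonals between character vectors x and
# y; calls fn(ia_run, ib_run) for every run of equality of length >= k.
# Character-level scan -- no k-mers, no joins -- so it is an independent
# path from the package's anchor machinery.
scan_diagonals <- function(x, y, k, fn) {
  nx <- length(x)
  ny <- length(y)
  for (d in (-(ny - 1)):(nx - 1)) {
    ia <- max(1, 1 + d):min(nx, ny + d)
    ib <- ia - d
    eq <- x[ia] == y[ib]
    if (!any(eq)) next
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (ri in which(r$values & r$lengths >= k)) {
      fn(ia[starts[ri]:ends[ri]], ib[starts[ri]:ends[ri]])
    }
  }
  invisible(NULL)
}

# Independent longest-inverted-repeat oracle for a circular sequence:
# scans the doubled sequence against its doubled reverse complement and
# returns the maximal length of a disjoint inverted block pair, or 0.
oracle_longest_ir <- function(s) {
  n <- nchar(s)
  x <- strsplit(paste0(s, s), "")[[1]]
  y <- strsplit(paste0(revcomp(s), revcomp(s)), "")[[1]]
  best <- 0
  scan_diagonals(x, y, 1, function(ia, ib) {
    len <- min(length(ia), n)
    if (len <= best) {
      return(invisible(NULL))
    }
    a0 <- ia[1] - 1 # 0-based position in the doubled sequence
    b0 <- ib[1] - 1
    i <- a0 %% n
    j <- (((n - b0 - len) %% n) + n) %% n
    if (i != j && ((j - i) %% n) >= len && ((i - j) %% n) >= len &&
        2 * len <= n) {
      best <<- len
    }
  })
  best
}

# Independent per-base coverage oracle: logical vector marking target
# bases inside any exact match of >= k bases with the query, on either
# strand.
oracle_covered_vector <- function(qseq, tseq, k) {
  nt <- nchar(tseq)
  covered <- rep(FALSE, nt)
  xq <- strsplit(qseq, "")[[1]]
  scan_diagonals(xq, strsplit(tseq, "")[[1]], k, function(ia, ib) {
    covered[ib] <<- TRUE
  })
  scan_diagonals(xq, strsplit(revcomp(tseq), "")[[1]], k, function(ia, ib) {
    covered[nt - ib + 1] <<- TRUE
  })
  covered
}

# Rotation of a string opened at 0-based offset k.
rotate_string <- function(s, k) {
  n <- nchar(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# Direct substitution into the composite-score formula, independent of
# compute_score().
oracle_score <- function(cov_ref, cov_qry, n_contigs) {
  rep_term <- if (cov_ref == 0 || cov_qry == 0) {
    0
  } else {
    min(cov_qry / cov_ref, cov_ref / cov_qry)
  }
  25 * (cov_ref + cov_qry + rep_term + 1 / n_contigs)
}
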