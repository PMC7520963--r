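make_aln <- function(qs, qe, ts, te, qlen = 100, tlen = 100, primary = TRUE,
                     strand = "+") {
  tibble::tibble(
    query_id = "q", query_len = qlen, query_start = qs, query_end = qe,
    strand = strand, target_id = "t", target_len = tlen,
    target_start = ts, target_end = te, n_matches = qe - qs,
    block_len = qe - qs, is_primary = primary
  )
}

test_that("covered_fraction unions intervals and checks its inputs", {
  two <- dplyr::bind_rows(make_aln(0, 50, 0, 50), make_aln(25, 75, 25, 75))
  expect_equal(covered_fraction(two, "target", c(t = 100)), 0.75)
  expect_equal(covered_fraction(two[0, ], "target", c(t = 100)), 0)
  expect_equal(
    covered_fraction(make_aln(0, 100, 0, 100), "target", c(t = 100)), 1
  )

  # order-independent and idempotent under duplicated records
  shuffled <- two[2:1, ]
  dup <- dplyr::bind_rows(two, two)
  expect_equal(covered_fraction(shuffled, "target", c(t = 100)), 0.75)
  expect_equal(covered_fraction(dup, "target", c(t = 100)), 0.75)

  # secondary alignments are ignored
  sec <- dplyr::bind_rows(make_aln(0, 50, 0, 50), make_aln(50, 100, 50, 100, primary = FALSE))
  expect_equal(covered_fraction(sec, "target", c(t = 100)), 0.5)

  expect_error(covered_fraction(two, "target", c(other = 100)), "missing")
  expect_error(covered_fraction(make_aln(0, 50, 90, 140), "target", c(t = 100)), "bounds")
})

test_that("the exact anchor aligner is complete on identity, strand and rotation", {
  t <- make_component(10000, seed = 41, id = "t", topology = "circular")
  q <- t
  q$id <- "q"
  self <- dplyr::filter(exact_anchor_align(q, t), is_primary)
  expect_equal(nrow(self), 1)
  expect_equal(self$query_start, 0)
  expect_equal(self$query_end, 10000)
  expect_equal(self$target_start, 0)
  expect_equal(self$target_end, 10000)
  expect_equal(self$strand, "+")

  rc <- seq_record("q", revcomp(t$seq))
  m <- dplyr::filter(exact_anchor_align(rc, t), is_primary)
  expect_equal(nrow(m), 1)
  expect_equal(m$strand, "-")
  expect_equal(m$query_end - m$query_start, 10000)

  rot <- seq_record("q", rotate_string(t$seq, 4000), topology = "circular")
  m <- dplyr::filter(exact_anchor_align(rot, t), is_primary)
  expect_equal(nrow(m), 2)
  ir <- IRanges::reduce(IRanges::IRanges(m$target_start + 1, m$target_end))
  expect_equal(sum(IRanges::width(ir)), 10000) # union covers the target

  expect_error(exact_anchor_align(q, t, k = 5), ">= 11")
})

test_that("coverage agrees with a per-base brute-force scan on small inputs", {
  p <- make_plastome(lsc_len = 700, ssc_len = 200, ir_len = 150, seed = 42)
  ref <- p$genome
  # k large enough that no spurious random k-mer matches arise: the brute
  # force counts every exact match while the pipeline assigns each query
  # base once, so the two only coincide when all matches are structural
  k <- 17
  cases <- list(
    identical = ref,
    rotated = make_variant(ref, "rotate", offset = 333),
    flipped = make_variant(ref, "flip_ssc", structure = p$structure),
    # deletion junction chosen free of chance homology: maximal match
    # blocks then stay query-disjoint and per-base assignment is
    # unambiguous, which the union oracle presumes
    dropped = make_variant(ref, "drop_region", start = 150, end = 400),
    fragmented = make_variant(ref, "split", n_pieces = 3)
  )
  for (nm in names(cases)) {
    asm <- cases[[nm]]
    cov <- bidirectional_coverage(asm, ref, k = k)
    # per-base union over all contigs' exact matches on the reference
    covered <- rep(FALSE, nchar(ref$seq))
    for (i in seq_len(nrow(asm))) {
      covered <- covered | oracle_covered_vector(asm$seq[i], ref$seq, k)
    }
    expect_equal(cov$cov_ref, mean(covered), info = nm)
  }

  # when junction homology does make maximal blocks overlap on the query,
  # per-base assignment keeps one witness of the contested bases, so the
  # union oracle is an upper bound
  messy <- make_variant(ref, "drop_region", start = 100, end = 350)
  cov <- bidirectional_coverage(messy, ref, k = 17)
  expect_lte(cov$cov_ref, mean(oracle_covered_vector(messy$seq, ref$seq, 17)))
})

test_that("bidirectional coverage reflects completeness and surplus copies", {
  p <- small_plastome(seed = 43)
  ref <- p$genome

  cov <- bidirectional_coverage(ref, ref)
  expect_equal(cov$cov_ref, 1)
  expect_equal(cov$cov_qry, 1)

  half <- seq_record("h", substr(ref$seq, 1, nchar(ref$seq) / 2))
  cov <- bidirectional_coverage(half, ref)
  expect_equal(cov$cov_ref, 0.5)
  expect_equal(cov$cov_qry, 1)

  tandem <- make_variant(ref, "tandem_duplicate")
  cov <- bidirectional_coverage(tandem, ref)
  expect_equal(cov$cov_ref, 1)
  expect_equal(cov$cov_qry, 0.5) # primary-only counting sees the surplus

  expect_error(bidirectional_coverage(ref[0, ], ref), "no sequences")
})
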