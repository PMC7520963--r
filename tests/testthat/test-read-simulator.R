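test_that("sliding-window simulation realizes the requested coverage", {
  sp <- simulation_spec(read_len = 150)

  circ <- make_component(10000, seed = 31, id = "c", topology = "circular")
  pr <- simulate_component(circ, 30, sp)
  expect_equal(nrow(pr), 1000) # step 10 over the 10 kb circle
  expect_equal(sum(nchar(pr$fwd_seq) + nchar(pr$rev_seq)), 300000)
  expect_equal(realized_coverage(pr, c(c = 10000))$coverage, 30)

  lin <- make_component(10000, seed = 32, id = "l")
  prl <- simulate_component(lin, 30, sp)
  bases <- sum(nchar(prl$fwd_seq) + nchar(prl$rev_seq))
  expect_lte(abs(bases - 30 * 10000), 2 * 150) # within one fragment

  # odd coverage on a linear sequence still lands within one fragment
  pro <- simulate_component(lin, 7, sp)
  expect_lte(abs(sum(nchar(pro$fwd_seq) + nchar(pro$rev_seq)) - 7 * 10000), 300)

  expect_error(simulate_component(make_component(100, seed = 1), 30, sp), "shorter")
})

test_that("simulated reads are perfect, including across the circular origin", {
  sp <- simulation_spec(read_len = 60, fragment_len = 150)
  circ <- make_component(2000, seed = 33, id = "c", topology = "circular")
  pr <- simulate_component(circ, 20, sp)
  doubled <- paste0(circ$seq, circ$seq)
  expect_true(all(
    substring(doubled, pr$frag_start + 1, pr$frag_start + 60) == pr$fwd_seq
  ))
  expect_true(all(
    substring(doubled, pr$frag_start + 91, pr$frag_start + 150) ==
      revcomp(pr$rev_seq)
  ))
  # some fragments must wrap the origin for the check to mean anything
  expect_gt(sum(pr$frag_start > 2000 - 150), 0)
  expect_true(all(nchar(pr$fwd_seq) == 60 & nchar(pr$rev_seq) == 60))
})

test_that("mixtures respect the genome:chloroplast ratio semantics", {
  plast <- small_plastome(seed = 34)$genome
  nuc <- make_component(20000, seed = 35, id = "nuclear")
  mit <- make_component(5000, seed = 36, id = "mito")
  lens <- c(nuclear = 20000, mito = 5000, plastome = nchar(plast$seq))

  # 0:1 keeps only plastid reads
  only <- simulate_mixture(plast, spec = simulation_spec(ratio = "0:1", seed = 2))
  expect_setequal(unique(only$component), "plastome")
  expect_equal(
    realized_coverage(only, lens)$coverage, 30 # nuclear_cov * c = 30 * 1
  )

  mix <- simulate_mixture(plast, nuc, mit,
    spec = simulation_spec(ratio = c(1, 10), seed = 2)
  )
  rc <- realized_coverage(mix, lens)
  expect_equal(rc$coverage[rc$component == "nuclear"], 30)
  expect_equal(rc$coverage[rc$component == "mito"], 300)
  expect_equal(rc$coverage[rc$component == "plastome"], 300)

  # base counts per origin are invariant to the shuffle seed
  mix2 <- simulate_mixture(plast, nuc, mit,
    spec = simulation_spec(ratio = c(1, 10), seed = 99)
  )
  expect_false(identical(mix$pair_id, mix2$pair_id))
  expect_equal(realized_coverage(mix2, lens), rc)

  expect_error(
    simulate_mixture(plast, spec = simulation_spec(ratio = c(1, 10), seed = 1)),
    "nuclear"
  )
})

test_that("simulation output is byte-identical for a fixed seed", {
  plast <- small_plastome(seed = 37)$genome
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    pairs <- simulate_mixture(plast,
      spec = simulation_spec(ratio = "0:1", nuclear_cov = 5, seed = 7)
    )
    write_paired_fastq(
      pairs, file.path(d, "forward.fq"), file.path(d, "reverse.fq")
    )
  }
  for (f in c("forward.fq", "reverse.fq")) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f))
    )
  }
})

test_that("subsampling is exact, uniform and error-checked", {
  plast <- small_plastome(seed = 38)$genome
  pairs <- simulate_component(
    plast, 3, simulation_spec(read_len = 50, fragment_len = 100)
  )[1:100, ]

  sub <- subsample_pairs(pairs, 40, seed = 5)
  expect_equal(nrow(sub), 40)
  expect_equal(anyDuplicated(sub$pair_id), 0)

  all_back <- subsample_pairs(pairs, 100, seed = 5)
  expect_setequal(all_back$pair_id, pairs$pair_id)

  expect_error(subsample_pairs(pairs, 101), "101.*100")

  # uniformity: selection frequency of each of 10 pairs over repeated
  # draws of one pair is 0.1 within 3 standard errors
  ten <- pairs[1:10, ]
  reps <- 2000
  picks <- vapply(
    seq_len(reps),
    function(i) subsample_pairs(ten, 1, seed = i)$pair_id, character(1)
  )
  freq <- table(factor(picks, levels = ten$pair_id)) / reps
  se <- sqrt(0.1 * 0.9 / reps)
  expect_true(all(abs(freq - 0.1) <= 3 * se))
})
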