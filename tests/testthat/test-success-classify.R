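test_that("reference-mode success is inclusive at the score threshold", {
  expect_true(classify_reference_mode(99)$success)
  expect_false(classify_reference_mode(98.99)$success)
  expect_true(classify_reference_mode(100)$success)
  expect_match(classify_reference_mode(50)$reasons[[1]], "score below")
  expect_length(classify_reference_mode(99.5)$reasons[[1]], 0)
  expect_error(classify_reference_mode(101), "\\[0, 100\\]")
})

test_that("reference-free classification checks all criteria inclusively", {
  # scaled-down criteria exercise the same logic as the full-size ones
  crit <- novel_criteria(min_total_len = 13500, min_ir_len = 2000)

  good <- small_plastome(seed = 71)$genome # 13,500 bp, IR 2,000
  res <- classify_novel_mode(good, crit)
  expect_true(res$success)
  expect_length(res$reasons[[1]], 0)
  expect_equal(res$ir_len, 2000)

  # one bp short in total length: that criterion alone fails
  short <- make_plastome(7999, 1500, 2000, seed = 72)$genome
  res <- classify_novel_mode(short, crit)
  expect_false(res$success)
  expect_match(res$reasons[[1]], "total length")
  expect_length(res$reasons[[1]], 1)

  # IR one bp short
  small_ir <- make_plastome(8002, 1500, 1999, seed = 73)$genome # 13,500 bp total
  res <- classify_novel_mode(small_ir, crit)
  expect_false(res$success)
  expect_match(res$reasons[[1]], "IR length")

  # fragmented assembly fails on the contig count
  frag <- make_variant(good, "split", n_pieces = 2)
  res <- classify_novel_mode(frag, crit)
  expect_false(res$success)
  expect_true(any(grepl("contig", res$reasons[[1]])))
})

test_that("precision/recall/F1 follow the confusion matrix", {
  mixed <- c(TRUE, FALSE, TRUE, FALSE)
  perfect <- prf(mixed, mixed)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  r <- prf(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(r[, c("tp", "fp", "fn", "tn")], tibble::tibble(tp = 2, fp = 1, fn = 1, tn = 0))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)

  allneg <- prf(rep(FALSE, 4), mixed)
  expect_equal(allneg$precision, 0)
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$f1, 0)

  expect_error(prf(TRUE, c(TRUE, FALSE)), "same length")
})

test_that("cutoff calibration recovers a separable labelled set", {
  # positives sit at or above (130 kb, 17 kb); negatives fail one axis
  features <- tibble::tibble(
    n_contigs = 1,
    total_len = c(130000, 140000, 155000, 129000, 135000, 120000, 150000),
    ir_len = c(17000, 20000, 25000, 18000, 16500, 12000, 10000),
    truth = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  cal <- select_cutoffs(features)
  expect_equal(glance(cal)$min_total_len, 130000)
  expect_equal(glance(cal)$min_ir_len, 17000)
  expect_equal(glance(cal)$f1, 1)

  # the selected F1 equals the grid maximum found by an independent
  # double loop over the grid
  lg <- seq(125000, 135000, by = 5000)
  ig <- seq(15000, 19000, by = 2000)
  cal2 <- select_cutoffs(features, length_grid = lg, ir_grid = ig)
  best <- 0
  for (l in lg) {
    for (i in ig) {
      pred <- features$n_contigs == 1 & features$total_len >= l &
        features$ir_len >= i
      best <- max(best, prf(pred, features$truth)$f1)
    }
  }
  expect_equal(glance(cal2)$f1, best)

  # all-positive truth: everything classified positive wins, so the
  # smallest grid pair is selected by the tie-break
  allpos <- features
  allpos$truth <- TRUE
  cal3 <- select_cutoffs(allpos, length_grid = c(100000, 110000), ir_grid = c(5000, 8000))
  expect_equal(glance(cal3)$min_total_len, 100000)
  expect_equal(glance(cal3)$min_ir_len, 5000)

  # a one-pair grid returns that pair
  cal4 <- select_cutoffs(features, length_grid = 130000, ir_grid = 17000)
  expect_equal(glance(cal4)$min_total_len, 130000)

  expect_error(select_cutoffs(features, length_grid = numeric()), "non-empty")
})

test_that("raising a cutoff never flips a prediction to positive", {
  set.seed(74)
  features <- tibble::tibble(
    n_contigs = sample(1:2, 40, replace = TRUE),
    total_len = sample(100000:160000, 40),
    ir_len = sample(5000:30000, 40),
    truth = sample(c(TRUE, FALSE), 40, replace = TRUE)
  )
  pred_at <- function(l, i) {
    features$n_contigs == 1 & features$total_len >= l & features$ir_len >= i
  }
  base <- pred_at(120000, 15000)
  for (l in c(125000, 140000)) {
    for (i in c(18000, 25000)) {
      expect_true(all(pred_at(l, i) <= base))
    }
  }
})
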