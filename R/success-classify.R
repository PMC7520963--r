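# Success classification: with a reference, success is a score of 99 or
# higher; without one, a single contig of at least 130 kbp carrying an
# inverted repeat of at least 17 kbp. The reference-free cutoffs can be
# recalibrated by F1-maximising grid search over a labelled set.

#' Reference-free success criteria
#'
#' @param min_total_len Minimum assembly length in bp (default 130,000).
#' @param min_ir_len Minimum inverted-repeat length in bp (default
#'   17,000).
#' @param require_single_contig Must the assembly be a single contig?
#' @return A `novel_criteria` list.
#' @export
novel_criteria <- function(min_total_len = 130000, min_ir_len = 17000,
                           require_single_contig = TRUE) {
  stopifnot(min_total_len > 0, min_ir_len > 0)
  structure(
    list(
      min_total_len = min_total_len, min_ir_len = min_ir_len,
      require_single_contig = require_single_contig
    ),
    class = "novel_criteria"
  )
}

#' Classify assembly success when a reference exists
#'
#' @param score Composite score in `[0, 100]`.
#' @param threshold Success threshold, inclusive (default 99).
#' @return A one-row tibble with `mode`, `success` and a `reasons`
#'   list-column naming each failed criterion (empty on success).
#' @examples
#' classify_reference_mode(99)$success # TRUE: the threshold is inclusive
#' @export
classify_reference_mode <- function(score, threshold = 99) {
  if (is.na(score) || score < 0 || score > 100) {
    abort("score must lie in [0, 100].")
  }
  ok <- score >= threshold
  tibble(
    mode = "reference", success = ok,
    reasons = list(if (ok) character() else sprintf("score below %g", threshold))
  )
}

# Per-assembly features the reference-free criteria look at. The IR scan
# treats the longest contig as circular (reference-free assemblies are
# putative circles) and reports the longest repeat of at least
# `ir_scan_min` bp, or 0 when none exists.
#' @keywords internal
assembly_features <- function(assembly, k = 31, ir_scan_min = 1000) {
  assembly <- validate_seq_tbl(assembly, "assembly")
  longest <- assembly[which.max(nchar(assembly$seq)), ]
  longest$topology <- "circular"
  st <- if (nchar(longest$seq) >= 2 * ir_scan_min) {
    find_ir(longest, min_ir_len = ir_scan_min, k = min(k, ir_scan_min))
  } else {
    NULL
  }
  tibble(
    n_contigs = nrow(assembly),
    total_len = sum(nchar(assembly$seq)),
    ir_len = if (is.null(st)) 0 else st$ir_len
  )
}

#' Classify assembly success without a reference
#'
#' Success requires (inclusively) a single contig, a total length of at
#' least `criteria$min_total_len`, and an inverted repeat of at least
#' `criteria$min_ir_len` on the (longest) contig treated as circular.
#'
#' @param assembly Sequence table, one row per contig.
#' @param criteria A [novel_criteria()] object.
#' @param k Anchor k-mer size for IR detection.
#' @return A one-row tibble with `mode`, `success`, a `reasons`
#'   list-column, and the measured `n_contigs`, `total_len`, `ir_len`.
#' @export
classify_novel_mode <- function(assembly, criteria = novel_criteria(),
                                k = 31) {
  f <- assembly_features(assembly, k = k)
  reasons <- character()
  if (criteria$require_single_contig && f$n_contigs != 1) {
    reasons <- c(reasons, "more than one contig")
  }
  if (f$total_len < criteria$min_total_len) {
    reasons <- c(reasons, sprintf(
      "total length %d below %d", f$total_len, criteria$min_total_len
    ))
  }
  if (f$ir_len < criteria$min_ir_len) {
    reasons <- c(reasons, sprintf(
      "IR length %d below %d", f$ir_len, criteria$min_ir_len
    ))
  }
  tibble(
    mode = "novel", success = length(reasons) == 0, reasons = list(reasons),
    n_contigs = f$n_contigs, total_len = f$total_len, ir_len = f$ir_len
  )
}

#' Precision, recall and F1 of a binary classification
#'
#' @param predicted,truth Logical vectors of equal length.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`. Undefined ratios (zero denominators) are reported
#'   as 0.
#' @examples
#' prf(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE, TRUE))
#' @export
prf <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth must have the same length.")
  }
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1
  )
}

#' Calibrate reference-free cutoffs by F1 grid search
#'
#' Exhaustively evaluates every (length cutoff, IR cutoff) pair on a
#' labelled feature set, applying the reference-free criteria to the
#' precomputed features, and returns the pair with the highest F1. Ties
#' break towards the smallest length cutoff, then the smallest IR cutoff.
#' The default grids bracket the plastome sizes seen across land plants
#' (genomes of 120-160 kbp, IRs from 10 kbp up).
#'
#' @param features Tibble with columns `n_contigs`, `total_len`, `ir_len`
#'   and logical `truth` (one row per labelled assembly).
#' @param length_grid,ir_grid Numeric vectors of candidate cutoffs in bp.
#' @param require_single_contig Passed through to the criteria.
#' @return A `cutoff_calibration` object; `glance()` gives the selected
#'   cutoffs with their precision/recall/F1, `tidy()` the full grid.
#' @export
select_cutoffs <- function(features,
                           length_grid = seq(100000, 160000, by = 1000),
                           ir_grid = seq(10000, 30000, by = 500),
                           require_single_contig = TRUE) {
  stopifnot(
    is.data.frame(features), nrow(features) > 0,
    all(c("n_contigs", "total_len", "ir_len", "truth") %in% names(features))
  )
  if (length(length_grid) == 0 || length(ir_grid) == 0) {
    abort("cutoff grids must be non-empty.")
  }
  single_ok <- !require_single_contig | features$n_contigs == 1
  grid <- tidyr::expand_grid(
    min_total_len = sort(length_grid), min_ir_len = sort(ir_grid)
  )
  stats_tbl <- purrr::map2(
    grid$min_total_len, grid$min_ir_len,
    function(lmin, imin) {
      pred <- single_ok & features$total_len >= lmin & features$ir_len >= imin
      prf(pred, features$truth)
    }
  ) |> bind_rows()
  grid <- dplyr::bind_cols(grid, stats_tbl)
  best <- grid |>
    arrange(desc(.data$f1), .data$min_total_len, .data$min_ir_len) |>
    dplyr::slice(1)
  structure(
    list(best = best, grid = grid, n = nrow(features)),
    class = "cutoff_calibration"
  )
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf(
    "Selected cutoffs: length >= %g bp, IR >= %g bp (F1 = %.3f on %d assemblies)\n",
    x$best$min_total_len, x$best$min_ir_len, x$best$f1, x$n
  ))
  invisible(x)
}

#' @rdname select_cutoffs
#' @param x A `cutoff_calibration`.
#' @param ... Unused.
#' @method tidy cutoff_calibration
#' @export
tidy.cutoff_calibration <- function(x, ...) {
  x$grid
}

#' @rdname select_cutoffs
#' @method glance cutoff_calibration
#' @export
glance.cutoff_calibration <- function(x, ...) {
  x$best
}
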