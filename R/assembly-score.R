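# The composite 0-100 assembly score: four equally weighted terms --
# completeness (cov_ref), correctness (cov_qry), repeat resolution
# (min of the two coverage ratios) and continuity (1 / number of contigs).

#' Compute the composite assembly score from its components
#'
#' The score is
#' `25 * (cov_ref + cov_qry + min(cov_qry/cov_ref, cov_ref/cov_qry) +
#' 1/n_contigs)`, on a 0-100 scale with 100 for a single contig that
#' covers, and is covered by, the reference completely. When either
#' coverage is zero the repeat-resolution term is defined as zero so that
#' failed mappings still yield a finite score.
#'
#' @param cov_ref Completeness: fraction of the reference covered by the
#'   assembly, in `[0, 1]`.
#' @param cov_qry Correctness: fraction of the assembly covered by the
#'   reference, in `[0, 1]`.
#' @param n_contigs Number of contigs (>= 1).
#' @return A `plast_score` object; see [tidy.plast_score()] and
#'   [glance.plast_score()].
#' @examples
#' compute_score(1, 1, 1)$score # 100
#' compute_score(1, 1, 3)$score # 83.33...
#' @export
compute_score <- function(cov_ref, cov_qry, n_contigs) {
  if (is.na(cov_ref) || is.na(cov_qry) ||
      cov_ref < 0 || cov_ref > 1 || cov_qry < 0 || cov_qry > 1) {
    abort("coverage fractions must lie in [0, 1].")
  }
  if (n_contigs < 1) abort("n_contigs must be >= 1.")
  repeat_term <- if (cov_ref == 0 || cov_qry == 0) {
    0
  } else {
    min(cov_qry / cov_ref, cov_ref / cov_qry)
  }
  structure(
    list(
      cov_ref = cov_ref, cov_qry = cov_qry, repeat_term = repeat_term,
      n_contigs = as.integer(n_contigs),
      score = 25 * (cov_ref + cov_qry + repeat_term + 1 / n_contigs),
      coverage = NULL
    ),
    class = "plast_score"
  )
}

#' Score an assembly against a reference genome
#'
#' Runs [bidirectional_coverage()] and feeds the two fractions plus the
#' contig count into [compute_score()].
#'
#' @inheritParams bidirectional_coverage
#' @return A `plast_score` object with the underlying `coverage_result`
#'   attached.
#' @examples
#' p <- make_plastome(lsc_len = 3000, ssc_len = 800, ir_len = 600, seed = 3)
#' score_assembly(p$genome, p$genome, k = 21)$score # 100
#' @export
score_assembly <- function(assembly, reference, k = 31, aln_ref = NULL,
                           aln_qry = NULL) {
  cov <- bidirectional_coverage(assembly, reference,
    k = k,
    aln_ref = aln_ref, aln_qry = aln_qry
  )
  out <- compute_score(cov$cov_ref, cov$cov_qry, nrow(assembly))
  out$coverage <- cov
  out
}

#' @export
print.plast_score <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Assembly score: %.2f / 100\n",
      "  completeness (cov_ref):    %.4f\n",
      "  correctness  (cov_qry):    %.4f\n",
      "  repeat resolution:         %.4f\n",
      "  continuity (1/%d contigs):  %.4f\n"
    ),
    x$score, x$cov_ref, x$cov_qry, x$repeat_term, x$n_contigs,
    1 / x$n_contigs
  ))
  invisible(x)
}

#' Tidy the four score components
#'
#' @param x A `plast_score` object.
#' @param ... Unused.
#' @return One row per component with its value in `[0, 1]` and its
#'   contribution in score points.
#' @method tidy plast_score
#' @export
tidy.plast_score <- function(x, ...) {
  tibble(
    component = c(
      "completeness", "correctness", "repeat_resolution", "continuity"
    ),
    value = c(x$cov_ref, x$cov_qry, x$repeat_term, 1 / x$n_contigs),
    contribution = 25 * c(x$cov_ref, x$cov_qry, x$repeat_term, 1 / x$n_contigs)
  )
}

#' One-row score summary
#'
#' @param x A `plast_score` object.
#' @param ... Unused.
#' @method glance plast_score
#' @export
glance.plast_score <- function(x, ...) {
  tibble(
    cov_ref = x$cov_ref, cov_qry = x$cov_qry, repeat_term = x$repeat_term,
    n_contigs = x$n_contigs, score = x$score
  )
}

#' Compare the scores of two evaluation runs
#'
#' Pairs the per-dataset scores of two runs of the same evaluation,
#' flags datasets that failed in exactly one run, and reports how many
#' scored identically within tolerance -- a robustness check for
#' assemblers that are not deterministic.
#'
#' @param run1,run2 Tibbles with columns `dataset` and `score` (`NA`
#'   score means the run produced no assembly), or named numeric vectors.
#' @param tolerance Absolute score difference still counted as identical
#'   (default 0.01, one reporting unit; boundary inclusive).
#' @return A `consistency_report` with per-dataset rows and a summary.
#' @export
compare_runs <- function(run1, run2, tolerance = 0.01) {
  as_run <- function(r) {
    if (is.numeric(r) && !is.null(names(r))) {
      r <- tibble(dataset = names(r), score = unname(r))
    }
    stopifnot(is.data.frame(r), all(c("dataset", "score") %in% names(r)))
    as_tibble(r)[, c("dataset", "score")]
  }
  r1 <- as_run(run1)
  r2 <- as_run(run2)
  if (!setequal(r1$dataset, r2$dataset) || anyDuplicated(r1$dataset) ||
      anyDuplicated(r2$dataset)) {
    abort("runs must cover the same set of datasets exactly once.")
  }
  d <- inner_join(
    rename(r1, score_run1 = "score"),
    rename(r2, score_run2 = "score"),
    by = "dataset"
  ) |>
    mutate(
      both_succeeded = !is.na(.data$score_run1) & !is.na(.data$score_run2),
      one_sided_failure = xor(is.na(.data$score_run1), is.na(.data$score_run2)),
      abs_diff = abs(.data$score_run1 - .data$score_run2),
      # inclusive boundary, robust to floating-point representation of
      # score differences (92.81 - 92.80 slightly exceeds 0.01 in binary)
      identical = .data$both_succeeded &
        .data$abs_diff <= tolerance + 1e-9
    )
  structure(
    list(
      datasets = d,
      summary = tibble(
        n_datasets = nrow(d),
        n_identical = sum(d$identical),
        n_one_sided_failures = sum(d$one_sided_failure),
        max_abs_diff = if (any(d$both_succeeded)) {
          max(d$abs_diff[d$both_succeeded])
        } else {
          NA_real_
        }
      ),
      tolerance = tolerance
    ),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Consistency: %d/%d identical (tol %.3g), %d one-sided failures, max |diff| %s\n",
    s$n_identical, s$n_datasets, x$tolerance, s$n_one_sided_failures,
    ifelse(is.na(s$max_abs_diff), "NA", sprintf("%.4f", s$max_abs_diff))
  ))
  invisible(x)
}

#' @rdname compare_runs
#' @param x A `consistency_report`.
#' @param ... Unused.
#' @method tidy consistency_report
#' @export
tidy.consistency_report <- function(x, ...) {
  x$datasets
}

#' @rdname compare_runs
#' @method glance consistency_report
#' @export
glance.consistency_report <- function(x, ...) {
  x$summary
}
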