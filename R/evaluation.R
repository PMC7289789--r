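#' Scanning-mode confusion counts
#'
#' Target-level sensitivity, call-level precision: TP is the number of
#' targets hit by at least one call under the fractional-overlap rule, FP is
#' the number of calls hitting no target, FN the remaining targets.
#' Duplicate hits on one target credit a single TP and no FP, so
#' \code{TP + FN == nrow(targets)} always.
#'
#' @param calls,targets strand-annotated \code{genomic_intervals}.
#' @param min_frac minimum overlap fraction (default 0.5).
#' @param denominator overlap denominator, see \code{\link{is_hit}}.
#' @return named vector \code{c(TP, FP, FN)}.
#' @export
confusion_scanning <- function(calls, targets, min_frac = 0.5,
                               denominator = "prediction") {
  m <- hit_matrix(calls, targets, min_frac, denominator)
  TP <- sum(colSums(m) > 0)
  FP <- if (nrow(calls)) sum(rowSums(m) == 0) else 0L
  c(TP = TP, FP = FP, FN = nrow(targets) - TP)
}

#' Pre-labelled confusion counts
#'
#' Classical thresholded confusion over a fixed candidate set: predicted
#' positive iff score >= threshold.
#'
#' @param scores numeric scores, one per candidate.
#' @param labels 0/1 labels, same length.
#' @param threshold score threshold.
#' @return named vector \code{c(TP, FP, FN, TN)}.
#' @export
confusion_prelabelled <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) {
    stop("confusion_prelabelled: scores and labels differ in length",
         call. = FALSE)
  }
  pred <- scores >= threshold
  y <- as.logical(labels)
  c(TP = sum(pred & y), FP = sum(pred & !y),
    FN = sum(!pred & y), TN = sum(!pred & !y))
}

#' Precision, sensitivity and F1 from confusion counts
#'
#' \code{P = TP/(TP+FP)}, \code{S = TP/(TP+FN)} (both 0 when the denominator
#' is 0), \code{F1 = 2PS/(P+S)} computed from the unrounded P and S (0 when
#' \code{P + S == 0}).
#'
#' @param TP,FP,FN non-negative counts.
#' @return named vector \code{c(precision, sensitivity, F1)}.
#' @export
prf <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  S <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + S > 0) 2 * P * S / (P + S) else 0
  c(precision = P, sensitivity = S, F1 = F1)
}

#' F1 from a printed precision/sensitivity pair
#' @param precision,sensitivity reals in [0, 1].
#' @return harmonic mean \code{2PS/(P+S)} (0 when both are 0).
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity > 0,
         2 * precision * sensitivity / (precision + sensitivity), 0)
}

#' Precision-sensitivity curve
#'
#' One operating point per threshold. Scanning mode re-derives calls from
#' the scored windows at every threshold (the merge policy is applied per
#' threshold); pre-labelled mode thresholds the candidate scores directly.
#' The default grid is the sorted set of observed scores (exact curve),
#' down-sampled to at most \code{max_points} distinct thresholds.
#'
#' @param windows scored windows (scanning mode) or \code{NULL}.
#' @param targets targets (scanning mode) or \code{NULL}.
#' @param scores,labels pre-labelled mode inputs.
#' @param mode \code{"scanning"} or \code{"pre_labelled"}.
#' @param thresholds optional sorted threshold grid in [0, 1].
#' @param min_frac,merge scanning-mode hit rule and merge policy.
#' @param max_points cap on the default grid size.
#' @return data.frame (threshold, precision, sensitivity); sensitivity is
#'   non-increasing in threshold.
#' @export
pr_curve <- function(windows = NULL, targets = NULL, scores = NULL,
                     labels = NULL, mode = c("scanning", "pre_labelled"),
                     thresholds = NULL, min_frac = 0.5,
                     merge = "cluster_max", max_points = 200L) {
  mode <- match.arg(mode)
  if (mode == "scanning") {
    stopifnot(!is.null(windows), !is.null(targets))
    obs <- sort(unique(windows$score))
  } else {
    stopifnot(!is.null(scores), !is.null(labels))
    obs <- sort(unique(scores))
  }
  if (is.null(thresholds)) {
    thresholds <- obs
    if (length(thresholds) > max_points) {
      # quantiles of the observed scores capture the mass of the
      # distribution; the uniform lattice keeps the grid dense where scores
      # are sparse (scan scores pile up near 0, leaving the informative
      # high-score range underrepresented in pure quantiles)
      thresholds <- unique(sort(c(
        stats::quantile(thresholds, probs = seq(0, 1,
                                                length.out = max_points %/% 2),
                        names = FALSE, type = 1),
        seq(min(obs), max(obs), length.out = max_points %/% 2))))
    }
  }
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(th) {
    cm <- if (mode == "scanning") {
      calls <- call_predictions(windows, th, merge)
      confusion_scanning(calls, targets, min_frac)
    } else {
      confusion_prelabelled(scores, labels, th)
    }
    pr <- prf(cm[["TP"]], cm[["FP"]], cm[["FN"]])
    data.frame(threshold = th, precision = pr[["precision"]],
               sensitivity = pr[["sensitivity"]])
  })
  do.call(rbind, rows)
}

#' Highest threshold reaching a target sensitivity
#'
#' The sensitivity-anchored operating points of the benchmarks: loose
#' (sensitivity 0.5) and strict (0.33) thresholds.
#'
#' @param curve data.frame from \code{\link{pr_curve}}.
#' @param target_s target sensitivity in (0, 1].
#' @return the highest threshold whose sensitivity >= \code{target_s}.
#' @export
threshold_at_sensitivity <- function(curve, target_s) {
  stopifnot(target_s > 0, target_s <= 1)
  ok <- curve$sensitivity >= target_s
  if (!any(ok)) {
    stop(structure(class = c("snc_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "threshold_at_sensitivity: maximum sensitivity %.3f < target %.3f",
                     max(curve$sensitivity), target_s),
                     call = NULL)))
  }
  max(curve$threshold[ok])
}

#' Scanned base pairs per false positive
#'
#' @param FP false-positive count.
#' @param scanned_bp total scanned nucleotides (> 0).
#' @return \code{scanned_bp / FP}; \code{Inf} when \code{FP == 0} ("no FP in
#'   N bp").
#' @export
fp_spacing <- function(FP, scanned_bp) {
  stopifnot(FP >= 0, scanned_bp > 0)
  if (FP == 0) Inf else scanned_bp / FP
}

#' Naive expression-ranked baseline
#'
#' The baseline any learned model should beat: for each percentile, the top
#' fraction of peaks ranked by decreasing expression are called positive and
#' compared with the targets under the hit rule. Expression ties break by
#' genomic order (deterministic).
#'
#' @param peaks \code{genomic_intervals} of expression peaks.
#' @param expression numeric expression per peak.
#' @param targets targets.
#' @param percentiles percentiles in (0, 100].
#' @param min_frac hit-rule overlap fraction.
#' @return data.frame (percentile, n_called, precision, sensitivity).
#' @export
expression_baseline <- function(peaks, expression, targets,
                                percentiles = c(1, 5, 10, 25, 50, 100),
                                min_frac = 0.5) {
  stopifnot(length(expression) == nrow(peaks),
            all(percentiles > 0), all(percentiles <= 100))
  ord <- order(-expression, peaks$chrom, peaks$start, peaks$end)
  rows <- lapply(percentiles, function(pct) {
    k <- max(1L, floor(length(ord) * pct / 100))
    calls <- peaks[ord[seq_len(k)], , drop = FALSE]
    class(calls) <- c("genomic_intervals", "data.frame")
    cm <- confusion_scanning(calls, targets, min_frac)
    pr <- prf(cm[["TP"]], cm[["FP"]], cm[["FN"]])
    data.frame(percentile = pct, n_called = k,
               precision = pr[["precision"]],
               sensitivity = pr[["sensitivity"]])
  })
  do.call(rbind, rows)
}

#' Assemble an evaluation report
#'
#' @param mode \code{"scanning"} or \code{"pre_labelled"}.
#' @param threshold score threshold used.
#' @param counts named confusion vector (TP, FP, FN, optionally TN).
#' @param scanned_bp scanned nucleotides (scanning mode; NA otherwise).
#' @param merge merge policy recorded for scanning reports.
#' @return an \code{evaluation_report} list.
#' @export
evaluation_report <- function(mode, threshold, counts, scanned_bp = NA_real_,
                              merge = NA_character_) {
  pr <- prf(counts[["TP"]], counts[["FP"]], counts[["FN"]])
  structure(list(mode = mode, threshold = threshold,
                 TP = unname(counts[["TP"]]), FP = unname(counts[["FP"]]),
                 FN = unname(counts[["FN"]]),
                 TN = if ("TN" %in% names(counts))
                   unname(counts[["TN"]]) else NA_integer_,
                 precision = unname(pr[["precision"]]),
                 sensitivity = unname(pr[["sensitivity"]]),
                 F1 = unname(pr[["F1"]]),
                 scanned_bp = scanned_bp,
                 fp_spacing = if (!is.na(scanned_bp))
                   fp_spacing(counts[["FP"]], scanned_bp) else NA_real_,
                 merge = merge),
            class = "evaluation_report")
}

#' Write an evaluation report as JSON and TSV
#' @param report an \code{evaluation_report}.
#' @param path_json,path_tsv output paths (either may be NULL).
#' @return invisibly, the report.
#' @export
write_report <- function(report, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_json)) {
    x <- unclass(report)
    if (length(x$fp_spacing) == 1L && !is.na(x$fp_spacing) &&
        is.infinite(x$fp_spacing)) {
      x$fp_spacing <- "no_false_positives"
    }
    jsonlite::write_json(x, path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(path_tsv)) {
    df <- as.data.frame(lapply(unclass(report), function(v)
      if (length(v) == 1L) v else paste(v, collapse = ",")))
    utils::write.table(df, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(report)
}
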