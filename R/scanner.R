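#' Slide a trained model across regions
#'
#' Generates width-\code{width} windows at stride \code{step} over every
#' region (and over both strands by default), encodes them and scores them
#' with the model. Window coordinates come from \code{\link{make_windows}}
#' (the same code path used everywhere), so a 150-bp region at width 100 and
#' step 5 yields 11 windows per strand.
#'
#' @param model a trained \code{snc_model}.
#' @param regions \code{genomic_intervals} to scan.
#' @param genome named character vector of chromosome sequences.
#' @param track \code{conservation_track}; required when the model has a C
#'   branch, may be \code{NULL} otherwise.
#' @param fold_backend \code{"nussinov"} or \code{"file"}.
#' @param structures precomputed structures for the file backend.
#' @param width,step window width and stride in bp (defaults 100 and 5, the
#'   genome-region protocol; peak scans conventionally use step 10).
#' @param strands strands to scan; default both.
#' @return a \code{scan_result}: list with \code{windows}
#'   (\code{genomic_intervals} with a score per window) and \code{params}.
#' @export
sliding_scan <- function(model, regions, genome, track = NULL,
                 fold_backend = "nussinov", structures = NULL,
                 width = 100, step = 5, strands = c("+", "-")) {
  stopifnot(inherits(model, "snc_model"))
  if ("C" %in% model$config$branches && is.null(track)) {
    stop("scan: model has a conservation branch but no track was supplied",
         call. = FALSE)
  }
  windows <- scan_windows(regions, width, step, strands)
  if (nrow(windows) == 0L) {
    return(structure(list(windows = windows,
                          params = list(width = width, step = step,
                                        strands = strands)),
                     class = "scan_result"))
  }
  enc <- encode_windows(windows, genome, track, fold_backend, structures,
                        target_length = model$config$input_length)
  windows$score <- predict_scores(model, enc)
  structure(list(windows = windows,
                 params = list(width = width, step = step, strands = strands)),
            class = "scan_result")
}

# Window coordinates for a scan, without encoding or scoring.
scan_windows <- function(regions, width = 100, step = 5,
                         strands = c("+", "-")) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    for (s in strands) {
      region <- regions[i, , drop = FALSE]
      region$strand <- s
      w <- make_windows(region, width, step)
      if (nrow(w)) out[[length(out) + 1L]] <- w
    }
  }
  if (!length(out)) return(genomic_intervals())
  res <- do.call(rbind, out)
  res <- unique(res)            # overlapping input regions may repeat windows
  rownames(res) <- NULL
  class(res) <- c("genomic_intervals", "data.frame")
  res
}

#' Convert scored windows into locus calls
#'
#' Windows with score >= \code{threshold} are clustered by same-strand
#' overlap (single linkage). Under the default \code{"cluster_max"} policy
#' each cluster emits one call spanning its highest-scoring window (ties:
#' leftmost), with the cluster's maximum score, so one locus yields one
#' call. Policy \code{"none"} emits every above-threshold window as its own
#' call (strict window-level PR curves).
#'
#' @param windows \code{genomic_intervals} with a \code{score} column (from
#'   \code{sliding_scan()$windows}).
#' @param threshold score threshold in [0, 1].
#' @param merge \code{"cluster_max"} (default) or \code{"none"}.
#' @return \code{genomic_intervals} of calls with scores.
#' @export
call_predictions <- function(windows, threshold,
                             merge = c("cluster_max", "none")) {
  merge <- match.arg(merge)
  stopifnot(threshold >= 0, threshold <= 1)
  hot <- windows[!is.na(windows$score) & windows$score >= threshold, ,
                 drop = FALSE]
  if (nrow(hot) == 0L) return(genomic_intervals())
  if (merge == "none") {
    out <- sort_intervals(hot)
    class(out) <- c("genomic_intervals", "data.frame")
    return(out)
  }
  cl <- cluster_by_overlap(hot)
  reps <- vapply(split(seq_len(nrow(hot)), cl), function(idx) {
    best <- idx[hot$score[idx] == max(hot$score[idx])]
    best[which.min(hot$start[best])]    # ties -> leftmost
  }, integer(1))
  out <- hot[reps, , drop = FALSE]
  out$score <- vapply(split(hot$score, cl), max, numeric(1))
  out$name <- sprintf("call_%d", seq_len(nrow(out)))
  sort_intervals(out)
}

#' Write scored windows as TSV
#' @param windows scored windows.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_windows_tsv <- function(windows, path) {
  df <- windows[, c("chrom", "start", "end", "strand", "score")]
  df$score <- formatC(df$score, format = "f", digits = 6)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
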