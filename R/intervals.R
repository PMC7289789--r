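#' Strand-aware genomic intervals
#'
#' Intervals are stored as a plain data.frame with class
#' \code{"genomic_intervals"} and columns \code{chrom}, \code{start},
#' \code{end}, \code{name}, \code{score}, \code{strand}. Coordinates follow
#' the BED convention: 0-based, half-open (\code{start} inclusive, \code{end}
#' exclusive). \code{score} is \code{NA} when absent (written as \code{"."}).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-valued coordinates, \code{0 <= start < end}.
#' @param strand \code{"+"} or \code{"-"} (recycled).
#' @param name feature names (recycled; default \code{"."}).
#' @param score numeric scores or \code{NA} (recycled).
#' @return A \code{genomic_intervals} data.frame.
#' @examples
#' genomic_intervals("chr1", 10, 110, strand = "+", score = 0.9)
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = "+", name = ".",
                              score = NA_real_) {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  df <- data.frame(
    chrom = as.character(chrom),
    start = start, end = end,
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df, context = "intervals") {
  if (nrow(df) == 0L) return(invisible(df))
  bad_coord <- which(!is.finite(df$start) | !is.finite(df$end) |
                       df$start < 0 | df$start >= df$end |
                       df$start != floor(df$start) | df$end != floor(df$end))
  if (length(bad_coord)) {
    stop(sprintf("%s: invalid coordinates at record %d (start=%s, end=%s); need 0 <= start < end, integral",
                 context, bad_coord[1], format(df$start[bad_coord[1]]),
                 format(df$end[bad_coord[1]])), call. = FALSE)
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop(sprintf("%s: invalid strand %s at record %d (must be '+' or '-')",
                 context, dQuote(df$strand[bad_strand[1]]), bad_strand[1]),
         call. = FALSE)
  }
  invisible(df)
}

as_intervals <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("name", "score", "strand")) {
    if (is.null(df[[col]])) {
      df[[col]] <- switch(col, name = ".", score = NA_real_, strand = "+")
    }
  }
  genomic_intervals(df$chrom, df$start, df$end, df$strand, df$name, df$score)
}

#' Interval lengths in base pairs
#' @param x a \code{genomic_intervals} data.frame.
#' @return numeric vector of \code{end - start}.
#' @export
interval_width <- function(x) x$end - x$start

sort_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  x <- x[order(x$chrom, x$start, x$end, x$strand), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a BED file
#'
#' Accepts 3- to 6-column BED (tab-separated, 0-based half-open). Columns 4-6
#' map to name/score/strand when present. A missing strand defaults to
#' \code{"+"} and the default is reported through a log message; a score of
#' \code{"."} is read as absent (\code{NA}).
#'
#' @param path path to an existing BED file.
#' @return A \code{genomic_intervals} data.frame, one row per line.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(genomic_intervals())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 tab-separated fields",
                 which(nf < 3L)[1]), call. = FALSE)
  }
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  chrom <- get_col(1L, NA_character_)
  start_s <- get_col(2L, NA_character_)
  end_s <- get_col(3L, NA_character_)
  start <- suppressWarnings(as.numeric(start_s))
  end <- suppressWarnings(as.numeric(end_s))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: '%s' (non-integer coordinates or start >= end)",
                 bad[1], lines[bad[1]]), call. = FALSE)
  }
  name <- get_col(4L, ".")
  score_s <- get_col(5L, ".")
  score <- suppressWarnings(as.numeric(ifelse(score_s == ".", NA, score_s)))
  strand <- get_col(6L, NA_character_)
  missing_strand <- is.na(strand) | !strand %in% c("+", "-")
  if (any(missing_strand)) {
    snc_log("read_bed: %d record(s) without a valid strand field; defaulting to '+'",
            sum(missing_strand))
    strand[missing_strand] <- "+"
  }
  genomic_intervals(chrom, start, end, strand, name, score)
}

#' Write intervals as 6-column BED
#'
#' Always emits BED6; absent scores are written as \code{"."}, present scores
#' with fixed precision so that \code{read_bed(write_bed(x))} round-trips
#' losslessly at that precision.
#'
#' @param x a \code{genomic_intervals} data.frame.
#' @param path output path.
#' @param digits decimal digits for the score column.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path, digits = 6L) {
  score <- ifelse(is.na(x$score), ".",
                  formatC(x$score, format = "f", digits = digits))
  lines <- if (nrow(x) == 0L) character() else
    paste(x$chrom, format_coord(x$start), format_coord(x$end),
          x$name, score, x$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(v) formatC(v, format = "d")

#' Extend targets and merge strand-specific overlaps
#'
#' Grows every interval by \code{flank} bp on both sides (start clipped at 0;
#' the right end is clipped at the chromosome length only when
#' \code{chrom_sizes} is supplied), then merges intervals on the same strand
#' that overlap or abut. Opposite strands never merge. This is the region
#' preparation step used before scanning: targets extended by +/- 5000 bp and
#' merged per strand.
#'
#' @param targets a \code{genomic_intervals} data.frame.
#' @param flank non-negative extension in bp (default 5000).
#' @param chrom_sizes optional named numeric vector of chromosome lengths.
#' @return Merged \code{genomic_intervals}, sorted by (chrom, start).
#' @export
extend_and_merge <- function(targets, flank = 5000, chrom_sizes = NULL) {
  stopifnot(flank >= 0)
  if (nrow(targets) == 0L) return(targets)
  x <- targets
  x$start <- pmax(0, x$start - flank)
  x$end <- x$end + flank
  if (!is.null(chrom_sizes)) {
    cap <- unname(chrom_sizes[x$chrom])
    clip <- !is.na(cap) & x$end > cap
    if (any(clip)) {
      snc_log("extend_and_merge: clipped %d interval end(s) at chromosome length",
              sum(clip))
      x$end[clip] <- cap[clip]
    }
    x <- x[x$start < x$end, , drop = FALSE]
  }
  x <- x[order(x$chrom, x$strand, x$start, x$end), , drop = FALSE]
  key <- paste(x$chrom, x$strand)
  out <- list()
  for (k in unique(key)) {
    g <- x[key == k, , drop = FALSE]
    cur_s <- g$start[1]; cur_e <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] <= cur_e) {          # overlap or abut: merge
        cur_e <- max(cur_e, g$end[i])
      } else {
        out[[length(out) + 1L]] <- list(g$chrom[1], cur_s, cur_e, g$strand[1])
        cur_s <- g$start[i]; cur_e <- g$end[i]
      }
    }
    out[[length(out) + 1L]] <- list(g$chrom[1], cur_s, cur_e, g$strand[1])
  }
  m <- do.call(rbind.data.frame, out)
  names(m) <- c("chrom", "start", "end", "strand")
  sort_intervals(genomic_intervals(m$chrom, m$start, m$end, m$strand))
}

#' Tile a region with sliding windows
#'
#' Windows start at \code{region$start}, advancing by \code{step}, while
#' \code{start + width <= region$end}; the count therefore equals
#' \code{floor((len - width) / step) + 1} when \code{len >= width} and 0
#' otherwise. Windows inherit the region's strand.
#'
#' @param region a single-row \code{genomic_intervals} data.frame.
#' @param width window width in bp (default 100, the model input width).
#' @param step stride in bp (default 5 for genome-region scans; peak scans
#'   conventionally use 10).
#' @return \code{genomic_intervals} of windows (possibly empty).
#' @export
make_windows <- function(region, width = 100, step = 5) {
  stopifnot(width >= 1, step >= 1, nrow(region) == 1L)
  len <- region$end - region$start
  if (len < width) {
    snc_log("make_windows: region %s:%d-%d shorter than width %d; no windows",
            region$chrom, region$start, region$end, width)
    return(genomic_intervals())
  }
  n <- floor((len - width) / step) + 1
  starts <- region$start + step * (seq_len(n) - 1)
  genomic_intervals(rep(region$chrom, n), starts, starts + width,
                    strand = region$strand)
}

#' Overlap-based hit rule
#'
#' A prediction hits a target iff they share chromosome and strand and the
#' overlap covers at least \code{min_frac} of the denominator interval. The
#' default denominator is the prediction (scanning uses fixed-width windows,
#' making the rule scale-free); the boundary (exactly \code{min_frac}) counts
#' as a hit.
#'
#' @param prediction,target single-row \code{genomic_intervals}.
#' @param min_frac minimum overlap fraction in (0, 1]; default 0.5.
#' @param denominator \code{"prediction"} (default) or \code{"target"}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_hit <- function(prediction, target, min_frac = 0.5,
                   denominator = c("prediction", "target")) {
  denominator <- match.arg(denominator)
  stopifnot(min_frac > 0, min_frac <= 1)
  m <- hit_matrix(prediction, target, min_frac, denominator)
  as.vector(m)[1]
}

# Logical matrix: m[i, j] = TRUE iff prediction i hits target j.
hit_matrix <- function(predictions, targets, min_frac = 0.5,
                       denominator = "prediction") {
  np <- nrow(predictions); nt <- nrow(targets)
  m <- matrix(FALSE, np, nt)
  if (np == 0L || nt == 0L) return(m)
  for (j in seq_len(nt)) {
    same <- predictions$chrom == targets$chrom[j] &
      predictions$strand == targets$strand[j]
    ov <- pmin(predictions$end, targets$end[j]) -
      pmax(predictions$start, targets$start[j])
    denom <- if (denominator == "prediction") {
      predictions$end - predictions$start
    } else {
      rep(targets$end[j] - targets$start[j], np)
    }
    m[, j] <- same & ov > 0 & (ov / denom >= min_frac)
  }
  m
}

#' Center-expand intervals to a fixed width
#'
#' Grows (or shrinks) every interval to exactly \code{width} bp around its
#' center (odd remainder goes right), shifting back into bounds at
#' chromosome edges. Used to turn annotated loci into fixed-width training
#' windows so that training examples and scan windows share one geometry and
#' the zero-padding path never has to fire for them.
#'
#' @param x a \code{genomic_intervals} data.frame.
#' @param width target width in bp.
#' @param chrom_sizes optional named numeric vector of chromosome lengths.
#' @return \code{genomic_intervals} of uniform width.
#' @export
expand_to_width <- function(x, width = 100, chrom_sizes = NULL) {
  if (nrow(x) == 0L) return(x)
  center <- floor((x$start + x$end) / 2)
  start <- center - floor(width / 2)
  start <- pmax(0, start)
  if (!is.null(chrom_sizes)) {
    cap <- unname(chrom_sizes[x$chrom])
    over <- !is.na(cap) & start + width > cap
    start[over] <- pmax(0, cap[over] - width)
  }
  out <- x
  out$start <- start
  out$end <- start + width
  validate_intervals(out, "expand_to_width")
  out
}

# Single-linkage clustering of intervals by same-strand overlap (abutting
# intervals do not cluster). Returns an integer cluster id per row.
cluster_by_overlap <- function(x) {
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  ord <- order(x$chrom, x$strand, x$start, x$end)
  key <- paste(x$chrom[ord], x$strand[ord])
  s <- x$start[ord]
  e <- x$end[ord]
  new_key <- key != c("", key[-n])
  grp <- cumsum(new_key)
  # running max of end within each (chrom, strand) run, shifted by one
  cm <- stats::ave(e, grp, FUN = cummax)
  prev_end <- c(-Inf, cm[-n])
  boundary <- new_key | s >= prev_end
  cl <- integer(n)
  cl[ord] <- cumsum(boundary)
  cl
}

snc_log <- function(fmt, ...) {
  message(sprintf(paste0("[sncscan] ", fmt), ...))
}
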