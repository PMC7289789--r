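#' One-hot encode a DNA sequence
#'
#' Row i carries a single 1 in the column of base i under the fixed alphabet
#' order (A, C, G, T); ambiguous N bases encode as all-zero rows, so row sums
#' are 1 for unambiguous bases and 0 for N. Case-insensitive; U is accepted
#' as T.
#'
#' @param seq a single nucleotide string over \code{A,C,G,T,U,N}.
#' @return An L x 4 numeric matrix with columns \code{A,C,G,T}.
#' @export
one_hot_sequence <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch[ch == "U"] <- "T"
  idx <- match(ch, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    off <- which(is.na(idx))[1]
    stop(sprintf("one_hot_sequence: invalid character '%s' at offset %d",
                 ch[off], off - 1L), call. = FALSE)
  }
  m <- matrix(0, length(ch), 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  keep <- idx <= 4L
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' One-hot encode a dot-bracket structure string
#'
#' Purely positional: parentheses need not balance. Symbol order is
#' \code{(".", "(", ")")}; every row sums to exactly 1.
#'
#' @param dotbracket a single string over \code{.}, \code{(}, \code{)}.
#' @return An L x 3 numeric matrix.
#' @export
encode_structure <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  idx <- match(ch, c(".", "(", ")"))
  if (anyNA(idx)) {
    off <- which(is.na(idx))[1]
    stop(sprintf("encode_structure: invalid symbol '%s' at offset %d",
                 ch[off], off - 1L), call. = FALSE)
  }
  m <- matrix(0, length(ch), 3L, dimnames = list(NULL, c(".", "(", ")")))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a one-hot sequence block back to a string
#' @param m L x 4 one-hot matrix (columns A,C,G,T); all-zero rows decode to N.
#' @return nucleotide string.
#' @export
decode_sequence <- function(m) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(nrow(m)), function(i) {
    if (sum(m[i, ]) == 0) "N" else bases[which.max(m[i, ])]
  }, character(1)), collapse = "")
}

#' Reverse-complement a DNA string
#' @param seq nucleotide string(s) over \code{A,C,G,T,N} (case-insensitive).
#' @return reverse-complemented string(s), upper case.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTUNacgtun", "TGCAANTGCAAN", seq)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Conservation track container
#'
#' A per-chromosome dense vector of per-base scores (phyloP-style signed
#' reals), element i holding the score of 0-based position i - 1. Positions a
#' wiggle file does not cover are 0 (the phyloP neutral value).
#'
#' @param scores named list of numeric vectors, one per chromosome.
#' @return object of class \code{conservation_track}.
#' @export
conservation_track <- function(scores = list()) {
  stopifnot(is.list(scores))
  for (v in scores) stopifnot(is.numeric(v), all(is.finite(v)))
  structure(list(scores = scores), class = "conservation_track")
}

#' Extract per-base conservation for an interval
#'
#' Scores are returned in the orientation of the interval: for minus-strand
#' intervals the vector is reversed so that it aligns with the
#' reverse-complemented sequence. Positions absent from the track (or beyond
#' its stored range) yield 0.
#'
#' @param track a \code{conservation_track}.
#' @param interval single-row \code{genomic_intervals}.
#' @return numeric vector of length \code{end - start}.
#' @export
extract_conservation <- function(track, interval) {
  stopifnot(inherits(track, "conservation_track"), nrow(interval) == 1L)
  len <- interval$end - interval$start
  v <- numeric(len)
  chrom_scores <- track$scores[[interval$chrom]]
  if (!is.null(chrom_scores)) {
    pos <- seq.int(interval$start, interval$end - 1L)  # 0-based
    in_range <- pos + 1L <= length(chrom_scores) & pos >= 0L
    v[in_range] <- chrom_scores[pos[in_range] + 1L]
    v[is.na(v)] <- 0
  }
  if (interval$strand == "-") v <- rev(v)
  v
}

#' Read a wiggle conservation track
#'
#' Supports \code{fixedStep} and \code{variableStep} blocks with \code{step}/
#' \code{span} of 1 (per-base tracks). Wiggle positions are 1-based.
#'
#' @param path wig file path.
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   pre-allocate dense vectors.
#' @return a \code{conservation_track}.
#' @export
read_wig <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  scores <- list()
  if (!is.null(chrom_sizes)) {
    for (cn in names(chrom_sizes)) scores[[cn]] <- numeric(chrom_sizes[[cn]])
  }
  i <- 1L
  ensure <- function(chrom, upto) {
    cur <- scores[[chrom]]
    if (is.null(cur)) cur <- numeric(0)
    if (length(cur) < upto) cur <- c(cur, numeric(upto - length(cur)))
    scores[[chrom]] <<- cur
  }
  n <- length(lines)
  while (i <= n) {
    header <- lines[i]
    if (startsWith(header, "fixedStep")) {
      kv <- parse_wig_header(header)
      chrom <- kv[["chrom"]]; start <- as.integer(kv[["start"]])
      step <- as.integer(kv[["step"]] %||% "1")
      if (step != 1L) stop("read_wig: only step=1 supported", call. = FALSE)
      j <- i + 1L
      while (j <= n && !grepl("^(fixed|variable)Step", lines[j])) j <- j + 1L
      vals <- as.numeric(lines[(i + 1L):(j - 1L)])
      ensure(chrom, start + length(vals) - 1L)
      scores[[chrom]][seq.int(start, length.out = length(vals))] <- vals
      i <- j
    } else if (startsWith(header, "variableStep")) {
      kv <- parse_wig_header(header)
      chrom <- kv[["chrom"]]
      j <- i + 1L
      while (j <= n && !grepl("^(fixed|variable)Step", lines[j])) j <- j + 1L
      body <- lines[(i + 1L):(j - 1L)]
      parts <- strsplit(body, "[ \t]+")
      pos <- as.integer(vapply(parts, `[`, character(1), 1L))
      vals <- as.numeric(vapply(parts, `[`, character(1), 2L))
      ensure(chrom, max(pos))
      scores[[chrom]][pos] <- vals
      i <- j
    } else {
      stop("read_wig: unexpected line: ", header, call. = FALSE)
    }
  }
  conservation_track(scores)
}

parse_wig_header <- function(line) {
  toks <- strsplit(line, "[ \t]+")[[1]][-1]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2L),
                  vapply(kv, `[`, character(1), 1L))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a conservation track as fixedStep wiggle
#' @param track a \code{conservation_track}.
#' @param path output path.
#' @param digits decimal digits per value.
#' @return \code{path}, invisibly.
#' @export
write_wig <- function(track, path, digits = 4L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$scores)) {
    v <- track$scores[[chrom]]
    if (!length(v)) next
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
    writeLines(formatC(v, format = "f", digits = digits), con)
  }
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return named character vector, one upper-case sequence per chromosome.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return \code{path}, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = width)
  invisible(path)
}

# Strand-corrected genomic sequences for a set of intervals.
interval_sequences <- function(intervals, genome) {
  chrom_len <- nchar(genome)[intervals$chrom]
  if (anyNA(chrom_len)) {
    stop("unknown chromosome: ",
         intervals$chrom[which(is.na(chrom_len))[1]], call. = FALSE)
  }
  beyond <- intervals$end > chrom_len
  if (any(beyond)) {
    i <- which(beyond)[1]
    stop(sprintf("interval %s:%d-%d exceeds chromosome end (%d)",
                 intervals$chrom[i], intervals$start[i], intervals$end[i],
                 chrom_len[i]), call. = FALSE)
  }
  seqs <- substr(genome[intervals$chrom], intervals$start + 1L, intervals$end)
  minus <- intervals$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  unname(seqs)
}

#' Encode one genomic window into aligned feature blocks
#'
#' Produces the three feature blocks consumed by the model branches: one-hot
#' sequence (L x 4), one-hot dot-bracket structure (L x 3) and raw per-base
#' conservation (L x 1). Minus-strand intervals are reverse-complemented
#' before folding and encoding, and their conservation vector reversed to
#' match. Intervals shorter than \code{target_length} are symmetrically
#' zero-padded (structure padding is \code{"."}; odd remainder pads one more
#' on the right); longer intervals are center-cropped, the floor of the
#' excess going to the left crop.
#'
#' @param interval single-row \code{genomic_intervals}.
#' @param genome named character vector of chromosome sequences.
#' @param track \code{conservation_track} or \code{NULL} (conservation block
#'   all zero).
#' @param fold_backend \code{"nussinov"} or \code{"file"}.
#' @param structures precomputed structures for \code{fold_backend = "file"}.
#' @param target_length model input length L (default 100, the scan width).
#' @param label optional class label in \{0, 1\}.
#' @return an \code{encoded_window}: list with \code{interval},
#'   \code{seq_block}, \code{struct_block}, \code{cons_block}, \code{label}.
#' @export
encode_window <- function(interval, genome, track = NULL,
                          fold_backend = "nussinov", structures = NULL,
                          target_length = 100L, label = NA_integer_) {
  b <- encode_windows(interval, genome, track, fold_backend, structures,
                      target_length, labels = label)
  structure(list(interval = interval,
                 seq_block = b$S[1, , ],
                 struct_block = b$F[1, , ],
                 cons_block = matrix(b$C[1, , 1], ncol = 1),
                 label = b$labels[1]),
            class = "encoded_window")
}

#' Encode a batch of windows into stacked feature arrays
#'
#' Vectorized batch path used by training and scanning. Returns arrays
#' \code{S} (N x L x 4), \code{F} (N x L x 3), \code{C} (N x L x 1).
#'
#' @inheritParams encode_window
#' @param intervals \code{genomic_intervals} (N rows).
#' @param labels optional numeric vector of labels.
#' @return list with arrays \code{S}, \code{F}, \code{C}, plus
#'   \code{intervals} and \code{labels}.
#' @export
encode_windows <- function(intervals, genome, track = NULL,
                           fold_backend = "nussinov", structures = NULL,
                           target_length = 100L, labels = NULL) {
  n <- nrow(intervals)
  L <- as.integer(target_length)
  seqs <- interval_sequences(intervals, genome)
  ids <- window_ids(intervals)
  db <- fold_sequence(seqs, backend = fold_backend, structures = structures,
                      ids = ids)
  S <- array(0, c(n, L, 4L))
  Fb <- array(0, c(n, L, 3L))
  Fb[, , 1L] <- 1  # padding structure is "."
  C <- array(0, c(n, L, 1L))
  if (n > 0L && all(nchar(seqs) == L)) {
    # fast path for uniform-width scan windows: no padding or cropping
    win <- rep(seq_len(n), each = L)
    pos <- rep(seq_len(L), n)
    sch <- unlist(strsplit(toupper(seqs), ""), use.names = FALSE)
    sch[sch == "U"] <- "T"
    scode <- match(sch, c("A", "C", "G", "T", "N"))
    if (anyNA(scode)) {
      stop("encode_windows: invalid sequence character '",
           sch[which(is.na(scode))[1]], "'", call. = FALSE)
    }
    keep <- scode <= 4L
    S[cbind(win[keep], pos[keep], scode[keep])] <- 1
    fch <- unlist(strsplit(db, ""), use.names = FALSE)
    fcode <- match(fch, c(".", "(", ")"))
    if (anyNA(fcode)) {
      stop("encode_windows: invalid structure symbol '",
           fch[which(is.na(fcode))[1]], "'", call. = FALSE)
    }
    Fb[, , 1L] <- 0
    Fb[cbind(win, pos, fcode)] <- 1
    if (!is.null(track)) {
      for (cn in unique(intervals$chrom)) {
        rows <- which(intervals$chrom == cn)
        cs <- track$scores[[cn]]
        if (is.null(cs)) next
        pmat <- outer(intervals$start[rows], seq_len(L), `+`)  # 1-based
        vals <- ifelse(pmat >= 1 & pmat <= length(cs), cs[pmat], 0)
        vals[is.na(vals)] <- 0
        minus <- intervals$strand[rows] == "-"
        if (any(minus)) {
          vals[minus, ] <- vals[minus, rev(seq_len(L)), drop = FALSE]
        }
        C[rows, , 1L] <- vals
      }
    }
    return(list(S = S, F = Fb, C = C, intervals = intervals,
                labels = if (is.null(labels)) rep(NA_real_, n) else
                  rep_len(as.numeric(labels), n)))
  }
  for (i in seq_len(n)) {
    len <- nchar(seqs[i])
    if (len == L) {
      src <- seq_len(L); dst <- seq_len(L)
    } else if (len < L) {
      pad_left <- (L - len) %/% 2           # odd remainder pads right
      src <- seq_len(len); dst <- pad_left + seq_len(len)
    } else {
      crop_left <- (len - L) %/% 2
      src <- crop_left + seq_len(L); dst <- seq_len(L)
    }
    sm <- one_hot_sequence(substr(seqs[i], src[1], src[length(src)]))
    fm <- encode_structure(substr(db[i], src[1], src[length(src)]))
    S[i, dst, ] <- sm
    Fb[i, dst, ] <- fm
    if (!is.null(track)) {
      cv <- extract_conservation(track, intervals[i, , drop = FALSE])
      C[i, dst, 1L] <- cv[src]
    }
  }
  list(S = S, F = Fb, C = C, intervals = intervals,
       labels = if (is.null(labels)) rep(NA_real_, n) else
         rep_len(as.numeric(labels), n))
}

window_ids <- function(intervals) {
  paste0(intervals$chrom, ":", format_coord(intervals$start), "-",
         format_coord(intervals$end), "(", intervals$strand, ")")
}
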