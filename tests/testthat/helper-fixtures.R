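# Shared fixtures: tiny hand-built worlds and independent oracles.

gi <- function(chrom, start, end, strand = "+", name = ".", score = NA_real_) {
  genomic_intervals(chrom, start, end, strand, name, score)
}

# Per-base set-intersection oracle for the fractional-overlap hit rule.
oracle_is_hit <- function(pred, target, min_frac = 0.5,
                          denominator = "prediction") {
  if (pred$chrom != target$chrom || pred$strand != target$strand) return(FALSE)
  p_bases <- seq.int(pred$start, pred$end - 1L)
  t_bases <- seq.int(target$start, target$end - 1L)
  ov <- length(intersect(p_bases, t_bases))
  denom <- if (denominator == "prediction") length(p_bases) else length(t_bases)
  ov / denom >= min_frac
}

# Enumeration oracle for window tiling.
oracle_count_windows <- function(len, width, step) {
  n <- 0L
  s <- 0L
  while (s + width <= len) {
    n <- n + 1L
    s <- s + step
  }
  n
}

# Brute-force maximum number of nested base pairs (loop >= min_loop,
# AU/UA/GC/CG/GU/UG, N unpairable), memoized per interval.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  n <- length(ch)
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pairable(ch[i], ch[k])) {
        inner <- if (k - i >= 2L) rec(i + 1L, k - 1L) else 0L
        right <- if (k < j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + right)
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < min_loop + 2L) return(0L)
  rec(1L, n)
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A tiny deterministic two-chromosome world for interval/encoding tests.
tiny_genome <- function() {
  c(chrA = paste(rep("ACGT", 100), collapse = ""),   # 400 bp
    chrB = paste(rep("GGCC", 50), collapse = ""))    # 200 bp
}

tiny_track <- function() {
  conservation_track(list(chrA = seq(0, 3.99, by = 0.01),
                          chrB = rep(c(1, -1), 100)))
}

# Desk-scale model configuration used across slow tests (mirrors the
# unweighted "-U" variant; sized to train in seconds).
desk_config <- function(branches = c("S", "F", "C"), seed = 1L,
                        epochs = 30L) {
  model_config(branches = branches, filters = c(8L, 16L, 32L),
               dense_units = 32L, class_weighting = FALSE, epochs = epochs,
               patience = 5L, batch_size = 32L, seed = seed)
}

# Brute-force recount oracle for consensus support: windows x models flag
# table -> per-cluster number of models contributing >= 1 flagged window.
oracle_support <- function(windows, flags) {
  flagged <- which(rowSums(flags) > 0)   # clusters form over flagged windows
  if (!length(flagged)) return(list())
  cl <- sncscan:::cluster_by_overlap(windows[flagged, , drop = FALSE])
  out <- list()
  for (g in sort(unique(cl))) {
    idx <- flagged[cl == g]
    support <- 0L
    for (m in seq_len(ncol(flags))) {
      if (any(flags[idx, m])) support <- support + 1L
    }
    out[[as.character(g)]] <- list(rows = idx, support = support)
  }
  out
}
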