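#' Specification of a synthetic benchmark genome
#'
#' Describes a fully synthetic world with the statistical structure the
#' classifier assumes: random background sequence at a given GC content,
#' planted hairpin loci with elevated per-base conservation, and two decoy
#' classes that each carry only part of the positive signal so that
#' single-branch ablations have predictable winners and losers:
#' \itemize{
#'   \item \code{sequence_only}: the full positive-like sequence (boxes +
#'     hairpin) but background-level conservation;
#'   \item \code{conserved_only}: elevated conservation over a random
#'     (non-hairpin) sequence.
#' }
#'
#' Positives are not bare hairpins: each locus is
#' \code{box5 + arm + loop + revcomp(arm) + box3}, with fixed flanking boxes
#' and a fixed 4-nt motif opening the loop. A bare hairpin with
#' strand-symmetric conservation is exactly self-complementary, so the
#' reverse-strand mirror of every positive would be indistinguishable from a
#' positive and scanning precision would be capped near 0.5 by construction.
#' The boxes mimic the strand-asymmetric sequence elements of real loci
#' (C/D boxes, mature-arm sequence) and give the sequence branch a learnable
#' orientation signal.
#'
#' Conservation is Gaussian per base (phyloP scores are signed reals): mean
#' \code{cons_mean_pos} inside positives and \code{conserved_only} decoys,
#' \code{cons_mean_bg} elsewhere, common sd \code{cons_sd}. The defaults
#' (+2 vs 0, sd 1) emulate a clearly conserved element over a neutral
#' background.
#'
#' @param n_chroms number of chromosomes (>= 3 for a benchmark suite).
#' @param chrom_length chromosome length in bp.
#' @param n_positives total planted positive loci (split evenly over
#'   chromosomes).
#' @param stem_len hairpin arm length in nt.
#' @param loop_len hairpin loop length in nt (>= 4: a fixed 4-nt motif opens
#'   the loop).
#' @param cons_mean_pos,cons_mean_bg,cons_sd conservation model parameters.
#' @param decoy_classes subset of \code{c("sequence_only", "conserved_only")}.
#' @param n_decoys_per_class decoys planted per class.
#' @param gc_background background GC fraction in (0, 1).
#' @param box5,box3,loop_motif fixed strand-orienting motifs.
#' @param arm_motif fixed prefix of the 5' hairpin arm, the analogue of a
#'   conserved mature-arm sequence shared by all loci of the class; must be
#'   no longer than \code{stem_len}.
#' @param seed RNG seed; the whole world is deterministic per seed.
#' @return a \code{synthetic_genome_spec}.
#' @export
synthetic_genome_spec <- function(n_chroms = 3L, chrom_length = 50000L,
                                  n_positives = 60L, stem_len = 24L,
                                  loop_len = 8L, cons_mean_pos = 2,
                                  cons_mean_bg = 0, cons_sd = 1,
                                  decoy_classes = c("sequence_only",
                                                    "conserved_only"),
                                  n_decoys_per_class = 20L,
                                  gc_background = 0.42,
                                  box5 = "ATGATGGC", box3 = "CTGACTGA",
                                  loop_motif = "GTGA",
                                  arm_motif = "TGAGGTAGTAGG", seed = 1L) {
  stopifnot(n_chroms >= 1L, chrom_length >= 1000L, n_positives >= 1L,
            stem_len >= 4L, loop_len >= nchar(loop_motif) + 0L,
            loop_len >= 3L, gc_background > 0, gc_background < 1,
            cons_sd > 0, nchar(arm_motif) <= stem_len)
  if (2L * stem_len + loop_len > 100L) {
    stop("synthetic_genome_spec: 2*stem_len + loop_len must be <= 100",
         call. = FALSE)
  }
  decoy_classes <- match.arg(decoy_classes,
                             c("sequence_only", "conserved_only"),
                             several.ok = TRUE)
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_positives = as.integer(n_positives),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 cons_mean_pos = cons_mean_pos, cons_mean_bg = cons_mean_bg,
                 cons_sd = cons_sd, decoy_classes = decoy_classes,
                 n_decoys_per_class = as.integer(n_decoys_per_class),
                 gc_background = gc_background, box5 = toupper(box5),
                 box3 = toupper(box3), loop_motif = toupper(loop_motif),
                 arm_motif = toupper(arm_motif),
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Plant a hairpin sequence
#'
#' \code{arm + loop + revcomp(arm)}: every arm base has a Watson-Crick
#' partner, so a base-pair-maximizing folder recovers at least
#' \code{stem_len} pairs.
#'
#' @param stem_len arm length (>= 4).
#' @param loop_len loop length (>= 3).
#' @param arm,loop optional explicit arm/loop sequences (random otherwise;
#'   uses the current RNG state).
#' @return nucleotide string of length \code{2*stem_len + loop_len}.
#' @export
plant_hairpin <- function(stem_len, loop_len, arm = NULL, loop = NULL) {
  if (stem_len < 4L) stop("plant_hairpin: stem_len must be >= 4", call. = FALSE)
  if (loop_len < 3L) stop("plant_hairpin: loop_len must be >= 3", call. = FALSE)
  if (is.null(arm)) arm <- random_dna(stem_len)
  if (is.null(loop)) loop <- random_dna(loop_len)
  stopifnot(nchar(arm) == stem_len, nchar(loop) == loop_len)
  paste0(arm, loop, revcomp(arm))
}

positive_locus_length <- function(spec) {
  2L * spec$stem_len + spec$loop_len + nchar(spec$box5) + nchar(spec$box3)
}

# One canonical positive-locus sequence: boxes + hairpin whose 5' arm opens
# with the fixed mature-arm motif and whose loop opens with the loop motif.
positive_locus_seq <- function(spec) {
  loop <- paste0(spec$loop_motif,
                 random_dna(spec$loop_len - nchar(spec$loop_motif)))
  arm <- paste0(spec$arm_motif,
                random_dna(spec$stem_len - nchar(spec$arm_motif)))
  paste0(spec$box5,
         plant_hairpin(spec$stem_len, spec$loop_len, arm = arm, loop = loop),
         spec$box3)
}

#' Simulate the synthetic benchmark genome
#'
#' Draws i.i.d. background bases at the spec's GC content, implants positive
#' and decoy loci at non-overlapping positions (>= 100 bp apart, away from
#' chromosome edges) on random strands, and draws per-base Gaussian
#' conservation. All outputs are mutually consistent and deterministic per
#' seed.
#'
#' @param spec a \code{synthetic_genome_spec}.
#' @param dir optional directory; when given, writes \code{genome.fa},
#'   \code{conservation.wig}, \code{positives.bed}, \code{decoys.bed} and
#'   \code{spec.json} there.
#' @return list with \code{genome} (named character), \code{track}
#'   (\code{conservation_track}), \code{positives}, \code{decoys}
#'   (\code{genomic_intervals}; decoy class in \code{name}), \code{spec},
#'   and \code{files} when \code{dir} was given.
#' @export
simulate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  pos_len <- positive_locus_length(spec)
  n_decoys <- length(spec$decoy_classes) * spec$n_decoys_per_class
  per_chrom_pos <- split_evenly(spec$n_positives, spec$n_chroms)
  per_chrom_dec <- split_evenly(n_decoys, spec$n_chroms)
  margin <- 200L; spacing <- 100L
  need <- (max(per_chrom_pos) + max(per_chrom_dec)) * (pos_len + spacing) +
    2L * margin
  if (need > spec$chrom_length) {
    stop("simulate_genome: loci do not fit in chrom_length ",
         spec$chrom_length, " (need ~", need, " bp)", call. = FALSE)
  }
  genome <- character(0)
  track_scores <- list()
  pos_rows <- list(); dec_rows <- list()
  decoy_class_pool <- sample(rep(spec$decoy_classes,
                                 each = spec$n_decoys_per_class))
  dec_taken <- 0L
  for (ci in seq_along(chroms)) {
    seq_chr <- random_dna(spec$chrom_length, spec$gc_background)
    np <- per_chrom_pos[ci]; nd <- per_chrom_dec[ci]
    n_loci <- np + nd
    starts <- place_loci(spec$chrom_length, n_loci, pos_len, spacing, margin)
    strands <- sample(c("+", "-"), n_loci, replace = TRUE)
    roles <- sample(c(rep("positive", np),
                      decoy_class_pool[dec_taken + seq_len(nd)]))
    dec_taken <- dec_taken + nd
    cons <- stats::rnorm(spec$chrom_length, spec$cons_mean_bg, spec$cons_sd)
    for (k in seq_len(n_loci)) {
      role <- roles[k]
      locus_seq <- switch(role,
        positive = positive_locus_seq(spec),
        sequence_only = positive_locus_seq(spec),
        conserved_only = random_dna(pos_len, spec$gc_background))
      if (strands[k] == "-") locus_seq <- revcomp(locus_seq)
      span <- starts[k] + seq_len(pos_len)   # 1-based positions
      substr(seq_chr, span[1], span[pos_len]) <- locus_seq
      if (role %in% c("positive", "conserved_only")) {
        cons[span] <- stats::rnorm(pos_len, spec$cons_mean_pos, spec$cons_sd)
      }
      row <- data.frame(chrom = chroms[ci], start = starts[k],
                        end = starts[k] + pos_len,
                        name = if (role == "positive")
                          sprintf("pos_%s_%d", chroms[ci], k) else
                          sprintf("%s_%s_%d", role, chroms[ci], k),
                        score = NA_real_, strand = strands[k],
                        stringsAsFactors = FALSE)
      if (role == "positive") pos_rows[[length(pos_rows) + 1L]] <- row
      else dec_rows[[length(dec_rows) + 1L]] <- row
    }
    genome[chroms[ci]] <- seq_chr
    track_scores[[chroms[ci]]] <- cons
  }
  positives <- sort_intervals(as_intervals(do.call(rbind, pos_rows)))
  decoys <- if (length(dec_rows)) {
    sort_intervals(as_intervals(do.call(rbind, dec_rows)))
  } else genomic_intervals()
  sim <- list(genome = genome, track = conservation_track(track_scores),
              positives = positives, decoys = decoys, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(genome = file.path(dir, "genome.fa"),
                  track = file.path(dir, "conservation.wig"),
                  positives = file.path(dir, "positives.bed"),
                  decoys = file.path(dir, "decoys.bed"),
                  spec = file.path(dir, "spec.json"))
    write_genome(sim$genome, files$genome)
    write_wig(sim$track, files$track)
    write_bed(sim$positives, files$positives)
    write_bed(sim$decoys, files$decoys)
    jsonlite::write_json(unclass(spec), files$spec, auto_unbox = TRUE,
                         digits = NA)
    sim$files <- files
  }
  sim
}

split_evenly <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0L) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

# Non-overlapping 0-based locus starts with pairwise gap >= spacing.
place_loci <- function(chrom_length, n, locus_len, spacing, margin) {
  if (n == 0L) return(integer(0))
  slot <- locus_len + spacing
  usable <- chrom_length - 2L * margin - locus_len
  free <- usable - (n - 1L) * slot
  stopifnot(free >= 0L)
  offsets <- sort(sample.int(free + 1L, n, replace = TRUE)) - 1L
  starts <- margin + offsets + (seq_len(n) - 1L) * slot
  starts
}

#' Assemble the chromosome-holdout benchmark suite
#'
#' Reserves the last chromosome as the left-out evaluation set (its loci are
#' never seen by any training stage), assigns the second-to-last chromosome's
#' positives as the per-model test split, and the remaining chromosomes as
#' train (with a random 15\% of training positives flagged as validation for
#' early stopping). Candidate negative regions are everything at least 100 bp
#' away from any planted locus on the training/test chromosomes.
#'
#' @param sim output of \code{\link{simulate_genome}} (or a
#'   \code{synthetic_genome_spec}, which is simulated first).
#' @param val_fraction fraction of training positives held out as validation.
#' @param train_width training-window width: positives are center-expanded
#'   to this width (the scan-window geometry) so training examples and scan
#'   windows match; the left-out targets keep their true locus coordinates.
#' @return list with \code{positives} (train/test chroms, with a
#'   \code{split} column), \code{candidate_regions}, \code{scan_regions}
#'   (training/test chromosomes, one interval per strand),
#'   \code{left_out_targets}, \code{left_out_chrom}, \code{split_map}
#'   (chromosome -> role) and \code{sim}.
#' @export
benchmark_suite <- function(sim, val_fraction = 0.15, train_width = 100L) {
  if (inherits(sim, "synthetic_genome_spec")) sim <- simulate_genome(sim)
  spec <- sim$spec
  if (spec$n_chroms < 3L) {
    stop("benchmark_suite: need at least 3 chromosomes", call. = FALSE)
  }
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  left_out <- chroms[spec$n_chroms]
  test_chrom <- chroms[spec$n_chroms - 1L]
  train_chroms <- chroms[seq_len(spec$n_chroms - 2L)]
  positives <- sim$positives[sim$positives$chrom != left_out, , drop = FALSE]
  positives <- expand_to_width(positives, train_width, nchar(sim$genome))
  split <- ifelse(positives$chrom == test_chrom, "test", "train")
  set.seed(spec$seed + 7919L)
  train_idx <- which(split == "train")
  n_val <- max(1L, round(val_fraction * length(train_idx)))
  split[sample(train_idx, n_val)] <- "validation"
  positives$split <- split
  loci <- rbind(sim$positives[, 1:6], sim$decoys[, 1:6])
  candidate_regions <- candidate_background(sim$genome, loci,
                                            setdiff(chroms, left_out))
  scan_chroms <- setdiff(chroms, left_out)
  scan_regions <- genomic_intervals(
    rep(scan_chroms, each = 2L),
    0, rep(nchar(sim$genome[scan_chroms]), each = 2L),
    strand = rep(c("+", "-"), length(scan_chroms)))
  left_out_targets <- sim$positives[sim$positives$chrom == left_out, ,
                                    drop = FALSE]
  rownames(positives) <- rownames(left_out_targets) <- NULL
  list(positives = positives, candidate_regions = candidate_regions,
       scan_regions = scan_regions, left_out_targets = left_out_targets,
       left_out_chrom = left_out,
       split_map = stats::setNames(
         c(rep("train", length(train_chroms)), "test", "left_out"),
         c(train_chroms, test_chrom, left_out)),
       sim = sim)
}

# Background regions >= `gap` bp away from every planted locus, both strands.
candidate_background <- function(genome, loci, chroms, gap = 100L) {
  rows <- list()
  for (cn in chroms) {
    len <- nchar(genome[[cn]])
    l <- loci[loci$chrom == cn, , drop = FALSE]
    blocked_start <- pmax(0, l$start - gap)
    blocked_end <- pmin(len, l$end + gap)
    ord <- order(blocked_start)
    cur <- 0
    free <- list()
    for (i in ord) {
      if (blocked_start[i] > cur) {
        free[[length(free) + 1L]] <- c(cur, blocked_start[i])
      }
      cur <- max(cur, blocked_end[i])
    }
    if (cur < len) free[[length(free) + 1L]] <- c(cur, len)
    for (f in free) {
      if (f[2] - f[1] < 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, start = f[1], end = f[2], name = ".",
        score = NA_real_, strand = c("+", "-"), stringsAsFactors = FALSE)
    }
  }
  sort_intervals(as_intervals(do.call(rbind, rows)))
}
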