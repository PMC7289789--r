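#' Sample random length-matched negatives
#'
#' For each positive, draws \code{ratio} negative intervals of identical
#' length uniformly from the candidate background regions, rejecting any
#' same-strand overlap with a positive or a previously drawn negative.
#' Deterministic per seed.
#'
#' @param positives \code{genomic_intervals}.
#' @param candidate_regions \code{genomic_intervals} of allowed background
#'   (strand-annotated; a negative inherits the strand of the candidate
#'   region it lands in).
#' @param ratio negatives per positive (default 4: the 1:4
#'   positive-to-negative ratio).
#' @param seed RNG seed.
#' @param max_tries rejection-sampling attempts per negative.
#' @return \code{genomic_intervals} of \code{ratio * nrow(positives)}
#'   negatives.
#' @export
sample_random_negatives <- function(positives, candidate_regions, ratio = 4L,
                                    seed = 1L, max_tries = 1000L) {
  stopifnot(nrow(positives) >= 1L, ratio >= 1L)
  cand_len <- interval_width(candidate_regions)
  if (sum(cand_len) < ratio * sum(interval_width(positives))) {
    stop("sample_random_negatives: candidate regions too small for ",
         ratio, "x the positive length", call. = FALSE)
  }
  set.seed(seed)
  taken <- positives[, c("chrom", "start", "end", "strand")]
  out <- list()
  shortfall <- 0L
  for (i in seq_len(nrow(positives))) {
    len <- positives$end[i] - positives$start[i]
    ok_regions <- which(cand_len >= len)
    if (!length(ok_regions)) {
      stop("sample_random_negatives: no candidate region can host a ",
           len, "-bp negative", call. = FALSE)
    }
    for (r in seq_len(ratio)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ri <- sample(ok_regions, 1L,
                     prob = cand_len[ok_regions] - len + 1)
        s <- candidate_regions$start[ri] +
          sample.int(cand_len[ri] - len + 1L, 1L) - 1L
        e <- s + len
        chrom <- candidate_regions$chrom[ri]
        strand <- candidate_regions$strand[ri]
        clash <- taken$chrom == chrom & taken$strand == strand &
          taken$start < e & s < taken$end
        if (!any(clash)) {
          row <- data.frame(chrom = chrom, start = s, end = e,
                            name = sprintf("neg_%d_%d", i, r),
                            score = NA_real_, strand = strand,
                            stringsAsFactors = FALSE)
          out[[length(out) + 1L]] <- row
          taken <- rbind(taken, row[, c("chrom", "start", "end", "strand")])
          placed <- TRUE
          break
        }
      }
      if (!placed) shortfall <- shortfall + 1L
    }
  }
  if (shortfall > 0L) {
    stop("sample_random_negatives: could not place ", shortfall,
         " negative(s) after ", max_tries, " attempts each", call. = FALSE)
  }
  as_intervals(do.call(rbind, out))
}

# Encode a TrainingRun (positives + negatives with split roles) into the
# train/validation/test batches consumed by train_model.
encode_training_run <- function(run, genome, track, fold_backend = "nussinov",
                                structures = NULL, input_length = 100L) {
  enc_set <- function(x, labels) {
    if (nrow(x) == 0L) return(NULL)
    encode_windows(x, genome, track, fold_backend, structures,
                   target_length = input_length, labels = labels)
  }
  sets <- list()
  for (role in c("train", "validation", "test")) {
    p <- run$positives[run$positives$split == role, , drop = FALSE]
    n <- run$negatives[run$negatives$split == role, , drop = FALSE]
    if (nrow(p) + nrow(n) == 0L) { sets[role] <- list(NULL); next }
    both <- rbind(p[, 1:6], n[, 1:6])
    sets[[role]] <- enc_set(both, c(rep(1, nrow(p)), rep(0, nrow(n))))
  }
  sets
}

# Replicate positive training windows at fixed offsets so the model learns
# positional tolerance of at least the scan step: trained only on perfectly
# centered loci while hard negatives sit at arbitrary offsets, a model can
# learn an exact positional template and score a locus 0 five bases away.
# Copies inherit their parent's split role (no leakage across splits).
augment_positives <- function(positives, offsets = c(-7L, 0L, 7L),
                              chrom_sizes = NULL) {
  if (length(offsets) == 0L) return(positives)
  out <- do.call(rbind, lapply(seq_along(offsets), function(k) {
    p <- positives
    p$start <- p$start + offsets[k]
    p$end <- p$end + offsets[k]
    p$name <- paste0(p$name, "_o", offsets[k])
    p
  }))
  out$start <- pmax(0, out$start)
  if (!is.null(chrom_sizes)) {
    cap <- unname(chrom_sizes[out$chrom])
    over <- !is.na(cap) & out$end > cap
    out$start[over] <- out$start[over] - (out$end[over] - cap[over])
    out$end[over] <- cap[over]
  }
  out$end <- out$start + (positives$end - positives$start)
  class(out) <- class(positives)
  rownames(out) <- NULL
  out
}

# Assign split roles to negatives by chromosome, mirroring the positives'
# chromosome-level assignment (test chromosomes stay test-only).
assign_negative_split <- function(negatives, split_map) {
  role <- unname(split_map[negatives$chrom])
  role[is.na(role)] <- "train"
  role[role == "left_out"] <- "test"
  negatives$split <- role
  negatives
}

#' Train an ensemble with independently resampled backgrounds
#'
#' Trains \code{n_models} classifiers on the same positive set, each against
#' a freshly sampled random negative set (seed + i), and records each
#' model's test-set F1 at threshold 0.5. This is round 1 of the iterative
#' background-selection scheme (the full-scale protocol uses 50 models).
#'
#' @param positives \code{genomic_intervals} with a \code{split} column
#'   (train/validation/test).
#' @param candidate_regions background regions for negative sampling.
#' @param genome,track,fold_backend,structures encoding inputs.
#' @param split_map named chromosome -> role map (for negatives).
#' @param n_models ensemble size (default 50).
#' @param config \code{model_config}.
#' @param ratio negatives per positive.
#' @param seed base seed; model i uses seed + i.
#' @param augment_offsets positional offsets (bp) at which each positive
#'   training window is replicated, teaching the scan-step positional
#'   tolerance; negatives are sampled 1:ratio against the original,
#'   unaugmented positives.
#' @return list of members, each \code{list(model, negatives, metrics)}.
#' @export
train_ensemble <- function(positives, candidate_regions, genome, track,
                           split_map, n_models = 50L,
                           config = model_config(), ratio = 4L, seed = 1L,
                           fold_backend = "nussinov", structures = NULL,
                           augment_offsets = c(-7L, 0L, 7L)) {
  if (n_models < 1L) stop("train_ensemble: n_models must be >= 1", call. = FALSE)
  aug_positives <- augment_positives(positives, augment_offsets,
                                     nchar(genome))
  members <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    negs <- sample_random_negatives(positives, candidate_regions, ratio,
                                    seed = seed + i)
    negs <- assign_negative_split(negs, split_map)
    run <- list(positives = aug_positives, negatives = negs, seed = seed + i)
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    sets <- encode_training_run(run, genome, track, fold_backend, structures,
                                cfg$input_length)
    model <- build_model(cfg)
    model <- train_model(model, sets$train, validation = sets$validation,
                         config = cfg)
    metrics <- if (!is.null(sets$test)) {
      sc <- predict_scores(model, sets$test)
      cm <- confusion_prelabelled(sc, sets$test$labels, 0.5)
      prf(cm[["TP"]], cm[["FP"]], cm[["FN"]])
    } else c(precision = NA_real_, sensitivity = NA_real_, F1 = NA_real_)
    members[[i]] <- list(model = model, negatives = negs, run = run,
                         metrics = metrics, seed = seed + i)
  }
  members
}

#' Consensus false positives ("hard cases") from an ensemble
#'
#' Every model scans the scan regions; a window is a false positive for a
#' model when its score is at least \code{score_threshold} and it hits no
#' true target under the 50\%-overlap rule. False-positive windows pooled
#' across models are clustered by same-strand overlap (single linkage);
#' a cluster's support is the number of distinct models contributing at
#' least one window, and clusters supported by at least
#' \code{support_threshold} models (the full-scale protocol: at least 25 of
#' 50) are emitted as one representative interval each — the cluster's
#' highest-scoring window, ties to the leftmost, with support recorded.
#'
#' Windows are encoded once and scored by every model.
#'
#' @param members ensemble from \code{\link{train_ensemble}} (or a list of
#'   trained models).
#' @param scan_regions regions to scan.
#' @param targets true target intervals.
#' @param genome,track,fold_backend,structures encoding inputs.
#' @param score_threshold score at/above which a window counts as predicted
#'   positive (default 0.5).
#' @param support_threshold minimum number of supporting models (default 25).
#' @param width,step scan geometry.
#' @param min_frac hit-rule overlap fraction.
#' @return \code{genomic_intervals} of hard negatives with a \code{support}
#'   column; \code{score} holds support scaled to [0, 1] by the ensemble
#'   size.
#' @export
collect_hard_negatives <- function(members, scan_regions, targets, genome,
                                   track = NULL, fold_backend = "nussinov",
                                   structures = NULL, score_threshold = 0.5,
                                   support_threshold = 25L, width = 100,
                                   step = 5, min_frac = 0.5) {
  models <- lapply(members, function(m) if (inherits(m, "snc_model")) m else m$model)
  if (support_threshold > length(models)) {
    stop("collect_hard_negatives: support_threshold exceeds ensemble size",
         call. = FALSE)
  }
  windows <- scan_windows(scan_regions, width, step,
                          strands = unique(scan_regions$strand))
  if (nrow(windows) == 0L) return(empty_hard_negatives())
  cfg <- models[[1]]$config
  enc <- encode_windows(windows, genome, track, fold_backend, structures,
                        target_length = cfg$input_length)
  hits <- rowSums(hit_matrix(windows, targets, min_frac)) > 0
  flags <- matrix(FALSE, nrow(windows), length(models))
  scores <- matrix(NA_real_, nrow(windows), length(models))
  for (j in seq_along(models)) {
    sc <- predict_scores(models[[j]], enc)
    scores[, j] <- sc
    flags[, j] <- sc >= score_threshold & !hits
  }
  consensus_hard_negatives(windows, flags, scores, support_threshold)
}

# Pure consensus step, testable against a brute-force recount: `flags` is a
# windows x models logical matrix of per-model false-positive calls.
consensus_hard_negatives <- function(windows, flags, scores,
                                     support_threshold) {
  flagged <- which(rowSums(flags) > 0L)
  if (!length(flagged)) return(empty_hard_negatives())
  sub <- windows[flagged, , drop = FALSE]
  cl <- cluster_by_overlap(sub)
  out <- list()
  for (g in split(seq_along(flagged), cl)) {
    support <- sum(colSums(flags[flagged[g], , drop = FALSE]) > 0L)
    if (support < support_threshold) next
    wscore <- apply(scores[flagged[g], , drop = FALSE], 1L, max, na.rm = TRUE)
    best <- g[wscore == max(wscore)]
    best <- best[which.min(sub$start[best])]
    rep_row <- sub[best, , drop = FALSE]
    rep_row$support <- support
    rep_row$score <- support / ncol(flags)
    rep_row$name <- "hard_negative"
    out[[length(out) + 1L]] <- rep_row
  }
  if (!length(out)) return(empty_hard_negatives())
  res <- do.call(rbind, out)
  res <- sort_intervals(res)
  class(res) <- c("genomic_intervals", "data.frame")
  res
}

empty_hard_negatives <- function() {
  x <- genomic_intervals()
  x$support <- integer(0)
  x
}

#' Pick the best ensemble member
#'
#' Arg-max by test-set F1 at score 0.5 (ties break to the lower model
#' index).
#'
#' @param members ensemble from \code{\link{train_ensemble}}.
#' @param metric \code{"F1"} (default) or \code{"precision"}.
#' @return index of the best member.
#' @export
select_best_model <- function(members, metric = "F1") {
  vals <- vapply(members, function(m) unname(m$metrics[[metric]]), numeric(1))
  if (all(is.na(vals))) return(1L)
  which.max(vals)             # ties -> first (lowest index)
}

#' Iterative background-selection training
#'
#' The full two-step scheme: (1) train an ensemble of models on the same
#' positives with independently resampled random negatives; (2) scan large
#' regions with every member, extract consensus false positives supported by
#' at least \code{support_threshold} models, append them to the best
#' member's negative pool, and retrain that member's configuration from
#' scratch (same seed) on the enhanced set. One iteration, as in the
#' published protocol; with an empty hard-negative set the final model is
#' retrained on the unchanged best set and a warning is raised.
#'
#' @inheritParams train_ensemble
#' @inheritParams collect_hard_negatives
#' @param members optional precomputed ensemble (from
#'   \code{\link{train_ensemble}}) to reuse instead of training round 1
#'   again.
#' @return list with \code{model} (final), \code{ensemble}, \code{best},
#'   \code{hard_negatives}, \code{enhanced_negatives} and \code{provenance}
#'   (machine-readable run record).
#' @export
iterate_train <- function(positives, candidate_regions, scan_regions,
                          targets, genome, track, split_map,
                          n_models = 50L, config = model_config(),
                          ratio = 4L, seed = 1L, score_threshold = 0.5,
                          support_threshold = 25L, width = 100, step = 5,
                          fold_backend = "nussinov", structures = NULL,
                          members = NULL, augment_offsets = c(-7L, 0L, 7L)) {
  if (is.null(members)) {
    members <- train_ensemble(positives, candidate_regions, genome, track,
                              split_map, n_models, config, ratio, seed,
                              fold_backend, structures, augment_offsets)
  }
  hard <- collect_hard_negatives(members, scan_regions, targets, genome,
                                 track, fold_backend, structures,
                                 score_threshold, support_threshold,
                                 width, step)
  best_idx <- select_best_model(members)
  best <- members[[best_idx]]
  if (nrow(hard) == 0L) {
    warning("iterate_train: empty hard-negative set; retraining on the ",
            "unchanged best training set", call. = FALSE)
    enhanced <- best$negatives
  } else {
    hard_as_neg <- hard[, c("chrom", "start", "end", "name", "score",
                            "strand")]
    hard_as_neg$score <- NA_real_
    hard_as_neg <- as_intervals(hard_as_neg)
    # mined hard cases are training material regardless of which scanned
    # chromosome produced them (only the left-out chromosomes are excluded
    # from the whole process); the test split keeps its original
    # composition. A held-out fifth of the hard cases goes to the
    # validation split so that early stopping sees the enhanced
    # distribution — otherwise validation loss is blind to whether the
    # retrained model has learned to reject the hard cases at all.
    set.seed(best$seed + 104729L)
    hard_as_neg$split <- "train"
    n_val <- floor(nrow(hard_as_neg) / 5)
    if (n_val > 0L) {
      hard_as_neg$split[sample.int(nrow(hard_as_neg), n_val)] <- "validation"
    }
    enhanced <- rbind(best$negatives, hard_as_neg)
    class(enhanced) <- c("genomic_intervals", "data.frame")
  }
  cfg <- config
  cfg$seed <- as.integer(best$seed)
  run <- list(positives = augment_positives(positives, augment_offsets,
                                            nchar(genome)),
              negatives = enhanced, seed = best$seed)
  sets <- encode_training_run(run, genome, track, fold_backend, structures,
                              cfg$input_length)
  final <- build_model(cfg)
  final <- train_model(final, sets$train, validation = sets$validation,
                       config = cfg)
  provenance <- list(
    n_models = n_models, ratio = ratio, seed = seed,
    score_threshold = score_threshold,
    support_threshold = support_threshold,
    scan_width = width, scan_step = step,
    ensemble_metrics = lapply(members, function(m) as.list(m$metrics)),
    ensemble_seeds = vapply(members, function(m) m$seed, numeric(1)),
    best_model_index = best_idx,
    n_hard_negatives = nrow(hard),
    enhanced_set = list(n_positives = nrow(positives),
                        n_negatives = nrow(enhanced)))
  list(model = final, ensemble = members, best = best_idx,
       hard_negatives = hard, enhanced_negatives = enhanced,
       provenance = provenance)
}
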