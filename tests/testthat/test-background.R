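test_that("sample_random_negatives length-matches at the requested ratio", {
  sim <- simulate_genome(synthetic_genome_spec(seed = 2))
  bench <- benchmark_suite(sim)
  negs <- sample_random_negatives(bench$positives, bench$candidate_regions,
                                  ratio = 4, seed = 7)
  expect_equal(nrow(negs), 4L * nrow(bench$positives))
  expect_equal(sort(unique(interval_width(negs))),
               sort(unique(interval_width(bench$positives))))
  # deterministic per seed
  negs2 <- sample_random_negatives(bench$positives, bench$candidate_regions,
                                   ratio = 4, seed = 7)
  expect_identical(negs, negs2)
  # no same-strand overlap with positives or other negatives
  all_iv <- rbind(bench$positives[, 1:6], negs[, 1:6])
  cl <- sncscan:::cluster_by_overlap(all_iv)
  expect_equal(length(unique(cl)), nrow(all_iv))
  # candidate space too small -> explicit error
  tiny_cand <- gi("chr1", 0, 30)
  expect_error(sample_random_negatives(bench$positives, tiny_cand, 4, 1),
               "too small")
})

test_that("consensus support equals the brute-force recount on toy tables", {
  set.seed(13)
  for (case in 1:10) {
    n_windows <- sample(20:200, 1)
    n_models <- sample(2:5, 1)
    starts <- sort(sample(seq(0, 4020, by = 20), n_windows))
    windows <- gi(rep("chr1", n_windows), starts, starts + 100,
                  sample(c("+", "-"), n_windows, replace = TRUE))
    flags <- matrix(runif(n_windows * n_models) < 0.2, n_windows, n_models)
    scores <- matrix(runif(n_windows * n_models), n_windows, n_models)
    thr <- sample(1:n_models, 1)
    hard <- sncscan:::consensus_hard_negatives(windows, flags, scores, thr)
    oracle <- oracle_support(windows, flags)
    want <- Filter(function(x) x$support >= thr, oracle)
    expect_equal(nrow(hard), length(want))
    if (nrow(hard)) {
      expect_true(all(hard$support >= thr))
      expect_equal(unname(sort(hard$support)),
                   unname(sort(vapply(want, `[[`, integer(1), "support"))))
    }
  }
})

test_that("the consensus boundary includes 25 of 50 and excludes 24", {
  windows <- gi(c("c", "c"), c(0, 1000), c(100, 1100))
  flags <- rbind(c(rep(TRUE, 25), rep(FALSE, 25)),
                 c(rep(TRUE, 24), rep(FALSE, 26)))
  scores <- matrix(runif(100), 2, 50)
  hard <- sncscan:::consensus_hard_negatives(windows, flags, scores, 25L)
  expect_equal(nrow(hard), 1L)
  expect_equal(hard$start, 0)
  expect_equal(hard$support, 25L)
})

test_that("toy three-model consensus at threshold 2", {
  windows <- gi("c", 0, 100)
  flags <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  scores <- matrix(c(0.8, 0.7, 0.1), 1, 3)
  hard <- sncscan:::consensus_hard_negatives(windows, flags, scores, 2L)
  expect_equal(nrow(hard), 1L)
  expect_equal(hard$support, 2L)
  expect_equal(hard$score, 2 / 3)   # support scaled by ensemble size
})

test_that("select_best_model arg-maxes F1 with lower-index tie-break", {
  fake <- function(f1) list(metrics = c(precision = 0, sensitivity = 0,
                                        F1 = f1))
  expect_equal(select_best_model(list(fake(0.3), fake(0.7), fake(0.5))), 2L)
  expect_equal(select_best_model(list(fake(0.5), fake(0.5))), 1L)
  expect_equal(select_best_model(list(fake(0.4))), 1L)
})

test_that("support_threshold above the ensemble size is rejected", {
  m <- list(structure(list(config = desk_config(), trained = TRUE),
                      class = "snc_model"))
  expect_error(collect_hard_negatives(m, genomic_intervals(),
                                      genomic_intervals(), c(chr1 = "ACGT"),
                                      support_threshold = 2L),
               "exceeds ensemble size")
})

# ---- desk-scale pipeline properties (cached run shared with acceptance) ----

test_that("ensemble members train on distinct negative sets with metrics", {
  pipe <- desk_pipeline(1)
  expect_length(pipe$members, 5L)
  negsets <- lapply(pipe$members, function(m)
    paste(m$negatives$chrom, m$negatives$start, collapse = ";"))
  expect_equal(length(unique(unlist(negsets))), 5L)
  for (m in pipe$members) {
    expect_true(is.finite(m$metrics[["F1"]]))
  }
})

test_that("iterate_train bookkeeping: enhanced set and provenance", {
  pipe <- desk_pipeline(1)
  fit <- pipe$fit
  best <- pipe$members[[fit$best]]
  expect_equal(nrow(fit$enhanced_negatives),
               nrow(best$negatives) + nrow(fit$hard_negatives))
  expect_gt(nrow(fit$hard_negatives), 0L)
  expect_true(all(fit$hard_negatives$support >= 3L))
  prov <- fit$provenance
  expect_equal(prov$n_models, 5L)
  expect_equal(prov$n_hard_negatives, nrow(fit$hard_negatives))
  expect_equal(prov$best_model_index, fit$best)
  expect_length(prov$ensemble_metrics, 5L)
  # the final model never saw the left-out chromosome
  expect_false(pipe$bench$left_out_chrom %in%
                 c(fit$enhanced_negatives$chrom, pipe$bench$positives$chrom))
})

test_that("no emitted negative overlaps a positive at >= 50% same-strand", {
  pipe <- desk_pipeline(1)
  # random negatives reject any same-strand overlap at all
  for (member in pipe$members) {
    m <- sncscan:::hit_matrix(member$negatives, pipe$bench$positives,
                              min_frac = 1e-9)
    expect_equal(sum(m), 0L)
  }
  # hard negatives may graze a positive but never hit one at >= 50%
  m <- sncscan:::hit_matrix(pipe$fit$enhanced_negatives,
                            pipe$bench$positives, min_frac = 0.5)
  expect_equal(sum(m), 0L)
})

test_that("hard negatives concentrate on decoys and mirror loci", {
  pipe <- desk_pipeline(1)
  hard <- pipe$fit$hard_negatives
  sim <- pipe$sim
  scan_chroms <- c("chr1", "chr2")
  decoys <- sim$decoys[sim$decoys$chrom %in% scan_chroms, , drop = FALSE]
  # fraction of hard negatives overlapping a planted decoy exceeds the
  # decoy fraction of scanned bp (strand-blind positional overlap)
  pos_overlap <- function(x, y) {
    hits <- logical(nrow(x))
    for (j in seq_len(nrow(y))) {
      hits <- hits | (x$chrom == y$chrom[j] &
                        pmin(x$end, y$end[j]) - pmax(x$start, y$start[j]) > 0)
    }
    hits
  }
  frac_hard <- mean(pos_overlap(hard, decoys))
  scanned_bp <- 2 * sum(nchar(sim$genome[scan_chroms]))
  frac_bp <- 2 * sum(interval_width(decoys)) / scanned_bp
  expect_gt(frac_hard, frac_bp)
})

test_that("the iterated model beats the median round-1 member on FPs", {
  # directional property at scan sensitivity 0.5, three seeded worlds
  wins <- vapply(1:3, function(seed) {
    pipe <- desk_pipeline(seed)
    member_fp <- vapply(pipe$member_windows, function(w) {
      fp_at_sensitivity(w, pipe$targets)$FP
    }, numeric(1))
    final_fp <- fp_at_sensitivity(pipe$final_windows, pipe$targets)$FP
    final_fp < stats::median(member_fp)
  }, logical(1))
  expect_gte(sum(wins), 2L)   # directional: majority of seeded worlds
})
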