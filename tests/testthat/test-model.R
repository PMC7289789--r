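# Small random batches used throughout.
random_batch <- function(n, L = 20L, seed = 1L, labels = NULL) {
  set.seed(seed)
  list(S = array(rnorm(n * L * 4), c(n, L, 4)),
       F = array(rnorm(n * L * 3), c(n, L, 3)),
       C = array(rnorm(n * L * 1), c(n, L, 1)),
       labels = labels)
}

tiny_cfg <- function(branches = c("S", "F", "C"), seed = 9L) {
  model_config(branches = branches, filters = c(2L, 3L, 4L), kernel = 3L,
               dense_units = 5L, input_length = 20L, epochs = 3L,
               batch_size = 4L, seed = seed)
}

test_that("model_config validates the branch set", {
  expect_error(model_config(branches = character()), "non-empty")
  expect_error(model_config(branches = c("S", "Q")), "subset")
  expect_equal(model_config(branches = "F")$branches, "F")
  expect_length(model_config()$conv, 3L)
})

test_that("build_model accepts any branch subset and predicts in [0,1]", {
  for (br in list(c("S", "F", "C"), "F", c("S", "C"))) {
    cfg <- tiny_cfg(branches = br)
    m <- build_model(cfg)
    m$trained <- TRUE   # probe the forward pass with random weights
    p <- predict_scores(m, random_batch(8))
    expect_length(p, 8L)
    expect_true(all(p >= 0 & p <= 1))
    # determinism: same input twice
    expect_identical(p, predict_scores(m, random_batch(8)))
  }
  expect_length(predict_scores({
    m <- build_model(tiny_cfg()); m$trained <- TRUE; m
  }, random_batch(0)), 0L)
})

test_that("predict refuses untrained models and mismatched shapes", {
  m <- build_model(tiny_cfg())
  expect_error(predict_scores(m, random_batch(4)), "untrained")
  m$trained <- TRUE
  bad <- random_batch(4, L = 30L)
  expect_error(predict_scores(m, bad), "shape")
  mF <- build_model(tiny_cfg(branches = "F"))
  mF$trained <- TRUE
  noF <- random_batch(4)[c("S", "C")]
  expect_error(predict_scores(mF, noF), "shape|missing")
})

test_that("class_weights implements N/(2*Nc) and the disabled toggle", {
  labels <- c(rep(1, 100), rep(0, 400))
  w <- class_weights(labels)
  expect_equal(unname(w["1"]), 2.5)
  expect_equal(unname(w["0"]), 0.625)
  expect_equal(unname(class_weights(c(rep(1, 100), rep(0, 100)))),
               c(1, 1))
  expect_equal(unname(class_weights(labels, enabled = FALSE)), c(1, 1))
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("weighted loss on 1:4 equals unweighted loss on duplicated 1:1", {
  set.seed(33)
  p <- runif(500)
  y <- c(rep(1, 100), rep(0, 400))
  w <- unname(class_weights(y)[as.character(y)])
  weighted <- sncscan:::bce_loss(p, y, w)
  p_dup <- c(rep(p[1:100], 4), p[101:500])
  y_dup <- c(rep(1, 400), rep(0, 400))
  unweighted <- sncscan:::bce_loss(p_dup, y_dup, rep(1, 800))
  # 2.5/500 = 4/800 and 0.625/500 = 1/800, so the two means coincide exactly
  expect_equal(weighted, unweighted, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  set.seed(9)
  params <- sncscan:::nn_init_params(cfg)
  b <- random_batch(6, seed = 2)
  y <- c(1, 0, 1, 0, 1, 0)
  w <- c(2.5, 0.625, 2.5, 0.625, 2.5, 0.625)
  fwd <- sncscan:::nn_forward(params, cfg, b, keep_cache = TRUE)
  grads <- sncscan:::nn_backward(params, cfg, b, fwd, y, w)
  loss_at <- function(p) sncscan:::bce_loss(
    sncscan:::nn_forward(p, cfg, b)$p, y, w)
  base <- loss_at(params)
  eps <- 1e-6
  set.seed(4)
  for (nm in names(params)) {
    for (k in sample(seq_along(params[[nm]]),
                     min(4L, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + eps
      num <- (loss_at(p2) - base) / eps
      expect_equal(grads[[nm]][k], num, tolerance = 1e-3)
    }
  }
})

test_that("compiled forward equals the R reference forward", {
  for (br in list(c("S", "F", "C"), c("S", "F"), "C")) {
    cfg <- model_config(branches = br, filters = c(4L, 6L, 8L),
                        dense_units = 16L, seed = 21L)
    set.seed(21)
    params <- sncscan:::nn_init_params(cfg)
    b <- random_batch(17, L = 100L, seed = 5)
    p_cpp <- sncscan:::nn_predict_batched(params, cfg, b)
    p_r <- sncscan:::nn_predict_batched(params, cfg, b,
                                        use_compiled = FALSE)
    expect_equal(p_cpp, p_r, tolerance = 1e-12)
  }
})

test_that("training separates a planted motif and is seed-reproducible", {
  # synthetic linearly separable task: positives carry a fixed 6-mer
  make_set <- function(n, seed) {
    set.seed(seed)
    seqs <- replicate(n, random_seq(20))
    labels <- rep(c(1, 0), length.out = n)
    seqs[labels == 1] <- vapply(seqs[labels == 1], function(s) {
      paste0(substr(s, 1, 7), "GGCGGC", substr(s, 14, 20))
    }, character(1))
    S <- array(0, c(n, 20, 4))
    for (i in seq_len(n)) S[i, , ] <- one_hot_sequence(seqs[i])
    list(S = S, labels = labels)
  }
  cfg <- model_config(branches = "S", filters = c(4L, 8L, 8L), kernel = 3L,
                      dense_units = 16L, input_length = 20L, epochs = 30L,
                      batch_size = 16L, seed = 11L)
  train_set <- make_set(200, 1)
  m <- train_model(build_model(cfg), train_set)
  p <- predict_scores(m, train_set)
  acc <- mean((p >= 0.5) == (train_set$labels == 1))
  expect_gt(acc, 0.95)
  expect_equal(nrow(m$history), 30L)
  # reproducibility: same seed, same data -> identical weights
  m2 <- train_model(build_model(cfg), train_set)
  expect_identical(m$params, m2$params)
  # 1 epoch -> exactly 1 history record
  cfg1 <- cfg; cfg1$epochs <- 1L
  m1 <- train_model(build_model(cfg1), make_set(20, 2))
  expect_equal(nrow(m1$history), 1L)
})

test_that("training rejects mismatched blocks and single-class labels", {
  cfg <- tiny_cfg(branches = "F")
  b <- random_batch(8, labels = rep(c(1, 0), 4))
  bad <- b[c("S", "labels")]   # sequence block for an F-only model
  expect_error(train_model(build_model(cfg), bad), "missing|shape")
  b1 <- random_batch(8, labels = rep(1, 8))
  expect_error(train_model(build_model(tiny_cfg()), b1), "both classes")
})

test_that("an S-only model is invariant to the conservation block", {
  cfg <- tiny_cfg(branches = "S")
  m <- build_model(cfg)
  m$trained <- TRUE
  b <- random_batch(10)
  p1 <- predict_scores(m, b)
  b$C <- b$C + 100
  expect_identical(p1, predict_scores(m, b))
})

test_that("save/load round-trips predictions bit-for-bit", {
  cfg <- tiny_cfg()
  set.seed(3)
  b <- random_batch(12, labels = rep(c(1, 0), 6))
  m <- train_model(build_model(cfg), b)
  probe <- random_batch(7, seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_scores(m, probe), predict_scores(m2, probe))
  # config retrievable without materializing the model
  cfg2 <- read_model_config(path)
  expect_equal(cfg2$branches, cfg$branches)
  # truncated file errors, not garbage
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:20], path)
  expect_error(load_model(path), "cannot read|not a")
  # foreign RDS errors
  saveRDS(list(a = 1), path)
  expect_error(load_model(path), "not a")
})
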