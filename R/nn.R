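# Internal neural-network engine: 1-D convolutions via im2col + BLAS matrix
# products, ReLU, width-2 max pooling, dense head, logistic output, weighted
# binary cross-entropy, Adam. Shapes: feature arrays are (N, L, channels);
# conv weights are (kernel, in_channels, filters).

branch_channels <- c(S = 4L, F = 3L, C = 1L)

# Convolution as a sum of k shifted slice products: for kernel offset j,
# Z += X[, j:(j+L_out-1), ] %*% W[j, , ]. Avoids materializing the full
# im2col matrix; each slice is a modest copy and each product hits BLAS.
conv1d_fwd <- function(X, W, b) {
  dx <- dim(X); N <- dx[1]; L <- dx[2]; Cin <- dx[3]
  dw <- dim(W); k <- dw[1]
  Fout <- dw[3]
  L_out <- L - k + 1L
  stopifnot(dw[2] == Cin, L_out >= 1L)
  Zm <- matrix(rep(b, each = N * L_out), N * L_out, Fout)
  for (j in seq_len(k)) {
    Xs <- X[, j:(j + L_out - 1L), , drop = FALSE]
    dim(Xs) <- c(N * L_out, Cin)
    Zm <- Zm + Xs %*% matrix(W[j, , ], Cin, Fout)
  }
  dim(Zm) <- c(N, L_out, Fout)
  list(Z = Zm, X = X, dims = c(N = N, L = L, Cin = Cin, k = k,
                               Fout = Fout, L_out = L_out))
}

conv1d_bwd <- function(dZ, cache, W) {
  d <- cache$dims
  N <- d[["N"]]; L_out <- d[["L_out"]]; Cin <- d[["Cin"]]
  k <- d[["k"]]; Fout <- d[["Fout"]]
  dZm <- dZ
  dim(dZm) <- c(N * L_out, Fout)
  dW <- array(0, dim(W))
  dX <- array(0, c(N, d[["L"]], Cin))
  for (j in seq_len(k)) {
    span <- j:(j + L_out - 1L)
    Xs <- cache$X[, span, , drop = FALSE]
    dim(Xs) <- c(N * L_out, Cin)
    dW[j, , ] <- crossprod(Xs, dZm)
    dXs <- tcrossprod(dZm, matrix(W[j, , ], Cin, Fout))
    dim(dXs) <- c(N, L_out, Cin)
    dX[, span, ] <- dX[, span, , drop = FALSE] + dXs
  }
  list(dX = dX, dW = dW, db = colSums(dZm))
}

maxpool2_fwd <- function(A) {
  dA <- dim(A); L <- dA[2]
  if (L < 2L) {                      # too short to pool: identity
    return(list(P = A, identity = TRUE, L_in = L, L_out = L))
  }
  L_out <- L %/% 2L
  odd <- seq.int(1L, 2L * L_out, by = 2L)
  A1 <- A[, odd, , drop = FALSE]
  A2 <- A[, odd + 1L, , drop = FALSE]
  P <- pmax(A1, A2)
  list(P = P, left_wins = A1 >= A2, L_in = L, L_out = L_out)
}

maxpool2_bwd <- function(dP, cache) {
  if (isTRUE(cache$identity)) return(dP)
  dA <- array(0, c(dim(dP)[1], cache$L_in, dim(dP)[3]))
  odd <- seq.int(1L, 2L * cache$L_out, by = 2L)
  dA[, odd, ] <- dP * cache$left_wins
  dA[, odd + 1L, ] <- dP * !cache$left_wins
  dA
}

relu <- function(x) x * (x > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

# Output length of one branch after the conv/pool stack.
branch_flat_size <- function(L, conv_spec) {
  for (layer in conv_spec) {
    L <- L - layer$kernel + 1L
    if (L < 1L) stop("branch collapses: input too short for conv stack",
                     call. = FALSE)
    if (layer$pool > 1L && L >= layer$pool) L <- L %/% layer$pool
  }
  c(L = L, filters = conv_spec[[length(conv_spec)]]$filters)
}

nn_init_params <- function(config) {
  params <- list()
  flat_total <- 0L
  for (br in config$branches) {
    Cin <- branch_channels[[br]]
    for (l in seq_along(config$conv)) {
      spec <- config$conv[[l]]
      fan_in <- spec$kernel * Cin
      params[[pname(br, l, "W")]] <-
        array(stats::rnorm(spec$kernel * Cin * spec$filters,
                           sd = sqrt(2 / fan_in)),
              c(spec$kernel, Cin, spec$filters))
      params[[pname(br, l, "b")]] <- numeric(spec$filters)
      Cin <- spec$filters
    }
    fs <- branch_flat_size(config$input_length, config$conv)
    flat_total <- flat_total + fs[["L"]] * fs[["filters"]]
  }
  U <- config$dense_units
  params$dense_W <- matrix(stats::rnorm(flat_total * U,
                                        sd = sqrt(2 / flat_total)),
                           flat_total, U)
  params$dense_b <- numeric(U)
  params$out_W <- matrix(stats::rnorm(U, sd = sqrt(1 / U)), U, 1L)
  params$out_b <- 0
  params
}

pname <- function(branch, layer, what) sprintf("%s_conv%d_%s", branch, layer, what)

# Forward pass. inputs: named list of (N, L, channels) arrays keyed S/F/C.
nn_forward <- function(params, config, inputs, keep_cache = FALSE) {
  caches <- list()
  flats <- list()
  for (br in config$branches) {
    X <- inputs[[br]]
    if (is.null(X)) stop("missing input block for branch ", br, call. = FALSE)
    if (length(dim(X)) != 3L || dim(X)[2] != config$input_length ||
        dim(X)[3] != branch_channels[[br]]) {
      stop(sprintf("shape error: branch %s expects (N, %d, %d) input, got (%s)",
                   br, config$input_length, branch_channels[[br]],
                   paste(dim(X), collapse = ", ")), call. = FALSE)
    }
    A <- X
    br_cache <- list()
    for (l in seq_along(config$conv)) {
      cv <- conv1d_fwd(A, params[[pname(br, l, "W")]], params[[pname(br, l, "b")]])
      R <- relu(cv$Z)
      pl <- maxpool2_fwd(R)
      br_cache[[l]] <- list(conv = cv, Z = cv$Z, pool = pl)
      A <- pl$P
    }
    flat <- A
    dim(flat) <- c(dim(A)[1], dim(A)[2] * dim(A)[3])
    flats[[br]] <- flat
    if (keep_cache) caches[[br]] <- br_cache
  }
  H <- do.call(cbind, flats)
  D_pre <- sweep(H %*% params$dense_W, 2L, params$dense_b, `+`)
  D <- relu(D_pre)
  logit <- drop(D %*% params$out_W) + params$out_b
  p <- sigmoid(logit)
  out <- list(p = p, logit = logit)
  if (keep_cache) {
    out$cache <- list(branches = caches, flats = flats, H = H,
                      D_pre = D_pre, D = D)
  }
  out
}

# Backward pass for weighted binary cross-entropy (mean over batch).
# weights: per-example loss weights.
nn_backward <- function(params, config, inputs, fwd, y, weights) {
  N <- length(y)
  dlogit <- weights * (fwd$p - y) / N            # (N)
  cache <- fwd$cache
  grads <- list()
  grads$out_W <- crossprod(cache$D, dlogit)      # (U, 1)
  grads$out_b <- sum(dlogit)
  dD <- outer(dlogit, drop(params$out_W)) * (cache$D_pre > 0)
  grads$dense_W <- crossprod(cache$H, dD)
  grads$dense_b <- colSums(dD)
  dH <- tcrossprod(dD, params$dense_W)
  col <- 0L
  for (br in config$branches) {
    nb <- ncol(cache$flats[[br]])
    dflat <- dH[, col + seq_len(nb), drop = FALSE]
    col <- col + nb
    br_cache <- cache$branches[[br]]
    last <- br_cache[[length(br_cache)]]
    dP <- dflat
    dim(dP) <- dim(last$pool$P)
    for (l in rev(seq_along(config$conv))) {
      lc <- br_cache[[l]]
      dR <- maxpool2_bwd(dP, lc$pool)
      dZ <- dR * (lc$Z > 0)
      bk <- conv1d_bwd(dZ, lc$conv, params[[pname(br, l, "W")]])
      grads[[pname(br, l, "W")]] <- bk$dW
      grads[[pname(br, l, "b")]] <- bk$db
      if (l > 1L) dP <- bk$dX
    }
  }
  grads
}

bce_loss <- function(p, y, weights) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(weights * -(y * log(p) + (1 - y) * log(1 - p)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

subset_inputs <- function(inputs, branches, idx) {
  out <- list()
  for (br in branches) out[[br]] <- inputs[[br]][idx, , , drop = FALSE]
  out
}
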