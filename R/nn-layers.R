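# Minimal 1-D neural-network engine.
#
# Layers operate on batched arrays: sequence layers on (batch, length,
# channels) arrays, dense layers on (batch, features) matrices.  Each
# layer is a mutable environment holding its parameters, gradient
# accumulators, Adam state and a forward cache.  Convolutions are
# evaluated as one BLAS matrix product per layer via im2col; the
# backward pass is the exact adjoint, verified against central finite
# differences in the test suite.

act_fun <- function(z, act) {
  switch(act,
         linear = z,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         stop("unknown activation: ", act))
}

# derivative expressed through the activation output a
act_grad <- function(a, act) {
  switch(act,
         linear = array(1, dim(a)),
         relu = (a > 0) * 1,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         stop("unknown activation: ", act))
}

# uniform fan-in initialisation
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

new_layer <- function(kind, params = list(), meta = list()) {
  env <- new.env(parent = emptyenv())
  env$kind <- kind
  env$params <- params
  env$grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  env$frozen <- FALSE
  env$meta <- meta
  env$cache <- NULL
  env$adam <- NULL
  class(env) <- "nn_layer"
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layer_n_params <- function(layer) {
  if (!length(layer$params)) return(0L)
  sum(vapply(layer$params, length, integer(1)))
}

# ---------------------------------------------------------------- dense

layer_dense <- function(n_in, n_out, activation = "relu") {
  new_layer("dense",
            params = list(W = init_mat(n_in, n_out, n_in),
                          b = numeric(n_out)),
            meta = list(n_in = n_in, n_out = n_out, activation = activation))
}

dense_forward <- function(ly, x) {
  a <- act_fun(sweep(x %*% ly$params$W, 2, ly$params$b, "+"),
               ly$meta$activation)
  ly$cache <- list(x = x, a = a)
  a
}

dense_backward <- function(ly, dy) {
  dz <- dy * act_grad(ly$cache$a, ly$meta$activation)
  ly$grads$W <- crossprod(ly$cache$x, dz)
  ly$grads$b <- colSums(dz)
  dz %*% t(ly$params$W)
}

# ------------------------------------------------------ flatten/reshape

layer_flatten <- function(len, ch) {
  new_layer("flatten", meta = list(len = len, ch = ch))
}

flatten_forward <- function(ly, x) {
  ly$cache <- list(B = dim(x)[1])
  matrix(x, dim(x)[1], ly$meta$len * ly$meta$ch)
}

flatten_backward <- function(ly, dy) {
  array(dy, c(ly$cache$B, ly$meta$len, ly$meta$ch))
}

layer_reshape <- function(len, ch) {
  new_layer("reshape", meta = list(len = len, ch = ch))
}

reshape_forward <- function(ly, x) {
  ly$cache <- list(B = nrow(x))
  array(x, c(nrow(x), ly$meta$len, ly$meta$ch))
}

reshape_backward <- function(ly, dy) {
  matrix(dy, dim(dy)[1], ly$meta$len * ly$meta$ch)
}

# ------------------------------------------------------------- conv 1d

# length-preserving 1-D convolution (symmetric zero padding, odd k)
layer_conv1d <- function(n_in, filters, kernel = 3, activation = "relu") {
  stopifnot(kernel %% 2 == 1)
  new_layer("conv1d",
            params = list(W = init_mat(n_in * kernel, filters, n_in * kernel),
                          b = numeric(filters)),
            meta = list(n_in = n_in, filters = filters, kernel = kernel,
                        activation = activation))
}

# im2col: (B, L, Cin) -> (B*L, Cin*kernel), tap-major columns
conv_im2col <- function(x, kernel) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  p <- (kernel - 1) %/% 2
  xp <- array(0, c(B, L + 2 * p, Cin))
  xp[, (p + 1):(p + L), ] <- x
  m <- matrix(0, B * L, Cin * kernel)
  for (j in seq_len(kernel)) {
    m[, ((j - 1) * Cin + 1):(j * Cin)] <-
      matrix(xp[, j:(j + L - 1), , drop = FALSE], B * L, Cin)
  }
  m
}

conv_col2im <- function(dm, B, L, Cin, kernel) {
  p <- (kernel - 1) %/% 2
  dxp <- array(0, c(B, L + 2 * p, Cin))
  for (j in seq_len(kernel)) {
    dxp[, j:(j + L - 1), ] <- dxp[, j:(j + L - 1), , drop = FALSE] +
      array(dm[, ((j - 1) * Cin + 1):(j * Cin)], c(B, L, Cin))
  }
  dxp[, (p + 1):(p + L), , drop = FALSE]
}

conv1d_forward <- function(ly, x) {
  d <- dim(x)
  m <- conv_im2col(x, ly$meta$kernel)
  a2 <- act_fun(sweep(m %*% ly$params$W, 2, ly$params$b, "+"),
                ly$meta$activation)
  ly$cache <- list(m = m, a2 = a2, B = d[1], L = d[2])
  array(a2, c(d[1], d[2], ly$meta$filters))
}

conv1d_backward <- function(ly, dy) {
  B <- ly$cache$B; L <- ly$cache$L
  dz <- matrix(dy, B * L, ly$meta$filters) *
    act_grad(ly$cache$a2, ly$meta$activation)
  ly$grads$W <- crossprod(ly$cache$m, dz)
  ly$grads$b <- colSums(dz)
  conv_col2im(dz %*% t(ly$params$W), B, L, ly$meta$n_in, ly$meta$kernel)
}

# ------------------------------------------------------------- maxpool

layer_maxpool <- function(size = 2) {
  new_layer("maxpool", meta = list(size = size))
}

maxpool_forward <- function(ly, x) {
  s <- ly$meta$size
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  stopifnot(L %% s == 0)
  Lp <- L %/% s
  y <- array(-Inf, c(B, Lp, C))
  amax <- array(1L, c(B, Lp, C))          # ties go to the earliest slot
  for (j in seq_len(s)) {
    slice <- x[, seq(j, L, by = s), , drop = FALSE]
    upd <- slice > y
    y[upd] <- slice[upd]
    amax[upd] <- j
  }
  ly$cache <- list(amax = amax, B = B, L = L, C = C)
  y
}

maxpool_backward <- function(ly, dy) {
  s <- ly$meta$size
  B <- ly$cache$B; L <- ly$cache$L; C <- ly$cache$C
  Lp <- L %/% s
  dx <- array(0, c(B, L, C))
  for (j in seq_len(s)) {
    mask <- ly$cache$amax == j
    tmp <- array(0, c(B, Lp, C))
    tmp[mask] <- dy[mask]
    dx[, seq(j, L, by = s), ] <- tmp
  }
  dx
}

# --------------------------------------------------- transposed conv 1d

# Transposed convolution implemented as zero-stuffing upsampling by
# `stride` followed by a length-preserving convolution; parameter
# count is the conv closed form n_in*kernel*filters + filters.
layer_tconv1d <- function(n_in, filters, kernel = 3, stride = 2,
                          activation = "relu") {
  ly <- layer_conv1d(n_in, filters, kernel, activation)
  ly$kind <- "tconv1d"
  ly$meta$stride <- stride
  ly
}

tconv1d_forward <- function(ly, x) {
  s <- ly$meta$stride
  d <- dim(x)
  if (s > 1) {
    up <- array(0, c(d[1], d[2] * s, d[3]))
    up[, seq(1, d[2] * s, by = s), ] <- x
  } else up <- x
  ly$cache_up <- list(s = s, L_in = d[2])
  conv1d_forward(ly, up)
}

tconv1d_backward <- function(ly, dy) {
  dup <- conv1d_backward(ly, dy)
  s <- ly$cache_up$s
  if (s > 1) dup[, seq(1, dim(dup)[2], by = s), , drop = FALSE] else dup
}

# ---------------------------------------------------------------- LSTM

# Full-sequence LSTM; gate order (i, f, g, o); forget-gate bias
# initialised to 1.
layer_lstm <- function(n_in, units) {
  W <- init_mat(n_in + units, 4 * units, n_in + units)
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1
  new_layer("lstm", params = list(W = W, b = b),
            meta = list(n_in = n_in, units = units))
}

lstm_forward <- function(ly, x) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  U <- ly$meta$units
  W <- ly$params$W; b <- ly$params$b
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  gi <- array(0, c(B, L, U)); gf <- gi; gg <- gi; go <- gi
  cs <- gi; tc <- gi; hp <- gi; cp <- gi
  out <- array(0, c(B, L, U))
  for (t in seq_len(L)) {
    hp[, t, ] <- h; cp[, t, ] <- cc
    xt <- matrix(x[, t, ], B, Cin)
    z <- sweep(cbind(xt, h) %*% W, 2, b, "+")
    i_ <- 1 / (1 + exp(-z[, 1:U, drop = FALSE]))
    f_ <- 1 / (1 + exp(-z[, (U + 1):(2 * U), drop = FALSE]))
    g_ <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
    o_ <- 1 / (1 + exp(-z[, (3 * U + 1):(4 * U), drop = FALSE]))
    cc <- f_ * cc + i_ * g_
    tcc <- tanh(cc)
    h <- o_ * tcc
    gi[, t, ] <- i_; gf[, t, ] <- f_; gg[, t, ] <- g_; go[, t, ] <- o_
    cs[, t, ] <- cc; tc[, t, ] <- tcc
    out[, t, ] <- h
  }
  ly$cache <- list(x = x, gi = gi, gf = gf, gg = gg, go = go,
                   cs = cs, tc = tc, hp = hp, cp = cp, B = B, L = L)
  out
}

lstm_backward <- function(ly, dy) {
  cc <- ly$cache
  B <- cc$B; L <- cc$L; U <- ly$meta$units; Cin <- ly$meta$n_in
  W <- ly$params$W
  dW <- array(0, dim(W)); db <- numeric(4 * U)
  dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
  dx <- array(0, c(B, L, Cin))
  getm <- function(a, t) matrix(a[, t, ], B, dim(a)[3])
  for (t in rev(seq_len(L))) {
    i_ <- getm(cc$gi, t); f_ <- getm(cc$gf, t)
    g_ <- getm(cc$gg, t); o_ <- getm(cc$go, t)
    tcc <- getm(cc$tc, t)
    dh <- matrix(dy[, t, ], B, U) + dh_next
    do_ <- dh * tcc
    dc <- dh * o_ * (1 - tcc^2) + dc_next
    di <- dc * g_
    dg <- dc * i_
    df <- dc * getm(cc$cp, t)
    dc_next <- dc * f_
    dz <- cbind(di * i_ * (1 - i_), df * f_ * (1 - f_),
                dg * (1 - g_^2), do_ * o_ * (1 - o_))
    xin <- cbind(matrix(cc$x[, t, ], B, Cin), getm(cc$hp, t))
    dW <- dW + crossprod(xin, dz)
    db <- db + colSums(dz)
    dxh <- dz %*% t(W)
    dx[, t, ] <- dxh[, seq_len(Cin), drop = FALSE]
    dh_next <- dxh[, (Cin + 1):(Cin + U), drop = FALSE]
  }
  ly$grads$W <- dW
  ly$grads$b <- db
  dx
}

# --------------------------------------------------------- dispatchers

layer_forward <- function(ly, x) {
  switch(ly$kind,
         dense = dense_forward(ly, x),
         flatten = flatten_forward(ly, x),
         reshape = reshape_forward(ly, x),
         conv1d = conv1d_forward(ly, x),
         maxpool = maxpool_forward(ly, x),
         tconv1d = tconv1d_forward(ly, x),
         lstm = lstm_forward(ly, x),
         stop("unknown layer kind: ", ly$kind))
}

layer_backward <- function(ly, dy) {
  switch(ly$kind,
         dense = dense_backward(ly, dy),
         flatten = flatten_backward(ly, dy),
         reshape = reshape_backward(ly, dy),
         conv1d = conv1d_backward(ly, dy),
         maxpool = maxpool_backward(ly, dy),
         tconv1d = tconv1d_backward(ly, dy),
         lstm = lstm_backward(ly, dy),
         stop("unknown layer kind: ", ly$kind))
}

# drop forward caches (before serialisation or after an update)
layer_clear_cache <- function(ly) {
  ly$cache <- NULL
  ly$cache_up <- NULL
  invisible(ly)
}

# ------------------------------------------------------------ optimiser

adam_init <- function(ly) {
  ly$adam <- list(m = lapply(ly$params, function(p) array(0, dim(p) %||% length(p))),
                  v = lapply(ly$params, function(p) array(0, dim(p) %||% length(p))))
  invisible(ly)
}

adam_step <- function(ly, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (ly$frozen || !length(ly$params)) return(invisible(ly))
  if (is.null(ly$adam)) adam_init(ly)
  for (nm in names(ly$params)) {
    g <- ly$grads[[nm]]
    ly$adam$m[[nm]] <- beta1 * ly$adam$m[[nm]] + (1 - beta1) * g
    ly$adam$v[[nm]] <- beta2 * ly$adam$v[[nm]] + (1 - beta2) * g^2
    mhat <- ly$adam$m[[nm]] / (1 - beta1^t)
    vhat <- ly$adam$v[[nm]] / (1 - beta2^t)
    ly$params[[nm]] <- ly$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(ly)
}
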