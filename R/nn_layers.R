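# Layer primitives for the U-shaped backbone. Feature maps are 4-D arrays
# dim (C, X, Y, Z), channel fastest, double precision. Every forward returns
# the output plus the cache its backward needs; backwards are hand-derived
# adjoints (validated against finite differences in the test suite).

conv_fwd <- function(x, W, b, stride = 1L, k = 3L) {
  pad <- if (k == 1L) 0L else (k - 1L) %/% 2L
  dims <- dim(x)
  y <- cpp_conv_fwd(x, as.integer(dims), W, b, as.integer(k),
                    as.integer(stride), as.integer(pad))
  od <- pmax((dims[2:4] + 2L * pad - k) %/% stride + 1L, 1L)
  list(y = array(y, c(nrow(W), od)),
       cache = list(x = x, stride = stride, k = k, pad = pad))
}

conv_bwd <- function(dy, W, cache) {
  r <- cpp_conv_bwd(cache$x, as.integer(dim(cache$x)), W, dy,
                    as.integer(cache$k), as.integer(cache$stride),
                    as.integer(cache$pad))
  list(dx = array(r$dx, dim(cache$x)), dW = r$dW, db = as.numeric(r$db))
}

inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- xhat * gamma + beta
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
}

inorm_bwd <- function(dy, gamma, cache) {
  d <- cache$d
  dym <- matrix(dy, nrow = d[1])
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * gamma
  n <- ncol(dym)
  dx <- cache$istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope = 0.01) {
  neg <- x < 0
  y <- x
  y[neg] <- y[neg] * slope
  list(y = y, cache = neg)
}

lrelu_bwd <- function(dy, cache, slope = 0.01) {
  dx <- dy
  dx[cache] <- dx[cache] * slope
  dx
}

# nearest-neighbour upsampling by 2 along each spatial axis
up2_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2),
    rep(seq_len(d[4]), each = 2), drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  od <- c(d[1], d[2] %/% 2L, d[3] %/% 2L, d[4] %/% 2L)
  dx <- array(0, od)
  for (ox in 1:2) for (oy in 1:2) for (oz in 1:2)
    dx <- dx + dy[, seq(ox, d[2], 2), seq(oy, d[3], 2), seq(oz, d[4], 2),
                  drop = FALSE]
  dx
}

# nearest-neighbour subsampling by integer factor (used to bring teacher
# outputs / references to an auxiliary head's resolution)
subsample_nn <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  if (length(d) == 3L)
    x[seq(1L, d[1], f), seq(1L, d[2], f), seq(1L, d[3], f), drop = FALSE]
  else
    x[, seq(1L, d[2], f), seq(1L, d[3], f), seq(1L, d[4], f), drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[2:4] == db[2:4]))
  y <- array(0, c(da[1] + db[1], da[2:4]))
  y[seq_len(da[1]), , , ] <- a
  y[da[1] + seq_len(db[1]), , , ] <- b
  y
}

# conv -> instance norm -> leaky ReLU
block_fwd <- function(x, p, stride = 1L, k = 3L) {
  cv <- conv_fwd(x, p$W, p$b, stride, k)
  nr <- inorm_fwd(cv$y, p$g, p$be)
  ac <- lrelu_fwd(nr$y)
  list(y = ac$y, cache = list(cv = cv$cache, nr = nr$cache, ac = ac$cache))
}

block_bwd <- function(dy, p, cache) {
  dy <- lrelu_bwd(dy, cache$ac)
  nb <- inorm_bwd(dy, p$g, cache$nr)
  cb <- conv_bwd(nb$dx, p$W, cache$cv)
  list(dx = cb$dx, dW = cb$dW, db = cb$db, dg = nb$dgamma, dbe = nb$dbeta)
}

# 1x1x1 linear head over channels
head_fwd <- function(x, p) {
  d <- dim(x)
  y <- p$W %*% matrix(x, nrow = d[1]) + p$b
  array(y, c(nrow(p$W), d[2:4]))
}

head_bwd <- function(dy, x, p) {
  d <- dim(x)
  dym <- matrix(dy, nrow = nrow(p$W))
  xm <- matrix(x, nrow = d[1])
  list(dx = array(crossprod(p$W, dym), d),
       dW = dym %*% t(xm), db = rowSums(dym))
}

# parameter initialisation (He fan-in for convs) from a private RNG stream
init_conv <- function(cout, cin, k, rng) {
  fan_in <- cin * k^3
  list(W = matrix(rng(cout * fan_in) * sqrt(2 / fan_in), cout, fan_in),
       b = numeric(cout), g = rep(1, cout), be = numeric(cout))
}

init_head <- function(cout, cin, rng) {
  list(W = matrix(rng(cout * cin) * sqrt(1 / cin), cout, cin),
       b = numeric(cout))
}

# deterministic per-component RNG: draws standard normals from an isolated
# stream so component initialisation is independent of call order
make_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
}
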