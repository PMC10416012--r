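# Internal helpers: seeded random streams, fast box blur, bilinear resampling,
# small error constructors shared across modules.

#' Derive a child seed from a master seed and a stream label
#'
#' Every source of randomness in the pipeline draws from a named stream whose
#' seed is a deterministic function of one master run seed, so a whole
#' experiment is reproducible from a single integer. The derivation is a small
#' polynomial hash kept strictly below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param label character stream label, e.g. `"jitter"`, `"geometry"`
#' @param index optional integer sub-index (e.g. tile number)
#' @return an integer seed in \[0, 2^31 - 2\]
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_stream <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# condition constructors ------------------------------------------------------

stop_stainpipe <- function(class, message, ...) {
  stop(structure(
    class = c(class, "stainpipe_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Running-mean box blur of a matrix with an odd window (2r+1), edge-replicated,
# separable rows then columns. Used by the synthetic generator.
box_blur <- function(m, r, passes = 1L) {
  if (r < 1) return(m)
  blur1d <- function(x, r) {
    n <- length(x)
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    cs <- cumsum(c(0, xp))
    (cs[(2 * r + 2):(n + 2 * r + 1)] - cs[1:n]) / (2 * r + 1)
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2L, blur1d, r = r)
    m <- t(apply(m, 1L, blur1d, r = r))
  }
  m
}

# Bilinear upsample of a small matrix to out_h x out_w (cell-centre alignment).
bilinear_upsample <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  ry <- (seq_len(out_h) - 0.5) * in_h / out_h + 0.5
  rx <- (seq_len(out_w) - 0.5) * in_w / out_w + 0.5
  y0 <- pmin(pmax(floor(ry), 1L), in_h); y1 <- pmin(y0 + 1L, in_h)
  x0 <- pmin(pmax(floor(rx), 1L), in_w); x1 <- pmin(x0 + 1L, in_w)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  (a * (1 - WX) + b * WX) * (1 - WY) + (c_ * (1 - WX) + d * WX) * WY
}

# column-wise unit normalization
unit_cols <- function(m) sweep(m, 2L, sqrt(colSums(m^2)), "/")

# angle in degrees between two 3-vectors
angle_deg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}
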