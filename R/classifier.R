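# Pluggable tile-level classifier.
#
# The training contract is: per epoch, each labelled tile passes through the
# geometric augmentation hook, then the optional stain hook (normalization is
# deterministic; jitter redraws its factors per tile per step), is featurized,
# and the batch gradient of the binary cross-entropy is applied with Adam.
# The default desk-scale backend is a one-hidden-layer perceptron on 18
# colour/density summary features; a heavier backbone can be registered under
# the same contract without touching the pipeline.

#' Training configuration
#'
#' Defaults are the reference protocol: Adam with learning rate 1e-4 and
#' betas (0.9, 0.999), binary cross-entropy loss, 100 epochs, batch size 100.
#' Desk-scale runs typically override `epochs` (and often `learning_rate`)
#' downwards/upwards respectively.
#'
#' @param learning_rate Adam step size
#' @param adam_betas length-2 numeric, exponential decay rates
#' @param epochs training epochs
#' @param batch_size tiles per gradient step
#' @param model backend name (currently `"mlp"`)
#' @param hidden hidden units of the default backend
#' @param seed integer seed controlling init, shuffling and augmentation draws
#' @export
train_config <- function(learning_rate = 1e-4, adam_betas = c(0.9, 0.999),
                         epochs = 100L, batch_size = 100L, model = "mlp",
                         hidden = 16L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            length(adam_betas) == 2L, all(adam_betas > 0 & adam_betas < 1))
  structure(list(learning_rate = learning_rate, adam_betas = adam_betas,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 model = model, hidden = as.integer(hidden),
                 seed = as.integer(seed), loss = "bce"),
            class = "train_config")
}

#' Summary features of a tile
#'
#' 18 per-tile statistics: mean and sd of each RGB channel and of each OD
#' channel, fractions of pixels whose OD exceeds 0.15 / 0.5 in every channel,
#' mean absolute luminance gradient, and the 10/50/90% luminance quantiles.
#' Deliberately stain-sensitive: the raw-colour components expose the
#' classifier to scanner shift exactly as a pixel-space network would be.
#'
#' @param tile an [rgb_image()]
#' @return numeric vector of length 18
#' @export
tile_features <- function(tile) {
  p <- unclass(tile) / img_i0(tile)
  od <- -log10(pmin(pmax(p, 1 / 255), 1))   # same floor as rgb_to_od()
  gray <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  odmin <- pmin(od[, , 1], od[, , 2], od[, , 3])
  gx <- abs(gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE])
  gy <- abs(gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE])
  pm <- matrix(p, ncol = 3L); om <- matrix(od, ncol = 3L)
  mp <- colMeans(pm); mo <- colMeans(om)
  c(mp, sqrt(pmax(colMeans(pm^2) - mp^2, 0)),
    mo, sqrt(pmax(colMeans(om^2) - mo^2, 0)),
    mean(odmin > 0.15), mean(odmin > 0.5),
    (mean(gx) + mean(gy)) / 2,
    stats::quantile(gray, c(0.1, 0.5, 0.9), names = FALSE))
}

# -- Adam-trained MLP backend -------------------------------------------------

.mlp_init <- function(d, h) {
  list(W1 = matrix(stats::rnorm(h * d, sd = 1 / sqrt(d)), h, d),
       b1 = numeric(h),
       W2 = matrix(stats::rnorm(h, sd = 1 / sqrt(h)), 1, h),
       b2 = 0)
}

.mlp_forward <- function(par, X) {
  # X: n x d
  A <- tanh(sweep(X %*% t(par$W1), 2L, par$b1, "+"))       # n x h
  z <- as.vector(A %*% t(par$W2)) + par$b2
  list(A = A, p = 1 / (1 + exp(-z)))
}

.mlp_grad <- function(par, X, y) {
  n <- nrow(X)
  fw <- .mlp_forward(par, X)
  dz <- (fw$p - y) / n                                     # dBCE/dz
  gW2 <- matrix(dz %*% fw$A, 1)
  gb2 <- sum(dz)
  dA <- outer(dz, as.vector(par$W2)) * (1 - fw$A^2)        # n x h
  gW1 <- t(dA) %*% X
  gb1 <- colSums(dA)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Train a tile classifier
#'
#' @param tiles list of tiles (each with a `pixels` [rgb_image()], as produced
#'   by [extract_tiles()]; bare `rgb_image`s are also accepted)
#' @param labels binary vector (0/1 or logical), one per tile; 1 = positive
#' @param config a [train_config()]
#' @param augment optional `function(tile, step_seed)` applied to each tile
#'   before each step (geometric augmentation)
#' @param stain_op optional `function(tile, step_seed)` applied after
#'   augmentation (normalization or jitter; `NULL` for the no-processing arm)
#' @param stain_when `"after_augment"` (default; required for per-step
#'   jitter) or `"before_augment"`: a deterministic stain op such as
#'   normalization may be applied once per tile, before the epoch loop
#' @return a `tile_classifier` handle exposing `score_tiles()`
#' @export
train_tile_classifier <- function(tiles, labels, config = train_config(),
                                  augment = NULL, stain_op = NULL,
                                  stain_when = c("after_augment",
                                                 "before_augment")) {
  stain_when <- match.arg(stain_when)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)))
    stop_stainpipe("invalid_input", "labels must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop_stainpipe("degenerate_labels", "training set contains a single class")
  if (length(tiles) != length(y))
    stop_stainpipe("invalid_input", "one label per tile required")
  pix <- lapply(tiles, function(t) if (is_rgb_image(t)) t else t$pixels)
  if (!is.null(stain_op) && stain_when == "before_augment") {
    pix <- lapply(seq_along(pix), function(i) {
      s <- derive_seed(config$seed, "stainpre", i)
      with_stream(s, stain_op(pix[[i]], s))
    })
    stain_op <- NULL
  }
  static <- is.null(augment) && is.null(stain_op)
  featurize <- function(epoch) {
    do.call(rbind, lapply(seq_along(pix), function(i) {
      tl <- pix[[i]]
      s <- derive_seed(config$seed, "augstep", epoch * 1000003 + i)
      if (!is.null(augment)) tl <- with_stream(s, augment(tl, s))
      if (!is.null(stain_op))
        tl <- with_stream(derive_seed(s, "stain"), stain_op(tl, s))
      tile_features(tl)
    }))
  }
  X0 <- featurize(0L)
  mu <- colMeans(X0); sg <- apply(X0, 2L, stats::sd)
  # absolute floor: features live on ~[0, 1] scales, and near-constant
  # features (e.g. the background plateau of normalized tiles) must not
  # turn small systematic offsets into huge standardized excursions
  sg <- pmax(sg, 0.01)
  n <- length(y); d <- ncol(X0)
  par <- with_stream(derive_seed(config$seed, "init"),
                     .mlp_init(d, config$hidden))
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
  lr <- config$learning_rate; t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    X <- if (static && epoch > 1L) X else {
      Xe <- if (epoch == 1L) X0 else featurize(epoch)
      sweep(sweep(Xe, 2L, mu), 2L, sg, "/")
    }
    ord <- with_stream(derive_seed(config$seed, "shuffle", epoch), sample.int(n))
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      g <- .mlp_grad(par, X[idx, , drop = FALSE], y[idx])
      t_step <- t_step + 1L
      for (k in names(par)) {
        m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
        v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
        mhat <- m[[k]] / (1 - b1^t_step)
        vhat <- v[[k]] / (1 - b2^t_step)
        par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
  }
  structure(list(par = par, mu = mu, sigma = sg, config = config,
                 n_train = n, backend = config$model),
            class = "tile_classifier")
}

#' Score tiles with a trained classifier
#'
#' @param model a `tile_classifier` from [train_tile_classifier()]
#' @param tiles list of tiles (or bare [rgb_image()]s)
#' @return numeric positivity scores in \[0, 1\], one per tile
#' @export
score_tiles <- function(model, tiles) {
  pix <- lapply(tiles, function(t) if (is_rgb_image(t)) t else t$pixels)
  X <- do.call(rbind, lapply(pix, tile_features))
  X <- sweep(sweep(X, 2L, model$mu), 2L, model$sigma, "/")
  .mlp_forward(model$par, X)$p
}

#' Save / load a classifier handle as JSON
#' @param model a `tile_classifier`
#' @param path file path
#' @export
save_classifier <- function(model, path) {
  obj <- list(par = lapply(model$par, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))
              }),
              mu = model$mu, sigma = model$sigma,
              n_train = model$n_train, backend = model$backend)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$par, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else if (length(p$data) == 1L) p$data else as.numeric(p$data)
  })
  structure(list(par = par, mu = obj$mu, sigma = obj$sigma,
                 config = NULL, n_train = obj$n_train, backend = obj$backend),
            class = "tile_classifier")
}
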