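# Magnification handling, Otsu tissue segmentation, sliding-window tile
# extraction with tissue filtering, and geometric training augmentation.

#' Tiling specification
#'
#' Defaults follow the pipeline's protocol: 224 px tiles at x10 magnification;
#' sliding-window stride 112 px (half the tile) at inference and 56 px (a
#' quarter) in training; training tiles are cut oversized at 316 px so a
#' random rotation can be centre-cropped back to 224 px without data loss;
#' tiles with under 10% tissue are discarded.
#'
#' @param tile_size final tile side in pixels
#' @param stride_inference,stride_training sliding-window strides
#' @param min_tissue_fraction retention threshold on the window's tissue mean
#' @param training_tile_size oversized pre-rotation side
#' @param target_magnification objective power tiles are extracted at
#' @export
tile_spec <- function(tile_size = 224L, stride_inference = 112L,
                      stride_training = 56L, min_tissue_fraction = 0.10,
                      training_tile_size = 316L, target_magnification = 10) {
  stopifnot(stride_inference > 0, stride_inference <= tile_size,
            stride_training > 0, stride_training <= tile_size,
            min_tissue_fraction >= 0, min_tissue_fraction <= 1,
            training_tile_size >= tile_size)
  structure(list(tile_size = as.integer(tile_size),
                 stride_inference = as.integer(stride_inference),
                 stride_training = as.integer(stride_training),
                 min_tissue_fraction = min_tissue_fraction,
                 training_tile_size = as.integer(training_tile_size),
                 target_magnification = target_magnification),
            class = "tile_spec")
}

#' Downsample a scan to the target magnification
#'
#' Area (local-mean) resampling by the integer factor
#' `native_mag / target_magnification`; an identity when the scan is already
#' at target power. Supported native powers: 10, 20, 40.
#'
#' @param img an [rgb_image()]
#' @param native_mag objective power the image was scanned at
#' @param spec a [tile_spec()] carrying the target magnification
#' @return the resampled [rgb_image()]
#' @export
rescale_to_magnification <- function(img, native_mag, spec = tile_spec()) {
  if (!native_mag %in% c(10, 20, 40))
    stop_stainpipe("config_error", sprintf(
      "unsupported native magnification x%g", native_mag))
  f <- native_mag / spec$target_magnification
  if (f < 1 || f != round(f))
    stop_stainpipe("config_error", sprintf(
      "cannot rescale x%g to x%g", native_mag, spec$target_magnification))
  f <- as.integer(f)
  if (f == 1L) return(img)
  d <- dim(img)
  h2 <- d[1] %/% f; w2 <- d[2] %/% f
  if (h2 < 1L || w2 < 1L)
    stop_stainpipe("invalid_input", "image too small for requested rescale")
  out <- array(0, c(h2, w2, 3L))
  for (ch in 1:3) {
    m <- unclass(img)[seq_len(h2 * f), seq_len(w2 * f), ch]
    # mean over f x f blocks via a reshape: rows first, then columns
    m <- matrix(colMeans(matrix(m, nrow = f)), nrow = h2)     # h2 x (w2*f)
    out[, , ch] <- t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w2))
  }
  rgb_image(out, i0 = img_i0(img))
}

#' Otsu threshold of a grayscale matrix
#'
#' Maximizes the between-class variance over a 256-bin integer histogram and
#' returns the split level `t + 0.5` (pixels strictly below the level form the
#' dark class).
#'
#' @param gray numeric matrix on the 0-255 scale
#' @return the threshold level, or `NA` for a (near-)constant input
#' @export
otsu_threshold <- function(gray) {
  g <- pmin(pmax(round(gray), 0), 255)
  if (diff(range(g)) < 2) return(NA_real_)
  h <- as.numeric(tabulate(as.integer(g) + 1L, nbins = 256L))
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(h)                       # count in class {<= t}
  s0 <- cumsum(h * lv)
  mu_t <- s0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- s0 / w0
  m1 <- (mu_t - s0) / w1
  bcv <- w0 * w1 * (m0 - m1)^2
  bcv[!valid] <- -Inf
  t <- lv[which.max(bcv)]
  t + 0.5
}

#' Segment tissue with Otsu thresholding
#'
#' Computes Rec. 601 luminance, takes the Otsu threshold of its histogram,
#' and marks pixels darker than the threshold as tissue (H&E tissue is darker
#' than the near-white scanner background). Near-constant images yield an
#' all-false mask.
#'
#' @param img an [rgb_image()]
#' @return H x W logical matrix, `TRUE` = tissue
#' @export
segment_tissue <- function(img) {
  gray <- luminance(img)
  thr <- otsu_threshold(gray)
  if (is.na(thr)) return(matrix(FALSE, nrow(gray), ncol(gray)))
  gray < thr
}

#' Sliding-window tile positions
#'
#' Top-left (row, col) anchors, 0-based, row-major; windows that would extend
#' past the image are dropped, not padded.
#'
#' @param height,width image dimensions in pixels
#' @param size window side
#' @param stride step between anchors
#' @return data.frame with integer columns `row`, `col`
#' @export
plan_tiles <- function(height, width, size, stride) {
  rows <- seq(0L, by = as.integer(stride), length.out = max(
    0L, (height - size) %/% stride + 1L))
  cols <- seq(0L, by = as.integer(stride), length.out = max(
    0L, (width - size) %/% stride + 1L))
  if (height < size || width < size)
    return(data.frame(row = integer(0), col = integer(0)))
  data.frame(row = rep(rows, each = length(cols)),
             col = rep(cols, times = length(rows)))
}

#' Extract tissue tiles from a slide
#'
#' Windows are placed by [plan_tiles()] (inference: side 224, stride 112;
#' training: side 316, stride 56, per the [tile_spec()]), the tissue fraction
#' of each window is the mean of the mask over it, and windows below
#' `min_tissue_fraction` are discarded (the 10% rule; ties are retained).
#'
#' @param img an [rgb_image()] at target magnification
#' @param mask logical tissue mask of the same spatial shape
#' @param spec a [tile_spec()]
#' @param mode `"inference"` or `"training"`
#' @param slide_id identifier carried on each tile
#' @return list of tiles; each is a list with `pixels` ([rgb_image()]), `row`,
#'   `col`, `tissue_fraction`, `slide_id`
#' @export
extract_tiles <- function(img, mask, spec = tile_spec(),
                          mode = c("inference", "training"),
                          slide_id = "slide") {
  mode <- match.arg(mode)
  d <- dim(img)
  if (!is.matrix(mask) || nrow(mask) != d[1] || ncol(mask) != d[2])
    stop_stainpipe("invalid_input", "mask shape must match image")
  size <- if (mode == "training") spec$training_tile_size else spec$tile_size
  stride <- if (mode == "training") spec$stride_training else spec$stride_inference
  pos <- plan_tiles(d[1], d[2], size, stride)
  if (nrow(pos) == 0L) return(list())
  # integral image for O(1) window sums
  cs <- apply(apply(mask * 1, 2L, cumsum), 1L, cumsum)  # transposed integral
  ii <- matrix(0, d[1] + 1L, d[2] + 1L)
  ii[-1, -1] <- t(cs)
  r0 <- pos$row; c0 <- pos$col
  sums <- ii[cbind(r0 + size + 1L, c0 + size + 1L)] -
          ii[cbind(r0 + 1L, c0 + size + 1L)] -
          ii[cbind(r0 + size + 1L, c0 + 1L)] +
          ii[cbind(r0 + 1L, c0 + 1L)]
  frac <- sums / (size * size)
  keep <- which(frac >= spec$min_tissue_fraction)
  i0 <- img_i0(img)
  lapply(keep, function(k) {
    r <- r0[k]; c_ <- c0[k]
    list(pixels = rgb_image(unclass(img)[(r + 1):(r + size),
                                         (c_ + 1):(c_ + size), , drop = FALSE],
                            i0 = i0),
         row = r, col = c_, tissue_fraction = frac[k], slide_id = slide_id)
  })
}

#' Rotate an oversized training tile and centre-crop it
#'
#' Rotates the 316 px tile about its centre by `angle_degrees` (bilinear
#' interpolation, white fill outside the source support) and centre-crops to
#' the final 224 px side. Multiples of 90 degrees are handled as exact index
#' permutations (no interpolation error).
#'
#' @param tile316 an [rgb_image()] of side `spec$training_tile_size`
#' @param angle_degrees rotation angle, counter-clockwise
#' @param spec a [tile_spec()]
#' @return an [rgb_image()] of side `spec$tile_size`
#' @export
rotate_and_crop <- function(tile316, angle_degrees, spec = tile_spec()) {
  d <- dim(tile316)
  n <- spec$training_tile_size
  if (d[1] != n || d[2] != n)
    stop_stainpipe("invalid_input", sprintf(
      "rotate_and_crop expects a %d px square tile, got %d x %d", n, d[1], d[2]))
  i0 <- img_i0(tile316)
  a <- (angle_degrees %% 360) * pi / 180
  src <- unclass(tile316)
  if ((angle_degrees %% 90) == 0) {
    k <- as.integer((angle_degrees %% 360) / 90)
    rot <- src
    rot90 <- function(m) t(m)[nrow(m):1, , drop = FALSE]  # 90 deg CCW
    if (k > 0) for (ch in 1:3) {
      m <- src[, , ch]
      for (i in seq_len(k)) m <- rot90(m)
      rot[, , ch] <- m
    }
    off <- (n - spec$tile_size) %/% 2
    idx <- (off + 1):(off + spec$tile_size)
    return(rgb_image(rot[idx, idx, , drop = FALSE], i0 = i0))
  }
  # bilinear path: evaluate the inverse map on the centre-crop grid only
  ts <- spec$tile_size
  off <- (n - ts) %/% 2
  ctr <- (n + 1) / 2
  xs <- (off + seq_len(ts)) - ctr
  X <- matrix(xs, ts, ts, byrow = TRUE)   # column offsets
  Y <- matrix(xs, ts, ts)                 # row offsets
  sx <- cos(a) * X - sin(a) * Y + ctr     # source coords of output pixels
  sy <- sin(a) * X + cos(a) * Y + ctr
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- function(xx, yy) xx >= 1 & xx <= n & yy >= 1 & yy <= n
  gather <- function(m, yy, xx, ok) {
    v <- rep(i0, length(yy))
    v[ok] <- m[(xx[ok] - 1L) * n + yy[ok]]
    v
  }
  ok00 <- inside(x0, y0); ok01 <- inside(x0 + 1, y0)
  ok10 <- inside(x0, y0 + 1); ok11 <- inside(x0 + 1, y0 + 1)
  any_ok <- ok00 | ok01 | ok10 | ok11
  w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
  w10 <- (1 - fx) * fy; w11 <- fx * fy
  out <- array(i0, c(ts, ts, 3L))
  for (ch in 1:3) {
    m <- src[, , ch]
    v <- gather(m, y0, x0, ok00) * w00 + gather(m, y0, x0 + 1L, ok01) * w01 +
         gather(m, y0 + 1L, x0, ok10) * w10 +
         gather(m, y0 + 1L, x0 + 1L, ok11) * w11
    v[!any_ok] <- i0
    out[, , ch] <- matrix(v, ts, ts)
  }
  rgb_image(out, i0 = i0)
}

#' Reflect a tile over the y-axis with probability p
#'
#' @param tile an [rgb_image()]
#' @param p reflection probability (default 0.5)
#' @param seed optional integer for a private seeded draw
#' @return the (possibly) reflected tile
#' @export
maybe_reflect <- function(tile, p = 0.5, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  u <- if (is.null(seed)) stats::runif(1) else with_stream(seed, stats::runif(1))
  if (u < p) {
    out <- unclass(tile)[, rev(seq_len(dim(tile)[2])), , drop = FALSE]
    rgb_image(out, i0 = img_i0(tile))
  } else tile
}

#' Write a tile manifest CSV
#' @param tiles list of tiles from [extract_tiles()]
#' @param path file path
#' @param label optional slide label recorded on every row
#' @export
write_tile_manifest <- function(tiles, path, label = NA) {
  df <- data.frame(
    slide_id = vapply(tiles, `[[`, "", "slide_id"),
    row = vapply(tiles, `[[`, 0, "row"),
    col = vapply(tiles, `[[`, 0, "col"),
    tissue_fraction = vapply(tiles, `[[`, 0, "tissue_fraction"),
    label = label
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
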