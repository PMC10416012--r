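# Macenko stain-vector estimation, stain normalization, stain jittering.
#
# A stain matrix is a 3 x 2 matrix whose columns are the optical-density
# absorption directions of hematoxylin (column 1) and eosin (column 2).
# Estimation follows Macenko: the two stains are the extreme angular
# directions (percentile-bounded) of the foreground OD pixel cloud inside its
# top-2 principal plane.

#' Construct / validate a stain matrix
#'
#' @param m 3 x 2 numeric matrix: column 1 hematoxylin, column 2 eosin
#' @param normalized if TRUE, require unit-norm columns (estimation output);
#'   jittered matrices are exempt
#' @param min_angle_deg minimum angle between columns (default 1 degree)
#' @return the validated matrix with class `stain_matrix`
#' @export
stain_matrix <- function(m, normalized = FALSE, min_angle_deg = 1) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 2L)))
    stop_stainpipe("invalid_input", "stain matrix must be 3 x 2")
  if (!all(is.finite(m)) || min(m) < 0)
    stop_stainpipe("invalid_input", "stain matrix elements must be finite and >= 0")
  if (normalized && any(abs(sqrt(colSums(m^2)) - 1) > 1e-9))
    stop_stainpipe("invalid_input", "stain columns must have unit norm")
  if (angle_deg(m[, 1], m[, 2]) <= min_angle_deg)
    stop_stainpipe("degenerate_stains",
                   "stain columns are (near-)collinear")
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  structure(m, class = c("stain_matrix", class(unclass(m))))
}

#' The packaged default target stain matrix
#'
#' The fixed matrix tiles are normalized to. The canonical H&E absorption
#' directions H = (0.65, 0.70, 0.29), E = (0.07, 0.99, 0.11), unit-normalized.
#' This is a documented stand-in for a target patch chosen from an external
#' dataset; any 3 x 2 matrix satisfying the invariants can be supplied instead.
#'
#' @return a unit-column [stain_matrix()]
#' @export
default_target_stains <- function() {
  stain_matrix(unit_cols(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))),
               normalized = TRUE)
}

#' Macenko estimation parameters
#'
#' @param alpha angle percentile in (0, 50); the stain directions are the
#'   alpha-th and (100 - alpha)-th percentiles of the foreground OD angles
#' @param beta OD foreground threshold: a pixel is foreground when its OD
#'   exceeds beta in all three channels
#' @param min_foreground_pixels minimum foreground pixels required (>= 3)
#' @param i0 white point
#' @export
macenko_params <- function(alpha = 1, beta = 0.15,
                           min_foreground_pixels = 100, i0 = 255) {
  stopifnot(alpha > 0, alpha < 50, beta > 0, min_foreground_pixels >= 3)
  structure(list(alpha = alpha, beta = beta,
                 min_foreground_pixels = min_foreground_pixels, i0 = i0),
            class = "macenko_params")
}

#' Stain-jitter parameters
#'
#' Each of the six stain-matrix elements is multiplied by an independent
#' Uniform(low, high) factor; columns are deliberately not re-normalized.
#'
#' @param low,high multiplicative bounds, 0 < low <= high (defaults 0.75, 1.25)
#' @export
jitter_params <- function(low = 0.75, high = 1.25) {
  stopifnot(low > 0, low <= high)
  structure(list(low = low, high = high), class = "jitter_params")
}

# foreground OD pixels as an n x 3 matrix
.od_foreground <- function(od, beta) {
  m <- matrix(od, ncol = 3L)
  m[m[, 1] > beta & m[, 2] > beta & m[, 3] > beta, , drop = FALSE]
}

#' Estimate the stain matrix of a tile with the Macenko method
#'
#' Steps: (1) keep OD pixels above `beta` in every channel; (2) top-2 right
#' singular vectors of the uncentred foreground OD matrix, each flipped so its
#' entry sum is positive; (3) polar angles of the pixels projected into that
#' plane; (4) the `alpha` and `100 - alpha` angle percentiles give the two
#' extreme directions; (5) mapped back to 3-space, negatives clipped, columns
#' unit-normalized; (6) hematoxylin is the column with the larger red
#' component (tie-break: larger green).
#'
#' @param od an `od_image` from [rgb_to_od()] (an [rgb_image()] is converted)
#' @param params a [macenko_params()]
#' @return a unit-column [stain_matrix()]
#' @export
estimate_stain_matrix <- function(od, params = macenko_params()) {
  if (is_rgb_image(od)) od <- rgb_to_od(od)
  X <- .od_foreground(od, params$beta)
  if (nrow(X) < params$min_foreground_pixels)
    stop_stainpipe("insufficient_tissue", sprintf(
      "only %d foreground pixels (need >= %d)", nrow(X),
      params$min_foreground_pixels))
  sv <- svd(X, nu = 0, nv = 3)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop_stainpipe("degenerate_stains",
                   "OD cloud is rank-deficient: effectively a single stain")
  V <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  proj <- X %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(params$alpha, 100 - params$alpha) / 100,
                        names = FALSE)
  cols <- vapply(qs, function(a) {
    v <- as.vector(V %*% c(cos(a), sin(a)))
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / sqrt(sum(v^2))
  }, numeric(3))
  # hematoxylin = larger red component; tie-break on green
  h_first <- cols[1, 1] > cols[1, 2] ||
    (cols[1, 1] == cols[1, 2] && cols[2, 1] >= cols[2, 2])
  if (!h_first) cols <- cols[, 2:1]
  stain_matrix(cols, normalized = TRUE)
}

#' Per-pixel stain concentrations by least squares
#'
#' Solves od ~ S c for every pixel and clips negative components to zero.
#'
#' @param od an `od_image` (or [rgb_image()], converted)
#' @param S a [stain_matrix()]
#' @return H x W x 2 array of non-negative concentrations
#' @export
compute_concentrations <- function(od, S) {
  if (is_rgb_image(od)) od <- rgb_to_od(od)
  S <- unclass(S)
  g <- crossprod(S)                     # 2 x 2 Gram matrix
  if (abs(det(g)) < 1e-12 * (g[1, 1] * g[2, 2] + 1e-300))
    stop_stainpipe("degenerate_stains", "singular stain matrix")
  pinv <- solve(g, t(S))                # 2 x 3
  X <- matrix(od, ncol = 3L)
  C <- X %*% t(pinv)
  C[C < 0] <- 0
  array(C, c(dim(od)[1:2], 2L))
}

# shared estimate-or-fallback plumbing for normalize/jitter
.with_source_stains <- function(tile, params, what, f) {
  S_src <- tryCatch(
    estimate_stain_matrix(rgb_to_od(tile), params),
    stainpipe_error = function(e) e
  )
  if (inherits(S_src, "condition")) {
    warning(sprintf("%s skipped (%s): tile passed through unchanged",
                    what, conditionMessage(S_src)), call. = FALSE)
    out <- tile
    attr(out, "stain_fallback") <- TRUE
    return(out)
  }
  f(S_src)
}

#' Normalize a tile's stains to a fixed target matrix
#'
#' Estimates the tile's own stain matrix, computes concentrations against it,
#' and reconstructs the tile as OD' = target C. Concentrations are preserved,
#' not rescaled. Tiles on which estimation fails (insufficient tissue or a
#' degenerate stain cloud) are returned unchanged with a warning and a
#' `stain_fallback` attribute.
#'
#' @param tile an [rgb_image()]
#' @param target a [stain_matrix()]; default [default_target_stains()]
#' @param params [macenko_params()]
#' @return the normalized [rgb_image()]
#' @export
normalize_stains <- function(tile, target = default_target_stains(),
                             params = macenko_params()) {
  .with_source_stains(tile, params, "stain normalization", function(S_src) {
    C <- compute_concentrations(rgb_to_od(tile), S_src)
    od2 <- array(matrix(C, ncol = 2L) %*% t(unclass(target)), dim(tile))
    out <- od_to_rgb(od2, i0 = img_i0(tile))
    attr(out, "source_stains") <- S_src
    out
  })
}

#' Stain-jitter a tile
#'
#' Estimates the tile's stain matrix S, multiplies each of its six elements by
#' an independent Uniform(low, high) draw, and reconstructs the tile from the
#' perturbed matrix with the original concentrations. The perturbed matrix is
#' exposed in the output's `jittered_stains` attribute; per the training
#' protocol the factors are drawn afresh per tile per training step.
#'
#' @param tile an [rgb_image()]
#' @param params [jitter_params()]
#' @param macenko [macenko_params()]
#' @param seed optional integer; if given the six factors are drawn from a
#'   private stream seeded with it (same seed, same tile: identical output)
#' @return the jittered [rgb_image()]
#' @export
jitter_stains <- function(tile, params = jitter_params(),
                          macenko = macenko_params(), seed = NULL) {
  .with_source_stains(tile, macenko, "stain jittering", function(S_src) {
    u <- if (is.null(seed)) stats::runif(6, params$low, params$high)
         else with_stream(seed, stats::runif(6, params$low, params$high))
    S2 <- unclass(S_src) * matrix(u, 3L, 2L)
    C <- compute_concentrations(rgb_to_od(tile), S_src)
    od2 <- array(matrix(C, ncol = 2L) %*% t(S2), dim(tile))
    out <- od_to_rgb(od2, i0 = img_i0(tile))
    attr(out, "source_stains") <- S_src
    attr(out, "jittered_stains") <- S2
    attr(out, "jitter_factors") <- matrix(u, 3L, 2L)
    out
  })
}

# JSON serialization ----------------------------------------------------------

#' Write a stain matrix to JSON
#'
#' Row-major 3 x 2 layout with explicit column labels.
#' @param S a [stain_matrix()]
#' @param path file path
#' @export
write_stain_matrix <- function(S, path) {
  obj <- list(columns = c("hematoxylin", "eosin"),
              rows = c("R", "G", "B"),
              values = lapply(1:3, function(i) as.numeric(S[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stain matrix from JSON written by [write_stain_matrix()]
#' @param path file path
#' @export
read_stain_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$values
  if (is.list(m)) m <- do.call(rbind, m)
  stain_matrix(m)
}
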