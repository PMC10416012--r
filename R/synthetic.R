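# Synthetic H&E slide generator with planted ground truth.
#
# Generative model (two-stain Beer-Lambert composition):
#   hematoxylin concentration = blurred random nuclei spots, whose density
#     depends on the class label; eosin concentration = a diffuse smooth blob
#     field (characteristic scale depends on the label), thresholded so real
#     stain-free valleys exist inside tissue;
#   OD = S_truth %*% C + Gaussian optics noise;  RGB = bg * 10^(-OD), then a
#   global gamma.
# Each slide uses two independent seeded streams: geometry (tissue mask,
# nuclei, blobs) and rendering (noise). Re-rendering the same geometry under a
# different scanner profile emulates rescanning the same biopsy.

#' A virtual scanner profile
#'
#' @param stains planted [stain_matrix()] (unit columns)
#' @param background_rgb near-white background, each channel in \[200, 255\]
#' @param noise_sd additive OD noise standard deviation (>= 0)
#' @param gamma global intensity exponent
#' @param name profile label used in manifests
#' @export
scanner_profile <- function(stains = default_target_stains(),
                            background_rgb = c(245, 243, 242),
                            noise_sd = 0.01, gamma = 1, name = "scanner") {
  stopifnot(length(background_rgb) == 3L,
            all(background_rgb >= 200 & background_rgb <= 255),
            noise_sd >= 0, gamma > 0)
  stains <- stain_matrix(unclass(stains))
  structure(list(stains = stains, background_rgb = background_rgb,
                 noise_sd = noise_sd, gamma = gamma, name = name),
            class = "scanner_profile")
}

#' Slide generation parameters
#'
#' Class signal: positive slides have denser nuclei (0.006 vs 0.0015 spots
#' per pixel) and a finer eosin blob scale (16 vs 40 px) - a crude stand-in
#' for crypt hyperplasia / villous flattening that is learnable at tile scale
#' and independent of the stain matrix, so stain processing is not
#' confounded with the class signal.
#'
#' @param height,width slide size in pixels (>= 2 training tile sides for
#'   default tiling; smaller sizes are allowed for unit fixtures)
#' @param label `"positive"` or `"negative"`
#' @param tissue_fraction_range (lo, hi) target range of the tissue fraction
#' @param nuclei_density_by_class named spots-per-pixel densities
#' @param blob_scale_by_class named eosin blob scales in pixels
#' @param seed slide seed
#' @export
slide_params <- function(height = 1024L, width = 1024L,
                         label = c("positive", "negative"),
                         tissue_fraction_range = c(0.3, 0.6),
                         nuclei_density_by_class = c(positive = 0.006,
                                                     negative = 0.0015),
                         blob_scale_by_class = c(positive = 16, negative = 40),
                         seed = 1L) {
  label <- match.arg(label)
  lo <- tissue_fraction_range[1]; hi <- tissue_fraction_range[2]
  stopifnot(lo > 0, lo <= hi, hi <= 1, height >= 64, width >= 64)
  structure(list(height = as.integer(height), width = as.integer(width),
                 label = label, tissue_fraction_range = c(lo, hi),
                 nuclei_density_by_class = nuclei_density_by_class,
                 blob_scale_by_class = blob_scale_by_class,
                 seed = as.integer(seed)),
            class = "slide_params")
}

# smooth [0,1]-normalized random field from a coarse Gaussian grid
.smooth_field <- function(h, w, scale) {
  gh <- max(2L, ceiling(h / scale)); gw <- max(2L, ceiling(w / scale))
  f <- bilinear_upsample(matrix(stats::rnorm(gh * gw), gh, gw), h, w)
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix(0.5, h, w))
  (f - rng[1]) / diff(rng)
}

#' Generate one synthetic slide
#'
#' @param params a [slide_params()]
#' @param profile a [scanner_profile()]
#' @return a `synthetic_slide`: list with `image` ([rgb_image()]),
#'   `truth_mask` (logical matrix), `truth_stains` ([stain_matrix()]),
#'   `label`, `seed`, `profile_name`
#' @export
generate_slide <- function(params, profile = scanner_profile()) {
  h <- params$height; w <- params$width
  if (h < 64 || w < 64)
    stop_stainpipe("config_error", "slide dimensions too small")
  lab <- params$label
  geom <- with_stream(derive_seed(params$seed, "geometry"), {
    # Truth tissue is STAINED material: unstained lumina inside the biopsy
    # outline count as background, exactly as they appear to a segmenter.
    # Both dyes carry a visibility floor of 0.3 so every truth pixel is
    # clearly darker than the near-white background, and stain-dominant
    # populations (nuclei cores without eosin; strong eosin without nuclei)
    # exist for percentile-extreme vector estimation. Eosin amplitude 2.4:
    # eosin-dominant pixels must clear the all-channel OD foreground rule
    # (eosin red component ~0.07 needs concentration > ~2.1 for red
    # OD > 0.15).
    dens <- params$nuclei_density_by_class[[lab]]
    spots <- matrix(stats::rbinom(h * w, 1L, dens), h, w)
    cH0 <- pmin(box_blur(spots * 60, r = 2L, passes = 2L), 2)  # ~5 px nuclei
    bscale <- params$blob_scale_by_class[[lab]]
    blob <- .smooth_field(h, w, scale = bscale)
    # rank-uniformize so eosin coverage fractions are exact regardless of
    # blob scale; the spatial granularity still carries the class signal
    blob <- matrix(rank(blob, ties.method = "average") / length(blob), h, w)
    cE0 <- 2.4 * pmax(blob - 0.45, 0) / 0.55
    support <- cE0 > 0.3 | cH0 > 0.3
    p_s <- mean(support)
    lo <- params$tissue_fraction_range[1]
    hi <- params$tissue_fraction_range[2]
    target <- stats::runif(1, lo, min(hi, max(lo, 0.95 * p_s)))
    tissue_field <- .smooth_field(h, w, scale = max(h, w) / 4)
    # threshold the outline field among support pixels so the stained
    # fraction itself lands on the target
    thr <- stats::quantile(tissue_field[support], 1 - target / p_s,
                           names = FALSE)
    mask <- support & (tissue_field > thr)
    cH <- cH0 * (mask & cH0 > 0.3)
    cE <- cE0 * (mask & cE0 > 0.3)
    list(mask = mask, cH = cH, cE = cE)
  })

  S <- unclass(profile$stains)
  C <- cbind(as.vector(geom$cH), as.vector(geom$cE))      # n x 2
  od <- C %*% t(S)                                        # n x 3
  if (profile$noise_sd > 0)
    od <- od + with_stream(derive_seed(params$seed, "render"),
                           matrix(stats::rnorm(length(od), 0, profile$noise_sd),
                                  nrow(od)))
  od <- pmax(od, 0)
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    I <- profile$background_rgb[ch] * 10^(-od[, ch])
    img[, , ch] <- matrix(pmin(pmax(I, 0), 255), h, w)
  }
  if (profile$gamma != 1) img <- 255 * (img / 255)^profile$gamma
  structure(list(image = rgb_image(img, i0 = 255),
                 truth_mask = geom$mask,
                 truth_stains = profile$stains,
                 label = lab, seed = params$seed,
                 profile_name = profile$name),
            class = "synthetic_slide")
}

#' Generate a labelled dataset of synthetic slides
#'
#' Per-slide seeds are derived from the master seed, so two datasets built
#' from the same master seed are identical, and the same seeds rendered under
#' a different [scanner_profile()] share geometry (truth masks, labels) while
#' differing in pixel statistics - a virtual rescan.
#'
#' @param n_pos,n_neg class counts (n_pos + n_neg >= 2)
#' @param template a [slide_params()] used for every slide (label and seed
#'   are overridden per slide)
#' @param profile a [scanner_profile()]
#' @param seed master seed
#' @param prefix slide-id prefix
#' @return list with `slides` (named list of `synthetic_slide`) and
#'   `manifest` (data.frame: slide_id, label, profile, seed)
#' @export
generate_dataset <- function(n_pos, n_neg, template = slide_params(),
                             profile = scanner_profile(), seed = 1L,
                             prefix = "slide") {
  stopifnot(n_pos + n_neg >= 2)
  labels <- c(rep("positive", n_pos), rep("negative", n_neg))
  ids <- sprintf("%s_%03d_%s", prefix, seq_along(labels),
                 ifelse(labels == "positive", "pos", "neg"))
  slides <- vector("list", length(labels)); names(slides) <- ids
  for (i in seq_along(labels)) {
    p <- template
    p$label <- labels[i]
    p$seed <- derive_seed(seed, "slide", i)
    slides[[i]] <- generate_slide(p, profile)
  }
  manifest <- data.frame(slide_id = ids, label = labels,
                         profile = profile$name,
                         seed = vapply(slides, `[[`, 0L, "seed"),
                         stringsAsFactors = FALSE)
  list(slides = slides, manifest = manifest)
}

#' Derive a shifted scanner profile
#'
#' Rotates each stain column by `column_rotation_degrees` towards the blue
#' axis (inside the plane the column spans with (0,0,1)), re-normalizes, and
#' offsets background and gamma - a controlled emulation of a scanner change.
#'
#' @param base a [scanner_profile()]
#' @param column_rotation_degrees rotation per column
#' @param background_delta length-3 additive background change
#' @param gamma_delta additive gamma change
#' @param name new profile name
#' @return the shifted [scanner_profile()]
#' @export
shift_profile <- function(base, column_rotation_degrees = 0,
                          background_delta = c(0, 0, 0), gamma_delta = 0,
                          name = paste0(base$name, "_shifted")) {
  S <- unclass(base$stains)
  a <- column_rotation_degrees * pi / 180
  ref <- c(0, 0, 1)
  S2 <- S
  for (j in 1:2) {
    v <- S[, j] / sqrt(sum(S[, j]^2))
    b <- ref - sum(ref * v) * v
    nb <- sqrt(sum(b^2))
    if (nb < 1e-9)
      stop_stainpipe("config_error", "stain column parallel to reference axis")
    b <- b / nb
    S2[, j] <- cos(a) * v + sin(a) * b
  }
  if (min(S2) < 0)
    stop_stainpipe("config_error",
                   "rotation produces a negative stain element")
  bg <- base$background_rgb + background_delta
  if (any(bg < 200 | bg > 255))
    stop_stainpipe("config_error", "shifted background leaves [200, 255]")
  scanner_profile(stains = stain_matrix(S2, normalized = TRUE),
                  background_rgb = bg, noise_sd = base$noise_sd,
                  gamma = base$gamma + gamma_delta, name = name)
}

#' Write a synthetic slide to disk (PNG image + mask + truth JSON)
#' @param slide a `synthetic_slide`
#' @param dir output directory
#' @param id slide identifier used as the filename stem
#' @export
write_slide <- function(slide, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(slide$image, file.path(dir, paste0(id, ".png")))
  png::writePNG(slide$truth_mask * 1, file.path(dir, paste0(id, "_mask.png")))
  truth <- list(label = slide$label, seed = slide$seed,
                profile = slide$profile_name,
                stains = lapply(1:3, function(i)
                  as.numeric(slide$truth_stains[i, ])))
  jsonlite::write_json(truth, file.path(dir, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(id)
}
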