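# Three-arm experiment harness: NP (no processing), SN (stain normalization),
# SJ (stain jittering), plus dataset splitting and QA utilities.
#
# Arm/processing consistency is structural: the arm alone decides which stain
# hook is attached where. SN normalizes training AND validation tiles to the
# target matrix; SJ jitters training tiles only (fresh factors per tile per
# step); NP touches neither. Validation tiles are never jittered.

#' Experiment configuration
#'
#' @param arm `"NP"`, `"SN"` or `"SJ"`
#' @param spec a [tile_spec()]
#' @param macenko a [macenko_params()]
#' @param jitter a [jitter_params()] (SJ arm)
#' @param target target [stain_matrix()] (SN arm; required there)
#' @param train a [train_config()]
#' @param tile_cutoff tile positivity cutoff for slide aggregation
#' @param n_boot bootstrap resamples for metric intervals (0 disables)
#' @param seed master seed; every stage stream derives from it
#' @export
experiment_config <- function(arm = c("NP", "SN", "SJ"), spec = tile_spec(),
                              macenko = macenko_params(),
                              jitter = jitter_params(),
                              target = default_target_stains(),
                              train = train_config(), tile_cutoff = 0.5,
                              n_boot = 200L, seed = 1L) {
  arm <- match.arg(arm)
  if (arm == "SN" && is.null(target))
    stop_stainpipe("config_error", "SN arm requires a target stain matrix")
  structure(list(arm = arm, spec = spec, macenko = macenko, jitter = jitter,
                 target = target, train = train, tile_cutoff = tile_cutoff,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Split a slide manifest into training and validation sets
#'
#' Seeded random split at the slide level; `round(n * ratio)` slides go to
#' training and the remainder to validation (414 slides at 80:20 give
#' 331 / 83). Optionally stratified by label.
#'
#' @param manifest data.frame with at least `slide_id` and `label`
#' @param ratio training proportion (default 0.8)
#' @param seed integer seed
#' @param stratify split within each label separately
#' @return list with `train` and `validation` manifests
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = 1L, stratify = FALSE) {
  n <- nrow(manifest)
  if (is.null(n) || n < 2L)
    stop_stainpipe("invalid_input", "manifest needs at least 2 slides")
  pick <- function(idx, seed) {
    k <- round(length(idx) * ratio)
    sel <- with_stream(seed, sample(idx, k))
    sel
  }
  train_idx <- if (stratify) {
    unlist(lapply(unique(manifest$label), function(l) {
      pick(which(manifest$label == l), derive_seed(seed, paste0("split_", l)))
    }))
  } else pick(seq_len(n), derive_seed(seed, "split"))
  list(train = manifest[sort(train_idx), , drop = FALSE],
       validation = manifest[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

# tiles + per-tile labels for a set of slides
.collect_tiles <- function(slides, manifest, spec, mode) {
  out_tiles <- list(); out_labels <- numeric(0); out_slide <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$slide_id[i]
    sl <- slides[[id]]
    if (is.null(sl))
      stop_stainpipe("io_error", sprintf("slide '%s' missing from inputs", id))
    mask <- if (!is.null(sl$truth_mask)) sl$truth_mask else segment_tissue(sl$image)
    tl <- extract_tiles(sl$image, mask, spec, mode = mode, slide_id = id)
    if (length(tl)) {
      out_tiles <- c(out_tiles, tl)
      out_labels <- c(out_labels,
                      rep(as.numeric(manifest$label[i] == "positive"),
                          length(tl)))
      out_slide <- c(out_slide, rep(id, length(tl)))
    }
  }
  list(tiles = out_tiles, labels = out_labels, slide_id = out_slide)
}

#' Run one experiment arm
#'
#' Pipeline: tile the training slides (oversized 316 px windows, stride 56),
#' train the classifier with per-step rotation/reflection augmentation and
#' the arm's stain hook, then for each validation set: tile (224 px, stride
#' 112), apply the arm's validation-side stain rule (SN only), score tiles,
#' aggregate to slide fractions, select the accuracy-maximal gamma on that
#' set, and report metrics, ROC/AUC and bootstrap intervals.
#'
#' @param config an [experiment_config()]
#' @param slides named list mapping slide_id to `synthetic_slide` (or any
#'   list with `image` and optional `truth_mask`)
#' @param train_manifest data.frame slide_id/label for training
#' @param validation_manifests named list of validation manifests
#' @param augment_training apply rotation/reflection augmentation (default
#'   TRUE; turning it off speeds up desk-scale smoke runs)
#' @return an `arm_report` list: arm, per-set metrics/roc/ci, tile metrics,
#'   provenance (seed, config echo)
#' @export
run_arm <- function(config, slides, train_manifest, validation_manifests,
                    augment_training = TRUE) {
  spec <- config$spec
  tr <- .collect_tiles(slides, train_manifest, spec, "training")
  if (!length(tr$tiles))
    stop_stainpipe("invalid_input", "no training tiles survived tissue filtering")
  augment <- if (augment_training) {
    function(tile, step_seed) {
      ang <- stats::runif(1, 0, 360)
      tile <- rotate_and_crop(tile, ang, spec)
      maybe_reflect(tile, p = 0.5)
    }
  } else {
    # no rotation/reflection: centre-crop the oversized tile
    function(tile, step_seed) rotate_and_crop(tile, 0, spec)
  }
  stain_op <- switch(config$arm,
    NP = NULL,
    SN = function(tile, step_seed)
      suppressWarnings(normalize_stains(tile, config$target, config$macenko)),
    SJ = function(tile, step_seed)
      suppressWarnings(jitter_stains(tile, config$jitter, config$macenko))
  )
  cfg_train <- config$train
  cfg_train$seed <- derive_seed(config$seed, "train")
  # normalization is deterministic, so the SN arm applies it once per tile
  # before the epoch loop; jitter must redraw per tile per step
  model <- train_tile_classifier(tr$tiles, tr$labels, cfg_train,
                                 augment = augment, stain_op = stain_op,
                                 stain_when = if (config$arm == "SN")
                                   "before_augment" else "after_augment")
  per_set <- list()
  for (set_name in names(validation_manifests)) {
    vm <- validation_manifests[[set_name]]
    va <- .collect_tiles(slides, vm, spec, "inference")
    if (!length(va$tiles))
      stop_stainpipe("invalid_input",
                     sprintf("validation set '%s' has no tiles", set_name))
    tiles <- va$tiles
    if (config$arm == "SN")
      tiles <- lapply(tiles, function(t) {
        t$pixels <- suppressWarnings(
          normalize_stains(t$pixels, config$target, config$macenko))
        t
      })
    scores <- score_tiles(model, tiles)
    tile_metrics <- compute_metrics(scores, va$labels, gamma = 0.5,
                                    level = "tile")
    by_slide <- split(scores, va$slide_id)
    fr <- vapply(by_slide, function(s)
      slide_score(s, config$tile_cutoff)$fraction_positive, numeric(1))
    lab <- as.numeric(vm$label[match(names(fr), vm$slide_id)] == "positive")
    sel <- select_threshold(fr, lab)
    slide_metrics <- compute_metrics(fr, lab, sel$gamma, level = "slide")
    roc <- if (length(unique(lab)) > 1L) roc_and_auc(fr, lab) else NULL
    ci <- if (config$n_boot > 0 && length(fr) >= 2L) {
      gm <- sel$gamma
      list(f1 = bootstrap_ci(function(f, y)
             compute_metrics(f, y, gm)$f1, fr, lab,
             n_boot = config$n_boot,
             seed = derive_seed(config$seed, paste0("boot_", set_name))),
           accuracy = bootstrap_ci(function(f, y)
             compute_metrics(f, y, gm)$accuracy, fr, lab,
             n_boot = config$n_boot,
             seed = derive_seed(config$seed, paste0("boota_", set_name))))
    } else NULL
    per_set[[set_name]] <- list(
      fractions = fr, labels = lab, gamma = sel$gamma,
      tile_metrics = tile_metrics, slide_metrics = slide_metrics,
      roc = roc, ci = ci)
  }
  structure(list(arm = config$arm, sets = per_set,
                 n_train_tiles = length(tr$tiles),
                 provenance = list(seed = config$seed,
                                   epochs = cfg_train$epochs,
                                   model = cfg_train$model,
                                   version = as.character(
                                     utils::packageVersion("stainpipe")))),
            class = "arm_report")
}

#' Desk-scale cross-scanner replication of the three-arm experiment
#'
#' Builds a synthetic world with a base virtual scanner and a strongly
#' shifted one (20 degree stain-column rotation plus a cold background tint),
#' renders a training set and a validation set under the base profile, and
#' re-renders the same validation geometry ("rescans") under the shifted
#' profile. Each requested arm is trained on the base training set and
#' evaluated on both validation renders. The qualitative expectation mirrors
#' the cross-scanner finding: the unprocessed arm collapses on the shifted
#' scanner while the stain-normalized arm largely retains its performance.
#'
#' @param seed master seed for the whole replication
#' @param arms which arms to run (default NP and SN)
#' @param epochs training epochs of the desk-scale backend
#' @param n_train_pos,n_train_neg,n_val_pos,n_val_neg slide counts
#' @param slide_px slide side in pixels
#' @param shift_degrees stain-column rotation of the shifted scanner
#' @param background_delta background tint of the shifted scanner
#' @return named list per arm, each with `same` and `shifted` slide-level
#'   `metrics_report`s plus the arm's full `arm_report`
#' @export
run_shift_replication <- function(seed, arms = c("NP", "SN"), epochs = 12L,
                                  n_train_pos = 5L, n_train_neg = 5L,
                                  n_val_pos = 4L, n_val_neg = 4L,
                                  slide_px = 448L, shift_degrees = 20,
                                  background_delta = c(-20, -12, -4)) {
  tmpl <- slide_params(height = slide_px, width = slide_px)
  base <- scanner_profile(name = "base")
  shifted <- shift_profile(base, shift_degrees,
                           background_delta = background_delta,
                           name = "shifted")
  train_ds <- generate_dataset(n_train_pos, n_train_neg, tmpl, base,
                               seed = derive_seed(seed, "train"),
                               prefix = "tr")
  val_ds <- generate_dataset(n_val_pos, n_val_neg, tmpl, base,
                             seed = derive_seed(seed, "val"), prefix = "va")
  # virtual rescans: same geometry seeds, shifted rendering
  sh_slides <- list()
  for (i in seq_along(val_ds$slides)) {
    sl <- val_ds$slides[[i]]
    p <- tmpl; p$label <- sl$label; p$seed <- sl$seed
    sh_slides[[paste0(names(val_ds$slides)[i], "_sh")]] <-
      generate_slide(p, shifted)
  }
  man_sh <- val_ds$manifest
  man_sh$slide_id <- paste0(man_sh$slide_id, "_sh")
  man_sh$profile <- "shifted"
  slides <- c(train_ds$slides, val_ds$slides, sh_slides)
  vals <- list(same = val_ds$manifest, shifted = man_sh)
  out <- list()
  for (arm in arms) {
    cfg <- experiment_config(arm = arm, seed = seed, n_boot = 0L,
                             train = train_config(epochs = epochs,
                                                  learning_rate = 1e-2,
                                                  seed = seed))
    rep <- run_arm(cfg, slides, train_ds$manifest, vals)
    out[[arm]] <- list(same = rep$sets$same$slide_metrics,
                       shifted = rep$sets$shifted$slide_metrics,
                       report = rep)
  }
  out
}

#' Save a 10 x 10 (or near-square) QA grid of tiles as JPEG
#'
#' The first `n` tiles (or all, if fewer) are arranged row-major on a
#' ceil(sqrt(n)) grid; unused cells stay white.
#'
#' @param tiles list of tiles (or bare [rgb_image()]s)
#' @param path output JPEG path
#' @param n grid capacity (default 100)
#' @return the grid dimensions, invisibly
#' @export
export_qa_grid <- function(tiles, path, n = 100L) {
  if (!length(tiles))
    stop_stainpipe("invalid_input", "no tiles to export")
  tiles <- tiles[seq_len(min(n, length(tiles)))]
  pix <- lapply(tiles, function(t) if (is_rgb_image(t)) t else t$pixels)
  side <- dim(pix[[1]])[1]
  k <- ceiling(sqrt(length(pix)))
  canvas <- array(1, c(k * side, k * side, 3L))
  for (i in seq_along(pix)) {
    r <- (i - 1) %/% k; c_ <- (i - 1) %% k
    canvas[(r * side + 1):((r + 1) * side),
           (c_ * side + 1):((c_ + 1) * side), ] <-
      unclass(pix[[i]]) / img_i0(pix[[i]])
  }
  jpeg::writeJPEG(canvas, path, quality = 0.9)
  invisible(c(k, k))
}

#' Serialize an arm report to JSON
#' @param report an `arm_report`
#' @param path file path
#' @export
write_arm_report <- function(report, path) {
  strip <- function(m) m[setdiff(names(m), "undefined")]
  obj <- list(arm = report$arm, n_train_tiles = report$n_train_tiles,
              provenance = report$provenance,
              sets = lapply(report$sets, function(s) list(
                gamma = s$gamma,
                slide = strip(unclass(s$slide_metrics)),
                tile = strip(unclass(s$tile_metrics)),
                auc = if (!is.null(s$roc)) s$roc$auc else NULL,
                ci = s$ci)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
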