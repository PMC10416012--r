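# classifier contract, slide aggregation, threshold, metrics, ROC, bootstrap

make_color_tiles <- function(n_per_class, seed, side = 32) {
  # classes differ in mean hue: class 1 tiles are bluish-purple (nuclei-rich),
  # class 0 pinkish -- linearly separable by the colour features
  withr::with_seed(seed, {
    tiles <- list(); labels <- numeric(0)
    for (i in seq_len(2 * n_per_class)) {
      y <- as.numeric(i > n_per_class)
      base <- if (y == 1) c(140, 120, 190) else c(230, 170, 190)
      px <- array(rep(base, each = side * side), c(side, side, 3)) +
        array(rnorm(side * side * 3, 0, 12), c(side, side, 3))
      tiles[[i]] <- rgb_image(pmin(pmax(px, 0), 255))
      labels <- c(labels, y)
    }
    list(tiles = tiles, labels = labels)
  })
}

test_that("the default backend learns colour-separable classes", {
  d <- make_color_tiles(30, seed = 5)
  ho <- make_color_tiles(20, seed = 6)
  cfg <- train_config(epochs = 5, learning_rate = 1e-2, seed = 11)
  model <- train_tile_classifier(d$tiles, d$labels, cfg)
  acc <- mean((score_tiles(model, ho$tiles) > 0.5) == (ho$labels == 1))
  expect_gte(acc, 0.95)
  # same config, trained twice: identical held-out scores
  model2 <- train_tile_classifier(d$tiles, d$labels, cfg)
  expect_identical(score_tiles(model, ho$tiles), score_tiles(model2, ho$tiles))
  # single class refuses to train
  expect_error(train_tile_classifier(d$tiles, rep(1, length(d$tiles)), cfg),
               class = "degenerate_labels")
})

test_that("classifier handles survive a save/load round trip", {
  d <- make_color_tiles(10, seed = 8)
  model <- train_tile_classifier(d$tiles, d$labels,
                                 train_config(epochs = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(model, path)
  re <- load_classifier(path)
  expect_equal(score_tiles(re, d$tiles), score_tiles(model, d$tiles),
               tolerance = 1e-12)
})

test_that("slide scores are positive-tile fractions with a strict cutoff", {
  expect_equal(slide_score(c(0.9, 0.8, 0.2))$fraction_positive, 2 / 3)
  expect_equal(slide_score(rep(0, 5))$fraction_positive, 0)
  # scores exactly at the cutoff count negative
  expect_equal(slide_score(c(0.5, 0.6))$fraction_positive, 1 / 2)
  expect_error(slide_score(numeric(0)), class = "no_tiles")
})

test_that("threshold selection matches a dense-grid oracle", {
  # worked example: positives at 0.8/0.6, negative at 0.1
  sel <- select_threshold(c(0.8, 0.6, 0.1), c(1, 1, 0))
  expect_equal(sel$gamma, 0.35)
  expect_equal(sel$accuracy, 1.0)
  # degenerate: all fractions equal -> majority-class accuracy
  sel2 <- select_threshold(rep(0.4, 5), c(1, 1, 1, 0, 0))
  expect_equal(sel2$accuracy, 3 / 5)
  # random instances vs brute-force dense grid
  withr::with_seed(29, {
    for (i in 1:10) {
      fr <- round(runif(20), 2)
      y <- rbinom(20, 1, 0.5)
      if (length(unique(y)) < 2) y[1] <- 1 - y[1]
      sel <- select_threshold(fr, y)
      grid <- seq(0, 1, by = 1e-3)
      best <- max(vapply(grid, function(g) mean((fr > g) == (y == 1)),
                         numeric(1)))
      expect_equal(sel$accuracy, best, tolerance = 1e-12)
      # returned gamma is the smallest maximizing candidate
      u <- sort(unique(fr))
      cand <- unique(c(0, (u[-1] + u[-length(u)]) / 2, 1))
      accs <- vapply(cand, function(g) mean((fr > g) == (y == 1)), numeric(1))
      expect_equal(sel$gamma, cand[which(accs >= best - 1e-12)[1]])
    }
  })
})

test_that("metrics obey their definitions and flag empty denominators", {
  m <- compute_metrics(c(0.9, 0.8, 0.1, 0.7), c(1, 1, 0, 0), gamma = 0.5)
  expect_equal(m$tp, 2); expect_equal(m$fp, 1)
  expect_equal(m$tn, 1); expect_equal(m$fn, 0)
  expect_equal(m$accuracy, 3 / 4)
  expect_equal(m$f1, 2 * m$sensitivity * m$precision /
                 (m$sensitivity + m$precision))
  # no predicted positives: precision undefined -> 0 with flag
  m0 <- compute_metrics(c(0.1, 0.2), c(1, 0), gamma = 0.9)
  expect_equal(m0$precision, 0)
  expect_true("precision" %in% m0$undefined)
  # internal consistency on random instances
  withr::with_seed(31, {
    for (i in 1:20) {
      fr <- runif(15); y <- rbinom(15, 1, 0.5); g <- runif(1)
      m <- compute_metrics(fr, y, g)
      expect_equal(m$tp + m$fp + m$tn + m$fn, 15)
      if (!length(m$undefined))
        expect_equal(m$f1, 2 * m$sensitivity * m$precision /
                       (m$sensitivity + m$precision))
      expect_true(all(unlist(m[c("accuracy", "sensitivity", "specificity",
                                 "precision", "f1")]) >= 0))
    }
  })
})

test_that("ROC is monotone and AUC equals the Mann-Whitney statistic", {
  # perfect separation -> AUC 1; constant scores -> AUC 0.5
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_and_auc(rep(0.3, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(roc_and_auc(c(0.1, 0.2), c(1, 1)), class = "undefined_roc")
  mw <- function(fr, y) {
    pos <- fr[y == 1]; neg <- fr[y == 0]
    s <- 0
    for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
  }
  withr::with_seed(37, {
    for (i in 1:10) {
      fr <- sample(seq(0, 1, by = 0.1), 15, replace = TRUE)
      y <- rbinom(15, 1, 0.5)
      if (length(unique(y)) < 2) y[1] <- 1 - y[1]
      roc <- roc_and_auc(fr, y)
      expect_equal(roc$auc, mw(fr, y), tolerance = 1e-12)
      expect_true(all(diff(roc$fpr) >= 0), info = "fpr monotone")
      expect_true(all(diff(roc$tpr) >= 0), info = "tpr monotone")
      expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
      expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]),
                   c(1, 1))
      # invariance under strictly monotone transforms
      expect_equal(roc_and_auc(plogis(3 * fr - 1), y)$auc, roc$auc)
    }
  })
})

test_that("bootstrap intervals are seeded, degenerate-safe, and calibrated", {
  # constant metric -> zero width; same seed -> identical
  fr <- rep(0.7, 6); y <- rep(c(1, 0), 3)
  ci <- bootstrap_ci(function(f, yy) mean(f), fr, y, n_boot = 50, seed = 4)
  expect_equal(ci$lower, ci$upper)
  ci2 <- bootstrap_ci(function(f, yy) mean(f > 0.5 & yy == 1), fr, y,
                      n_boot = 200, seed = 9)
  ci3 <- bootstrap_ci(function(f, yy) mean(f > 0.5 & yy == 1), fr, y,
                      n_boot = 200, seed = 9)
  expect_identical(ci2, ci3)
  # coverage: accuracy of a predictor corrupted at rate 0.2, true value 0.8
  acc_metric <- function(f, yy) mean((f > 0.5) == (yy == 1))
  n <- 200
  hits <- vapply(1:200, function(r) {
    withr::with_seed(5000 + r, {
      y <- rbinom(n, 1, 0.5)
      pred <- ifelse(runif(n) < 0.2, 1 - y, y)  # 80% correct
      f <- ifelse(pred == 1, 0.9, 0.1)
    })
    ci <- bootstrap_ci(acc_metric, f, y, n_boot = 300, seed = 6000 + r)
    ci$lower <= 0.8 && 0.8 <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})
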