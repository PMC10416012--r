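# tiling: magnification, Otsu, sliding window, augmentation

test_that("rescaling is the block-mean of the native scan", {
  withr::with_seed(3, {
    img <- rgb_image(array(runif(40 * 40 * 3, 0, 255), c(40, 40, 3)))
  })
  # identity at matching power
  expect_identical(unclass(rescale_to_magnification(img, 10)), unclass(img))
  # brute-force block-mean oracle at x40 -> x10 (factor 4) and x20 (factor 2)
  for (nat in c(40, 20)) {
    f <- nat / 10
    out <- rescale_to_magnification(img, nat)
    expect_equal(dim(out)[1:2], c(40 / f, 40 / f))
    oracle <- array(0, dim(out))
    for (i in seq_len(40 / f)) for (j in seq_len(40 / f)) for (ch in 1:3)
      oracle[i, j, ch] <- mean(img[((i - 1) * f + 1):(i * f),
                                   ((j - 1) * f + 1):(j * f), ch])
    expect_equal(unclass(out), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(rescale_to_magnification(img, 25), class = "config_error")
})

test_that("Otsu matches an exhaustive between-class variance scan", {
  brute_otsu <- function(g) {
    g <- round(as.vector(g))
    best <- -Inf; best_t <- NA
    for (t in 0:255) {
      lo <- g[g <= t]; hi <- g[g > t]
      if (!length(lo) || !length(hi)) next
      v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
      if (v > best) { best <- v; best_t <- t }
    }
    best_t + 0.5
  }
  withr::with_seed(9, {
    for (rep in 1:5) {
      g <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = (1:256)^(rep / 3)), 20, 20)
      expect_equal(otsu_threshold(g), brute_otsu(g))
    }
  })
  # bimodal sanity: left half 50, right half 250 -> mask is the left half
  img <- rgb_image(array(rep(c(50, 250), each = 10 * 10), c(10, 20, 3)))
  mask <- segment_tissue(img)
  expect_identical(mask, cbind(matrix(TRUE, 10, 10), matrix(FALSE, 10, 10)))
  # near-constant image -> empty mask
  white <- rgb_image(array(255, c(8, 8, 3)))
  expect_identical(segment_tissue(white), matrix(FALSE, 8, 8))
})

test_that("tile grids follow the stride arithmetic", {
  p <- plan_tiles(448, 448, 224, 112)
  expect_equal(nrow(p), 9)
  expect_equal(p$row[1:3], c(0, 0, 0))      # row-major
  expect_equal(p$col[1:3], c(0, 112, 224))
  expect_equal(nrow(plan_tiles(200, 200, 224, 112)), 0)
  # brute-force enumeration oracle
  brute <- function(h, w, size, stride) {
    n <- 0
    for (r in seq(0, h, by = stride)) for (c in seq(0, w, by = stride))
      if (r + size <= h && c + size <= w) n <- n + 1
    n
  }
  expect_equal(nrow(plan_tiles(500, 300, 224, 56)), brute(500, 300, 224, 56))
  withr::with_seed(4, {
    for (i in 1:10) {
      h <- sample(100:900, 1); w <- sample(100:900, 1)
      st <- sample(c(56, 112, 224), 1)
      expect_equal(nrow(plan_tiles(h, w, 224, st)), brute(h, w, 224, st))
    }
  })
  # halving the stride at least doubles positions per axis (minus boundary)
  n112 <- nrow(plan_tiles(900, 900, 224, 112))
  n56 <- nrow(plan_tiles(900, 900, 224, 56))
  expect_gte(sqrt(n56), 2 * sqrt(n112) - 1)
})

test_that("tissue filtering equals the brute-force window mean", {
  withr::with_seed(13, {
    img <- rgb_image(array(runif(300 * 260 * 3, 0, 255), c(300, 260, 3)))
    mask <- matrix(runif(300 * 260) < 0.12, 300, 260)
  })
  spec <- tile_spec(tile_size = 64L, stride_inference = 32L,
                    training_tile_size = 96L, stride_training = 16L)
  tiles <- extract_tiles(img, mask, spec, "inference", "s1")
  pos <- plan_tiles(300, 260, 64, 32)
  oracle_frac <- mapply(function(r, c)
    mean(mask[(r + 1):(r + 64), (c + 1):(c + 64)]), pos$row, pos$col)
  kept <- which(oracle_frac >= 0.10)
  expect_equal(length(tiles), length(kept))
  expect_equal(vapply(tiles, `[[`, 0, "tissue_fraction"), oracle_frac[kept],
               tolerance = 1e-12)
  expect_equal(vapply(tiles, `[[`, 0, "row"), pos$row[kept])
  # boundary convention: a window with exactly 10.0% tissue is retained
  spB <- tile_spec(tile_size = 40L, stride_inference = 40L,
                   training_tile_size = 40L, stride_training = 40L)
  mB <- matrix(FALSE, 40, 40); mB[1:16, 1:10] <- TRUE   # 160/1600 = 0.10
  imgB <- rgb_image(array(0, c(40, 40, 3)))
  expect_length(extract_tiles(imgB, mB, spB, "inference"), 1L)
  mB[16, 10] <- FALSE                                    # 159/1600 < 0.10
  expect_length(extract_tiles(imgB, mB, spB, "inference"), 0L)
  # all-false mask -> no tiles; shape mismatch -> error
  expect_length(extract_tiles(img, matrix(FALSE, 300, 260), spec), 0L)
  expect_error(extract_tiles(img, matrix(FALSE, 10, 10), spec),
               class = "invalid_input")
})

test_that("rotation crops exactly and right-angle paths are lossless", {
  withr::with_seed(17, {
    t316 <- rgb_image(array(runif(316 * 316 * 3, 0, 255), c(316, 316, 3)))
  })
  # angle 0: exact centre crop
  out0 <- rotate_and_crop(t316, 0)
  off <- (316 - 224) %/% 2
  expect_equal(unclass(out0), unclass(t316)[(off + 1):(off + 224),
                                            (off + 1):(off + 224), ],
               ignore_attr = TRUE)
  # angle 90: index-permutation oracle (counter-clockwise: transpose + flip)
  out90 <- rotate_and_crop(t316, 90)
  rot90 <- function(m) t(m)[nrow(m):1, ]
  oracle <- unclass(out0)
  for (ch in 1:3) oracle[, , ch] <- rot90(unclass(out0)[, , ch])
  expect_equal(unclass(out90), oracle, tolerance = 1e-12)
  # oblique angles keep size, range, and at most a sub-pixel corner fringe
  dark <- rgb_image(array(10, c(316, 316, 3)))
  for (ang in c(45, 133.3, 287)) {
    out <- rotate_and_crop(dark, ang)
    expect_equal(dim(out), c(224L, 224L, 3L))
    expect_true(all(out >= 0 & out <= 255))
    # white fill can only touch the four extreme corners (316 vs 224*sqrt2)
    fill <- sum(unclass(out)[, , 1] > 200)
    expect_lte(fill, 8)
  }
  expect_error(rotate_and_crop(out0, 45), class = "invalid_input")
})

test_that("reflection is seeded, involutive, and calibrated", {
  withr::with_seed(19, {
    tile <- rgb_image(array(runif(12 * 12 * 3, 0, 255), c(12, 12, 3)))
  })
  expect_identical(unclass(maybe_reflect(tile, p = 0)), unclass(tile))
  once <- maybe_reflect(tile, p = 1)
  expect_identical(unclass(maybe_reflect(once, p = 1)), unclass(tile))
  expect_false(identical(unclass(once), unclass(tile)))
  # p = 0.5 over 10,000 seeded draws: within 3 binomial SEs
  flips <- withr::with_seed(23, {
    tiny <- rgb_image(array(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
                            c(2, 2, 3)))
    vapply(1:10000, function(i)
      !identical(unclass(maybe_reflect(tiny, 0.5)), unclass(tiny)),
      logical(1))
  })
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(flips) - 0.5), 3 * se)
})
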