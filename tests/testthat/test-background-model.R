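test_that("gaussianDensity matches the closed form and is symmetric", {
  expect_equal(gaussianDensity(0, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gaussianDensity(1, 0, 1), exp(-0.5) / sqrt(2 * pi),
               tolerance = 1e-12)
  for (a in c(0.5, 1.7, 30))
    expect_equal(gaussianDensity(10 + a, 10, 7), gaussianDensity(10 - a, 10, 7))
  expect_error(gaussianDensity(0, 0, 0), "sigma2")
})

test_that("initMixture starts one full-weight component per pixel", {
  fr <- matrix(100L, 6, 5)
  p <- backgroundParams(bgt = 0.7)
  st <- initMixture(fr, p)
  expect_equal(st@weight[, 1L], rep(1, 30))
  expect_equal(st@mean[, 1L], rep(100, 30))
  expect_equal(rowSums(st@weight), rep(1, 30))
  one <- initMixture(matrix(7L, 1, 1), p)
  expect_identical(dim(one@weight), c(1L, 3L))
  expect_identical(st, initMixture(fr, p))   # deterministic
})

test_that("a static scene is absorbed into the background", {
  fr <- matrix(80L, 20, 20)
  p <- backgroundParams(bgt = 0.5, burnInFrames = 10L)
  st <- initMixture(fr, p)
  for (i in 1:10) {
    res <- updateAndClassify(st, fr, p)
    st <- res$state
  }
  expect_lt(mean(res$mask), 0.01)
})

test_that("a large intensity jump is classified foreground", {
  p <- backgroundParams(bgt = 0.5, initialVariance = 225)
  st <- initMixture(matrix(100L, 1, 1), p)
  for (i in 1:50) st <- updateAndClassify(st, matrix(100L, 1, 1), p)$state
  res <- updateAndClassify(st, matrix(255L, 1, 1), p)
  expect_identical(res$mask[1L, 1L], 1L)
})

test_that("per-pixel weights sum to 1 after every update", {
  set.seed(31)
  p <- backgroundParams(bgt = 0.6)
  st <- initMixture(matrix(sample(0:255, 100, TRUE), 10, 10), p)
  for (i in 1:25) {
    fr <- matrix(sample(0:255, 100, TRUE), 10, 10)
    st <- updateAndClassify(st, fr, p)$state
    expect_equal(rowSums(st@weight), rep(1, 100), tolerance = 1e-12)
    expect_true(all(st@var >= p@varianceFloor))
  }
})

test_that("noiseless constant video yields empty masks for any bgt <= 0.9", {
  fr <- matrix(60L, 15, 15)
  for (bgt in seq(0.1, 0.9, by = 0.2)) {
    p <- backgroundParams(bgt = bgt)
    st <- initMixture(fr, p)
    for (i in 1:5) {
      res <- updateAndClassify(st, fr, p)
      st <- res$state
      expect_identical(sum(res$mask), 0L)
    }
  }
})

test_that("an object moving a full diameter per frame is always foreground", {
  p <- backgroundParams(bgt = 0.5, burnInFrames = 10L)
  nr <- 30L; nc <- 120L
  bg <- matrix(50L, nr, nc)
  st <- initMixture(bg, p)
  for (i in 1:10) st <- updateAndClassify(st, bg, p)$state
  # 6-px-wide square stepping 8 px per frame over learned background
  for (k in 0:8) {
    fr <- bg
    c0 <- 5L + 8L * k
    fr[13:18, c0:(c0 + 5L)] <- 220L
    res <- updateAndClassify(st, fr, p)
    st <- res$state
    expect_identical(sum(res$mask[13:18, c0:(c0 + 5L)]), 36L)
  }
})

test_that("the mixture model is deterministic on identical input", {
  cfg <- synthConfig(width = 80L, height = 60L, nFrames = 12L, nMotile = 2L,
                     nImmotile = 1L, nDebris = 2L,
                     headSemiAxesRange = c(4, 6), seed = 13L)
  fs <- generateVideo(cfg)$frames
  p <- backgroundParams(bgt = 0.3)
  run <- function() {
    st <- initMixture(frames(fs)[[1L]], p)
    masks <- list()
    for (t in 2:nFrames(fs)) {
      res <- updateAndClassify(st, frames(fs)[[t]], p)
      st <- res$state
      masks[[t]] <- res$mask
    }
    list(st = st, masks = masks)
  }
  expect_identical(run(), run())
})

test_that("a single-element grid is returned unconditionally", {
  cfg <- synthConfig(width = 80L, height = 60L, nFrames = 12L, nMotile = 1L,
                     nImmotile = 0L, nDebris = 0L,
                     headSemiAxesRange = c(4, 6), seed = 8L)
  fs <- generateVideo(cfg)$frames
  p <- backgroundParams(burnInFrames = 10L, grid = 0.5)
  opt <- optimizeBackgroundThreshold(fs, p)
  expect_identical(opt@bgt, 0.5)
})

test_that("the optimized bgt attains the maximal detection count", {
  cfg <- synthConfig(width = 260L, height = 200L, nFrames = 30L,
                     nMotile = 3L, nImmotile = 1L, nDebris = 5L,
                     speedRange = c(2, 3.5), border = "reflect", seed = 21L)
  fs <- generateVideo(cfg)$frames
  p <- backgroundParams(burnInFrames = 20L)
  opt <- optimizeBackgroundThreshold(fs, p)
  counts <- attr(opt, "gridCounts")
  # brute force: re-evaluate every grid value with a fresh model
  brute <- vapply(p@grid, function(g) {
    pg <- p; pg@bgt <- g
    res <- SpermMotility:::burnInAndClassify(fs, pg, p@burnInFrames)
    nrow(detectFrame(res$mask, frameIndex = p@burnInFrames + 1L))
  }, numeric(1L))
  expect_equal(unname(counts), brute)
  expect_equal(counts[[sprintf("%.2f", opt@bgt)]], max(brute))
  # ties break toward the smallest grid value
  expect_identical(opt@bgt, p@grid[which(brute == max(brute))[1L]])
})

test_that("errors: too few frames, unset bgt, shape mismatch", {
  cfg <- synthConfig(width = 40L, height = 30L, nFrames = 5L, nMotile = 0L,
                     nImmotile = 0L, nDebris = 0L,
                     headSemiAxesRange = c(4, 6), seed = 1L)
  fs <- generateVideo(cfg)$frames
  expect_error(optimizeBackgroundThreshold(fs, backgroundParams()),
               "burnInFrames")
  p <- backgroundParams()   # bgt NA
  st <- initMixture(matrix(0L, 3, 3), p)
  expect_error(updateAndClassify(st, matrix(0L, 3, 3), p), "bgt")
  p2 <- backgroundParams(bgt = 0.5)
  expect_error(updateAndClassify(st, matrix(0L, 4, 3), p2), "dimensions")
})
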