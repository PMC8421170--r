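test_that("empty scene renders a constant raster at the background level", {
  cfg <- synthConfig(width = 40L, height = 30L, nFrames = 4L, nMotile = 0L,
                     nImmotile = 0L, nDebris = 0L, noiseSigma = 0, seed = 1L)
  out <- generateVideo(cfg)
  for (f in frames(out$frames))
    expect_true(all(f == 60L))
  expect_identical(nrow(groundTruthTable(out$groundTruth)), 0L)
})

test_that("ground truth contains exactly the configured objects", {
  cfg <- synthConfig(width = 320L, height = 240L, nFrames = 10L,
                     nMotile = 5L, nImmotile = 2L, nDebris = 3L,
                     headSemiAxesRange = c(5, 8), seed = 1L)
  gt <- groundTruthTable(generateVideo(cfg)$groundTruth)
  ids <- unique(gt[, c("id", "class")])
  expect_identical(sum(ids$class == "motile"), 5L)
  expect_identical(sum(ids$class == "immotile"), 2L)
  expect_identical(sum(ids$class == "debris"), 3L)
  # immotile and debris never move; motile objects do
  for (i in ids$id[ids$class != "motile"]) {
    sub <- gt[gt$id == i, ]
    expect_equal(diff(range(sub$x)), 0)
    expect_equal(diff(range(sub$y)), 0)
  }
  for (i in ids$id[ids$class == "motile"]) {
    sub <- gt[gt$id == i, ]
    expect_gt(max(abs(sub$x - sub$x[1L])) + max(abs(sub$y - sub$y[1L])), 0)
  }
})

test_that("constant-velocity kinematics are exact in the ground truth", {
  init <- data.frame(x = 60, y = 60, speed = 3, heading = 0.3)
  cfg <- synthConfig(width = 400L, height = 300L, nFrames = 15L,
                     nMotile = 1L, nImmotile = 0L, nDebris = 0L,
                     noiseSigma = 0, motileInit = init, seed = 2L)
  gt <- groundTruthTable(generateVideo(cfg)$groundTruth)
  p1 <- gt[gt$frame == 1L, c("x", "y")]
  p11 <- gt[gt$frame == 11L, c("x", "y")]
  expect_equal(sqrt(sum((p11 - p1)^2)), 30, tolerance = 1e-12)
})

test_that("identical configs give bit-identical frames and ground truth", {
  cfg <- synthConfig(width = 80L, height = 60L, nFrames = 6L, nMotile = 2L,
                     nImmotile = 1L, nDebris = 2L,
                     headSemiAxesRange = c(4, 6), seed = 7L)
  a <- generateVideo(cfg)
  b <- generateVideo(cfg)
  expect_identical(frames(a$frames), frames(b$frames))
  expect_identical(groundTruthTable(a$groundTruth),
                   groundTruthTable(b$groundTruth))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(generateVideo(synthConfig(width = 40L, height = 30L,
                                      nFrames = 2L, nMotile = 1L,
                                      nImmotile = 0L, nDebris = 0L,
                                      headSemiAxesRange = c(4, 6),
                                      seed = 5L)))
  expect_identical(runif(1), r1)
})

test_that("per-frame object counts follow the configuration (conservation)", {
  cfg <- synthConfig(width = 200L, height = 150L, nFrames = 12L,
                     nMotile = 3L, nImmotile = 2L, nDebris = 4L,
                     headSemiAxesRange = c(4, 6), border = "reflect",
                     seed = 3L)
  gt <- groundTruthTable(generateVideo(cfg)$groundTruth)
  for (f in seq_len(12L))
    expect_identical(nrow(gt[gt$frame == f, ]), 9L)  # reflect: none exit
})

test_that("objects exit permanently under the exit border rule", {
  init <- data.frame(x = 380, y = 150, speed = 5, heading = 0)
  cfg <- synthConfig(width = 400L, height = 300L, nFrames = 30L,
                     nMotile = 1L, nImmotile = 0L, nDebris = 0L,
                     border = "exit", noiseSigma = 0, motileInit = init,
                     seed = 4L)
  gt <- groundTruthTable(generateVideo(cfg)$groundTruth)
  present <- sort(unique(gt$frame))
  expect_lt(max(present), 30L)                       # it left
  expect_identical(present, seq_len(max(present)))   # and never came back
})

test_that("rendered ellipse pixel area tracks pi*a*b within 15 percent", {
  set.seed(11)
  for (k in 1:25) {
    a <- runif(1, 3, 12); b <- runif(1, 3, a); th <- runif(1, 0, pi)
    idx <- SpermMotility:::rasterEllipse(40 + runif(1), 40 + runif(1),
                                         a, b, th, 90, 90)
    expect_lt(abs(length(idx) - pi * a * b) / (pi * a * b), 0.15)
  }
})

test_that("ground truth JSON round-trips exactly", {
  cfg <- synthConfig(width = 120L, height = 90L, nFrames = 5L, nMotile = 2L,
                     nImmotile = 1L, nDebris = 2L,
                     headSemiAxesRange = c(4, 6), seed = 9L)
  gt <- generateVideo(cfg)$groundTruth
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeGroundTruth(gt, f1)
  back <- readGroundTruth(f1)
  expect_equal(groundTruthTable(back), groundTruthTable(gt))
  expect_equal(fps(back), fps(gt))
  writeGroundTruth(gt, f2)                     # double write: same bytes
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # empty ground truth still round-trips
  e <- new("GroundTruth",
           tracks = data.frame(id = integer(0), class = character(0),
                               frame = integer(0), x = numeric(0),
                               y = numeric(0), area = integer(0)),
           fps = 50)
  f3 <- tempfile(fileext = ".json")
  writeGroundTruth(e, f3)
  expect_identical(nrow(groundTruthTable(readGroundTruth(f3))), 0L)
})

test_that("impossible geometry is rejected", {
  expect_error(synthConfig(width = 10L, height = 10L,
                           headSemiAxesRange = c(8, 11)),
               "impossible geometry")
  expect_error(synthConfig(debrisAreaMax = 200), "150")
})
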