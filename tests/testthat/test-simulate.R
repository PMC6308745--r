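test_that("ground-truth ratio follows the configured concentration response", {
  sc <- makeStripScene(concentration = 0)
  expect_equal(groundTruthRatio(sc), 1.0449)

  sc@concentration <- 10
  expect_equal(groundTruthRatio(sc), 1.2009)   # 1.0449 + 0.0156 * 10

  # langmuir reduces to linear as the saturation constant grows
  lang <- makeStripScene(response = list(mode = "langmuir", a = 1.0449,
                                         b = 0.0156, K = 1e12))
  lin <- makeStripScene()
  for (cc in c(0, 2, 4, 10, 50, 100)) {
    lang@concentration <- cc; lin@concentration <- cc
    expect_equal(groundTruthRatio(lang), groundTruthRatio(lin),
                 tolerance = 1e-6)
  }

  # saturating form evaluated directly
  lg <- makeStripScene(response = list(mode = "langmuir", a = 1.0449,
                                       b = 0.0156, K = 100),
                       concentration = 50)
  expect_equal(groundTruthRatio(lg), 1 + (0.0449 + 0.78) / 1.5)
})

test_that("scene validity enforces geometry", {
  expect_error(makeStripScene(testLineCenterPx = 300L,
                              controlLineCenterPx = 150L), "upstream")
  expect_error(makeStripScene(testLineCenterPx = 4L, lineWidthPx = 12L),
               "outside")
  expect_error(makeStripScene(concentration = -1), "concentration")
})

test_that("rendering encodes the target ratio and is linear in gain", {
  # blank strip with unit intercept: test region indistinguishable from bg
  sc <- smallScene(response = list(mode = "linear", a = 1, b = 0.0156,
                                   K = 100))
  img <- renderScene(sc, quietSensor())
  expect_equal(img[, 40, 2], img[, 10, 2], tolerance = 1e-12)
  # only the control-line columns depart from the background
  offControl <- img[, , 2][, -(87:94)]
  expect_equal(max(offControl), min(offControl), tolerance = 1e-12)

  # doubling illumination gain doubles every pre-quantization value
  sc2 <- smallScene(concentration = 10)
  i1 <- renderScene(sc2, quietSensor(gain = 0.4))
  i2 <- renderScene(sc2, quietSensor(gain = 0.8))
  expect_equal(i2, 2 * i1, tolerance = 1e-12)

  # background channel values match a dense-quadrature oracle
  img10 <- renderScene(sc2, quietSensor(gain = 1))
  for (i in 1:3) {
    ctr <- c(613, 537, 456)[i]
    oracle <- riemannChannelValue(function(lam) rep(0.95, length(lam)), ctr)
    expect_equal(unname(img10[5, 5, i]), oracle, tolerance = 1e-4)
  }

  # the green-channel background/test means reproduce the target exactly
  sensor <- quietSensor()
  r <- groundTruthRatio(sc2)
  g <- renderScene(sc2, sensor)[, , 2]
  expect_equal(mean(g[, 5:20]) / mean(g[, 37:44]), r, tolerance = 1e-12)
})

test_that("gold scenes darken green most; iron oxide darkens blue most", {
  for (cc in c(2, 10, 100)) {
    img <- renderScene(smallScene(concentration = cc), quietSensor())
    contrast <- vapply(1:3, function(i)
      1 - mean(img[, 37:44, i]) / mean(img[, 5:20, i]), numeric(1))
    expect_true(contrast[2] > contrast[1])  # green > red
    expect_true(contrast[2] > contrast[3])  # green > blue
  }
  ironScene <- smallScene(concentration = 100,
                          label = makeLabelModel("iron_oxide"))
  img <- renderScene(ironScene, quietSensor())
  contrast <- vapply(1:3, function(i)
    1 - mean(img[, 37:44, i]) / mean(img[, 5:20, i]), numeric(1))
  expect_true(contrast[3] > contrast[1] && contrast[3] > contrast[2])
})

test_that("RGGB mosaic and native demosaic match hand-computed values", {
  # 4x4 colour image with distinct per-channel values
  h <- 4L; w <- 4L
  img <- array(0, c(h, w, 3))
  img[, , 1] <- matrix(1:16 / 100, h, w)         # red
  img[, , 2] <- matrix(1:16 / 100 + 0.3, h, w)   # green
  img[, , 3] <- matrix(1:16 / 100 + 0.6, h, w)   # blue
  m <- mosaicImage(img)
  d <- pixelData(m)
  # R sites at odd (row, col); B at even; G mixed (RGGB, R at (1,1))
  expect_equal(d[1, 1], img[1, 1, 1])
  expect_equal(d[3, 3], img[3, 3, 1])
  expect_equal(d[2, 2], img[2, 2, 3])
  expect_equal(d[1, 2], img[1, 2, 2])
  expect_equal(d[2, 1], img[2, 1, 2])

  pl <- demosaicPlanes(m)
  # per 2x2 cell: R from its site, B from its site, G = mean of two sites
  expect_equal(pixelData(pl$red), img[c(1, 3), c(1, 3), 1])
  expect_equal(pixelData(pl$blue), img[c(2, 4), c(2, 4), 3])
  gOracle <- (img[c(1, 3), c(2, 4), 2] + img[c(2, 4), c(1, 3), 2]) / 2
  expect_equal(pixelData(pl$green), gOracle)

  # constant-green input: green plane constant and equal to the input
  cg <- array(0, c(4, 4, 3)); cg[, , 2] <- 0.42
  expect_equal(unique(as.vector(pixelData(demosaicPlanes(mosaicImage(cg))$green))),
               0.42)

  # round trip is exact on per-2x2-cell-constant images
  blocky <- array(0, c(4, 4, 3))
  for (i in 1:3) blocky[, , i] <- kronecker(matrix(runif(4), 2, 2),
                                            matrix(1, 2, 2)) * 0.9
  pl2 <- demosaicPlanes(mosaicImage(blocky))
  expect_equal(pixelData(pl2$red), blocky[c(1, 3), c(1, 3), 1])
  expect_equal(pixelData(pl2$green), blocky[c(1, 3), c(1, 3), 2])
  expect_equal(pixelData(pl2$blue), blocky[c(1, 3), c(1, 3), 3])

  expect_error(mosaicImage(array(0, c(3, 4, 3))), "even")
})

test_that("bilinear demosaic reconstructs smooth fields", {
  # a linear ramp is reproduced exactly by bilinear interpolation (interior)
  h <- 8L; w <- 8L
  ramp <- matrix(rep(seq(0.1, 0.8, length.out = w), each = h), h, w)
  img <- array(0, c(h, w, 3))
  for (i in 1:3) img[, , i] <- ramp
  pl <- demosaicPlanes(mosaicImage(img), mode = "bilinear")
  for (nm in c("red", "green", "blue"))
    expect_equal(pixelData(pl[[nm]])[3:6, 3:6], ramp[3:6, 3:6],
                 tolerance = 1e-10)
})

test_that("noise stage is seeded, unbiased in scale, and quantizes cleanly", {
  sensorQ <- quietSensor()
  m <- mosaicImage(array(0.5, c(6, 6, 3)))
  q <- addNoiseAndQuantize(m, sensorQ)
  expect_true(all(pixelData(q) == round(0.5 * 255)))  # pure quantization
  expect_equal(q@bitDepth, 8L)

  sensorN <- makeSensorModel(shotNoise = 0.004, readNoise = 0.003, seed = 99L)
  big <- mosaicImage(array(0.5, c(100, 100, 3)))
  q1 <- addNoiseAndQuantize(big, sensorN)
  q2 <- addNoiseAndQuantize(big, sensorN)
  expect_identical(pixelData(q1), pixelData(q2))  # same seed, bit-identical

  # flat-field SD over 10^4 pixels matches the configured noise within 5%
  sdConf <- sqrt(0.003^2 + (0.004 * sqrt(0.5))^2)
  sdEst <- sd(pixelData(q1) / 255)
  expect_lt(abs(sdEst - sdConf) / sdConf, 0.05)

  expect_error(addNoiseAndQuantize(matrix(-0.1, 2, 2), sensorQ), "negative")
})

test_that("calibration sets are complete, manifested and reproducible", {
  sc <- smallScene()
  sensor <- makeSensorModel(seed = 5L)
  d1 <- withr::local_tempdir()
  set1 <- generateCalibrationSet(d1, concentrations = c(0, 2, 4, 10, 50, 100),
                                 replicates = 10, scene = sc,
                                 sensor = sensor, seed = 314L)
  expect_equal(nrow(set1$manifest), 60L)
  expect_length(list.files(d1, pattern = "\\.png$"), 60L)
  expect_setequal(names(set1$manifest),
                  c("filename", "concentration_ng_per_ml", "replicate",
                    "seed", "truth_ratio"))
  expect_equal(set1$manifest$truth_ratio[set1$manifest$concentration_ng_per_ml == 10][1],
               1.2009)

  d2 <- withr::local_tempdir()
  set2 <- generateCalibrationSet(d2, concentrations = 4, replicates = 1,
                                 scene = sc, sensor = sensor, seed = 314L)
  expect_equal(nrow(set2$manifest), 1L)

  # identical master seed reproduces identical images, bit for bit
  d3 <- withr::local_tempdir()
  generateCalibrationSet(d3, concentrations = c(0, 2), replicates = 2,
                         scene = sc, sensor = sensor, seed = 271L)
  d4 <- withr::local_tempdir()
  generateCalibrationSet(d4, concentrations = c(0, 2), replicates = 2,
                         scene = sc, sensor = sensor, seed = 271L)
  f3 <- list.files(d3, full.names = TRUE)
  f4 <- list.files(d4, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f3)), unname(tools::md5sum(f4)))

  expect_error(generateCalibrationSet(withr::local_tempdir(),
                                      scene = sc, sensor = sensor),
               "seed")
})
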