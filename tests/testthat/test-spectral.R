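test_that("label models place a unit-height unimodal band at the stated centre", {
  gold <- makeLabelModel("gold", 546, 80)
  expect_equal(peakWavelength(gold@extinction), 546)
  expect_equal(max(intensities(gold)), 1)
  expect_equal(intensities(gold)[wavelengths(gold) == 546], 1)

  io <- makeLabelModel("iron_oxide", 487, 120)
  expect_equal(peakWavelength(io@extinction), 487)

  # defaults carry the same band parameters
  expect_equal(makeLabelModel("gold")@bandCenterNm, 546)
  expect_equal(makeLabelModel("iron_oxide")@bandCenterNm, 487)

  expect_error(makeLabelModel("x", 900, 50), "outside")
  expect_error(makeLabelModel("x", 500, -1), "bandWidthNm")
})

test_that("reflectance follows Beer-Lambert attenuation of the membrane", {
  gold <- makeLabelModel("gold")
  mem <- flatSpectrum(0.95)

  # zero concentration leaves the membrane untouched
  expect_identical(intensities(reflectanceSpectrum(gold, 0, mem)),
                   intensities(mem))

  # log-attenuation is linear in concentration
  r1 <- reflectanceSpectrum(gold, 5, mem)
  r2 <- reflectanceSpectrum(gold, 10, mem)
  expect_equal(log(intensities(r2) / intensities(mem)),
               2 * log(intensities(r1) / intensities(mem)), tolerance = 1e-12)

  # pointwise oracle with the Lorentzian written out by hand, k = 1
  unitMem <- flatSpectrum(1)
  r <- reflectanceSpectrum(gold, 1, unitMem, k = 1)
  lam <- wavelengths(r)
  oracle <- exp(-1 / (1 + ((lam - 546) / 40)^2))
  expect_equal(intensities(r), oracle, tolerance = 1e-12)
  expect_equal(intensities(r)[lam == 546], exp(-1), tolerance = 1e-12)

  expect_error(reflectanceSpectrum(gold, -1), "concentration")
})

test_that("difference spectrum subtracts pointwise and is antisymmetric", {
  a <- makeSpectrum(1:5, c(1, 1, 1, 1, 1))
  b <- makeSpectrum(1:5, c(1, .8, .5, .8, 1))
  expect_equal(intensities(differenceSpectrum(a, b)), c(0, .2, .5, .2, 0))
  expect_equal(intensities(differenceSpectrum(a, a)), rep(0, 5))
  expect_equal(intensities(differenceSpectrum(a, b)),
               -intensities(differenceSpectrum(b, a)))
  expect_error(differenceSpectrum(a, makeSpectrum(2:6, rep(1, 5))), "grid")

  # gold at high concentration: difference peaks at the label band centre
  gold <- makeLabelModel("gold")
  d <- differenceSpectrum(flatSpectrum(), reflectanceSpectrum(gold, 100))
  expect_true(all(intensities(d) >= 0))
  expect_equal(peakWavelength(d), 546)
})

test_that("peakWavelength matches a linear-scan oracle and is affine-invariant", {
  s <- makeSpectrum(400:500, c(seq(0, 1, length.out = 101)))
  expect_equal(peakWavelength(s), 500)  # monotone case: last wavelength

  set.seed(41)
  for (i in 1:20) {
    w <- sort(sample(380:780, 50))
    v <- rnorm(50)
    s <- makeSpectrum(w, v)
    # brute-force linear scan
    best <- w[1]; bv <- v[1]
    for (j in seq_along(v)) if (v[j] > bv) { bv <- v[j]; best <- w[j] }
    expect_equal(peakWavelength(s), best)
    # positive affine transform of the values
    expect_equal(peakWavelength(makeSpectrum(w, 2.5 * v + 7)), best)
  }

  expect_warning(pk <- peakWavelength(makeSpectrum(400:410, rep(1, 11))),
                 "degenerate")
  expect_equal(pk, 400)
})

test_that("channel selection follows the label's absorption band", {
  mem <- flatSpectrum()
  dGold <- differenceSpectrum(mem,
                              reflectanceSpectrum(makeLabelModel("gold"), 100))
  selGold <- selectChannel(dGold)
  expect_equal(selGold$channel, "green")
  expect_true(selGold$scores[["green"]] > selGold$scores[["red"]])
  expect_true(selGold$scores[["green"]] > selGold$scores[["blue"]])

  dIron <- differenceSpectrum(
    mem, reflectanceSpectrum(makeLabelModel("iron_oxide"), 100))
  expect_equal(selectChannel(dIron)$channel, "blue")

  # delta spike exactly at the red centre
  grid <- defaultWavelengthGrid()
  spike <- makeSpectrum(grid, as.numeric(grid == 613))
  expect_equal(selectChannel(spike)$channel, "red")

  # all-zero difference carries no signal
  expect_error(selectChannel(makeSpectrum(grid, rep(0, length(grid)))),
               "no signal")
})

test_that("integral scores agree with dense Riemann summation on random unimodal bands", {
  centers <- c(red = 613, green = 537, blue = 456)
  set.seed(7)
  for (i in 1:15) {
    ctr <- runif(1, 430, 670)
    wid <- runif(1, 30, 150)
    diffFun <- function(lam) 1 / (1 + ((lam - ctr) / (wid / 2))^2)
    d <- makeSpectrum(defaultWavelengthGrid(),
                      diffFun(defaultWavelengthGrid()))
    sel <- selectChannel(d)
    oracleScores <- vapply(centers, function(cw) riemannScore(diffFun, cw),
                           numeric(1))
    expect_equal(sel$channel, names(centers)[which.max(oracleScores)])
    expect_equal(unname(sel$scores[names(centers)]), unname(oracleScores),
                 tolerance = 1e-3)
  }
})

test_that("congruent channel translates select the channel nearest the band", {
  set.seed(11)
  for (i in 1:10) {
    ctr <- runif(1, 440, 660)
    # congruent Gaussian channels, identical sigma, well inside the window
    ch <- bayerChannels(centers = c(red = 640, green = 540, blue = 440),
                        sigma = 20)
    d <- makeSpectrum(defaultWavelengthGrid(),
                      exp(-0.5 * ((defaultWavelengthGrid() - ctr) / 15)^2))
    nearest <- c("red", "green", "blue")[
      which.min(abs(c(640, 540, 440) - ctr))]
    expect_equal(selectChannel(d, ch)$channel, nearest)
    expect_equal(selectChannel(d, ch, method = "nearest")$channel, nearest)
  }
})

test_that("packaged channel preset loads and matches the generated curves", {
  p <- system.file("extdata", "bayer_channels_synthetic.csv",
                   package = "lfiaQuant")
  chs <- readChannelResponses(p)
  gen <- bayerChannels()
  for (i in 1:3) {
    expect_equal(channelName(chs[[i]]), channelName(gen[[i]]))
    expect_equal(chs[[i]]@centerNm, gen[[i]]@centerNm)
    expect_equal(intensities(chs[[i]]), intensities(gen[[i]]),
                 tolerance = 1e-5)
  }
  # the preset selects the same channel as the generated curves
  d <- differenceSpectrum(flatSpectrum(),
                          reflectanceSpectrum(makeLabelModel("gold"), 100))
  expect_equal(selectChannel(d, chs)$channel, "green")
})

test_that("spectra round-trip through two-column CSV", {
  s <- makeSpectrum(400:450, runif(51))
  p <- withr::local_tempfile(fileext = ".csv")
  writeSpectrum(s, p)
  s2 <- readSpectrum(p)
  expect_equal(wavelengths(s2), wavelengths(s))
  expect_equal(intensities(s2), intensities(s), tolerance = 1e-12)
  expect_identical(names(utils::read.csv(p)), c("wavelength_nm", "value"))
})
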