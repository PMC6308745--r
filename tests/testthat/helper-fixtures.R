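# shared fixtures and independent oracles

# noiseless sensor for exactness checks
quietSensor <- function(gain = 0.92)
  makeSensorModel(illuminationGain = gain, shotNoise = 0, readNoise = 0)

# small strip scene (even dims, lines inside) for fast rendering
smallScene <- function(concentration = 0, ...)
  makeStripScene(widthPx = 120L, heightPx = 40L, testLineCenterPx = 40L,
                 controlLineCenterPx = 90L, lineWidthPx = 8L,
                 concentration = concentration, ...)

# dense-Riemann oracle for the responsivity-normalised channel integral
# of a spectrum s against a Gaussian channel clipped to 400-700 nm
riemannChannelValue <- function(sFun, center, sigma = 25, step = 0.05) {
  lam <- seq(380, 780, by = step)
  curve <- exp(-0.5 * ((lam - center) / sigma)^2)
  curve[lam < 400 | lam > 700] <- 0
  sum(sFun(lam) * curve) / sum(curve)
}

# dense-Riemann oracle for the un-normalised score integral
riemannScore <- function(diffFun, center, sigma = 25, step = 0.05) {
  lam <- seq(380, 780, by = step)
  curve <- exp(-0.5 * ((lam - center) / sigma)^2)
  curve[lam < 400 | lam > 700] <- 0
  sum(diffFun(lam) * curve) * step
}

# closed-form normal-equation OLS oracle
normalEquationFit <- function(x, y) {
  X <- cbind(1, x)
  drop(solve(t(X) %*% X, t(X) %*% y))
}
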