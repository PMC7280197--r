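test_that("ball, stick, ADC and kurtosis closed forms are correct", {
  expect_equal(ballSignal(0, 2e-9), 1)
  expect_equal(ballSignal(1000, 2e-9), exp(-2))
  expect_error(ballSignal(1000, 0), "positive")
  expect_error(ballSignal(-5, 2e-9), "negative")

  ## stick geometry: orthogonal, parallel, 45 degrees
  b <- 1500; d <- 8e-9
  expect_equal(stickSignal(b, c(1, 0, 0), d, theta = 0, phi = 0), 1)
  expect_equal(stickSignal(b, c(0, 0, 1), d, theta = 0, phi = 0),
               ballSignal(b, d))
  g45 <- c(1, 0, 1) / sqrt(2)
  expect_equal(stickSignal(b, g45, d, theta = 0, phi = 0),
               exp(-b * 1e6 * d / 2))
  expect_error(stickSignal(b, c(1, 1, 0), d, 0, 0), "unit")

  expect_equal(adcSignal(1000, 1e-9), exp(-1))
  expect_equal(kurtosisSignal(1000, 1e-9, 1), exp(-5 / 6))
  ## K = 0 reduces the kurtosis model to the ADC model
  bs <- c(0, 80, 500, 1500, 3000)
  expect_equal(kurtosisSignal(bs, 1.3e-9, 0), adcSignal(bs, 1.3e-9))
})

test_that("GPD sphere signal has the right limits and monotonicity", {
  ## no gradient
  expect_equal(sphereSignal(0, 3e-3, 40e-3, 1e-9, 10), 1)
  ## motional narrowing: tiny sphere barely attenuates even at strong
  ## gradients and long diffusion time
  expect_equal(sphereSignal(gcm(12), 10e-3, 40e-3, 1e-9, 0.1), 1,
               tolerance = 1e-3)
  ## huge sphere approaches free (Gaussian) diffusion
  b <- computeBValue(gcm(10), 3e-3, 10e-3)
  expect_equal(sphereSignal(gcm(10), 3e-3, 10e-3, 1e-9, 100),
               exp(-b * 1e6 * 1e-9), tolerance = 0.02)
  ## decreasing in G and in R over the physiological range
  sG <- sphereSignal(gcm(c(5, 15, 25, 36)), 3e-3, 30e-3, 1e-9, 10)
  expect_true(all(diff(sG) < 0))
  sR <- vapply(c(2, 5, 10, 15), function(R)
    sphereSignal(gcm(21.6), 3e-3, 30e-3, 1e-9, R), numeric(1))
  expect_true(all(diff(sR) < 0))
  ## series truncation: 20 -> 40 roots changes protocol signals by < 1e-6
  m <- gradientCombinations(mouseScheme)
  for (R in c(0.5, 5, 19)) {
    s20 <- sphereSignal(m$G, m$delta, m$Delta, 1e-9, R, nRoots = 20)
    s40 <- sphereSignal(m$G, m$delta, m$Delta, 1e-9, R, nRoots = 40)
    expect_lt(max(abs(s20 - s40)), 1e-6)
  }
  expect_equal(sphereGPDRoots(3)[1], 2.0816, tolerance = 1e-4)
})

test_that("composite signal is a convex fraction-weighted combination", {
  p <- baselineParams()
  s <- verdictSignal(mouseScheme, p)
  expect_true(all(s > 0 & s <= 1 + 1e-12))
  expect_equal(s[isB0(mouseScheme)], rep(1, 46))

  ## degenerate mixture: pure ball
  pb <- list(fBall = 1, fSphere = 0, fStick = 0, dBall = 2e-9,
             dSphere = 1e-9, R = 10, dStick = 8e-9, theta = 0, phi = 0)
  expect_equal(verdictSignal(mouseScheme, pb),
               ballSignal(bValues(mouseScheme), 2e-9))

  ## equal thirds: mean of the compartment signals; linear in fractions
  m <- measurements(mouseScheme)
  Sb <- ballSignal(m$b, 2e-9)
  Ss <- sphereSignal(m$G, m$delta, m$Delta, 1e-9, 10.6)
  St <- stickSignal(m$b, as.matrix(m[, c("gx", "gy", "gz")]), 10.8e-9, 1, 0.5)
  pt <- baselineParams()
  pt$fBall <- pt$fSphere <- pt$fStick <- 1 / 3
  expect_equal(verdictSignal(mouseScheme, pt), (Sb + Ss + St) / 3)
  expect_true(all(s >= pmin(Sb, Ss, St) - 1e-12 & s <= pmax(Sb, Ss, St) + 1e-12))

  bad <- baselineParams(); bad$fBall <- 0.8
  expect_error(verdictSignal(mouseScheme, bad), "sum to 1")
})

test_that("sphere GPD agrees with a Monte-Carlo walker oracle at small scale", {
  ## quick version of the acceptance-scale comparison: one shell, two radii
  for (R in c(5, 10)) {
    mc <- mcSphereSignal(R, 3e-3, 30e-3, gcm(21.6), nWalkers = 4000, seed = 5)
    gpd <- sphereSignal(gcm(21.6), 3e-3, 30e-3, 1e-9, R)
    expect_lt(abs(mc - gpd), 0.02)
  }
})

test_that("Rician noise has Rayleigh mean at S=0 and the Rician second moment", {
  expect_identical(addRicianNoise(c(0.5, 1), 0), c(0.5, 1))
  sigma <- 0.1
  draws <- addRicianNoise(rep(0, 1e5), sigma, seed = 9)
  expect_equal(mean(draws), sigma * sqrt(pi / 2), tolerance = 0.01)
  s <- 0.7
  draws2 <- addRicianNoise(rep(s, 1e5), sigma, seed = 10)
  expect_equal(mean(draws2^2), s^2 + 2 * sigma^2, tolerance = 0.01)
  ## reproducible given seed
  expect_identical(addRicianNoise(rep(s, 10), sigma, seed = 3),
                   addRicianNoise(rep(s, 10), sigma, seed = 3))
})

test_that("Rician log-likelihood matches hand values and the Gaussian limit", {
  expect_equal(ricianLogLik(1, 0, 1), -0.5)
  ## maximised near nu = m for small sigma
  m <- c(0.9, 0.5, 0.2)
  ll0 <- ricianLogLik(m, m, 0.01)
  expect_gt(ll0, ricianLogLik(m, m * 1.05, 0.01))
  ## high-SNR limit: matches the Gaussian log-likelihood within 1%
  set.seed(2)
  obs <- addRicianNoise(rep(0.8, 50), 0.01)
  nu <- rep(0.8, 50)
  lr <- ricianLogLik(obs, nu, 0.01)
  lg <- gaussianLogLik(obs, nu, 0.01)
  expect_lt(abs(lr - lg) / abs(lg), 0.01)
  expect_error(ricianLogLik(c(1, NA), c(1, 1), 0.1), "non-finite")
  expect_error(ricianLogLik(1, 1, 0), "positive")
})
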