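test_that("noiseless VERDICT signals are inverted to the generating parameters", {
  truth <- baselineParams()
  sig <- mouseDwSignal(truth)
  fit <- fitVoxel(sig, mouseScheme, fitConfig("verdict", "mouse", sigma = 1e-4))
  expect_true(fit$converged)
  expect_equal(fit$params$fSphere, truth$fSphere, tolerance = 0.01)
  expect_equal(fit$params$fBall, truth$fBall, tolerance = 0.01)
  expect_equal(fit$params$R, truth$R, tolerance = 0.2 / truth$R)
  expect_equal(fit$params$dStick, truth$dStick, tolerance = 0.01)
  ## closure is exact, not approximate
  expect_equal(fit$params$fSphere + fit$params$fBall + fit$params$fStick, 1,
               tolerance = 1e-9)
  ## bounds respected
  expect_true(fit$params$R >= 0.1 && fit$params$R <= 20)
  expect_gte(fit$params$dStick, 3.05e-9)
  ## BIC consistency with the returned log-likelihood
  expect_equal(fit$bic, log(fit$nMeas) * 6 - 2 * fit$loglik, tolerance = 1e-9)
  expect_equal(computeBIC(fit), fit$bic)
})

test_that("human-mode fit fixes the stick diffusivity and fits 5 parameters", {
  truth <- baselineParams()
  truth$dStick <- 8e-9
  sig <- verdictSignal(humanScheme, truth)[!isB0(humanScheme)]
  cfg <- fitConfig("verdict", "human", sigma = 1e-4)
  expect_equal(nFittedParams(cfg), 5L)
  fit <- fitVoxel(sig, humanScheme, cfg)
  expect_equal(fit$params$dStick, 8e-9)
  expect_equal(fit$params$fSphere, truth$fSphere, tolerance = 0.02)
  expect_equal(fit$params$R, truth$R, tolerance = 0.05)
  expect_equal(fit$k, 5L)
})

test_that("flat signal drives the ADC estimate to the zero boundary", {
  sig <- rep(1, 138)
  fit <- fitVoxel(sig, mouseScheme, fitConfig("adc", sigma = 0.02))
  expect_identical(fit$params$ADC, 0)
  expect_equal(fit$k, 1L)
  ## and a known monoexponential decay is recovered
  b <- bValues(mouseScheme)[!isB0(mouseScheme)]
  fit2 <- fitVoxel(adcSignal(b, 0.99e-9), mouseScheme,
                   fitConfig("adc", sigma = 1e-4))
  expect_equal(fit2$params$ADC, 0.99e-9, tolerance = 0.01)
  ## kurtosis fit recovers (Dk, K)
  fit3 <- fitVoxel(kurtosisSignal(b, 1e-9, 0.85), mouseScheme,
                   fitConfig("kurtosis", sigma = 1e-4))
  expect_equal(fit3$params$Dk, 1e-9, tolerance = 0.02)
  expect_equal(fit3$params$K, 0.85, tolerance = 0.05)
  expect_equal(fit3$k, 2L)
})

test_that("multi-start optimum dominates every individual start", {
  truth <- baselineParams()
  sig <- addRicianNoise(mouseDwSignal(truth), 1 / 50, seed = 21)
  cfg <- fitConfig("verdict", "mouse", sigma = 1 / 50, seed = 4)
  fit <- fitVoxel(sig, mouseScheme, cfg)
  ## rerunning from any single coarse start cannot beat the multi-start fit
  for (g in c(1L, 2L)) {
    single <- fitVoxel(sig, mouseScheme,
                       fitConfig("verdict", "mouse", sigma = 1 / 50,
                                 nStartsGrid = g, nRestarts = 0L, seed = 4))
    expect_gte(fit$loglik + 1e-6, single$loglik)
  }
  expect_gte(fit$nRestartsAgreeing, 1L)
})

test_that("fitVoxel validates its inputs", {
  cfg <- fitConfig("verdict", "mouse", sigma = 0.02)
  expect_error(fitVoxel(rep(0.5, 10), mouseScheme, cfg), "length")
  sig <- mouseDwSignal()
  bad <- sig; bad[1] <- -1
  expect_error(fitVoxel(bad, mouseScheme, cfg), "non-negative")
  ## fewer measurements than parameters
  expect_error(fitVoxel(rep(0.5, 3), tinyScheme(), cfg), "fewer measurements")
})

test_that("fitRoi assembles maps, flags boundary hits and is deterministic", {
  vol <- tinyRawVolume(3, snr = 50, seed = 12)
  cfg <- fitConfig("verdict", "mouse", sigma = 1 / 50, nStartsGrid = 2L,
                   nRestarts = 1L, seed = 5)
  maps <- fitRoi(vol, cfg)
  expect_s4_class(maps, "ParameterMaps")
  expect_equal(sort(names(maps@maps)),
               sort(c("fSphere", "fBall", "fStick", "R", "dStick",
                      "theta", "phi")))
  ## closure across the whole map
  fs <- parameterMap(maps, "fSphere") + parameterMap(maps, "fBall") +
    parameterMap(maps, "fStick")
  expect_equal(fs[maps@mask], rep(1, 3), tolerance = 1e-9)
  ## deterministic given the seed
  maps2 <- fitRoi(vol, cfg)
  expect_equal(maps@maps, maps2@maps)
  ## 1-voxel mask reduces to fitVoxel
  vol1 <- tinyRawVolume(1, snr = Inf)
  m1 <- fitRoi(vol1, fitConfig("verdict", "mouse", sigma = 1e-4,
                               nStartsGrid = 2L, nRestarts = 0L, seed = 6))
  norm1 <- normalizeToB0(vol1)
  f1 <- fitVoxel(as.vector(dwiSignal(norm1)[1, 1, 1, ]), mouseScheme,
                 fitConfig("verdict", "mouse", sigma = 1e-4,
                           nStartsGrid = 2L, nRestarts = 0L,
                           seed = as.integer(6 + 1)))
  expect_equal(parameterMap(m1, "R")[1, 1, 1], f1$params$R)
  ## empty mask errors
  volE <- tinyRawVolume(2)
  volE@mask[] <- FALSE
  expect_error(fitRoi(volE, cfg), "empty mask")
  ## summary of a uniform map
  summ <- summarizeRoi(m1)
  expect_equal(summ$sd[summ$parameter == "R"], 0)
  expect_equal(summ$n, rep(1L, nrow(summ)))
})

test_that("BIC compares models sensibly on small simulated data", {
  expect_equal(log(138) * 6 + 100,
               {
                 f <- structure(list(nMeas = 138L, k = 6L, loglik = -50),
                                class = "VoxelFit")
                 computeBIC(f)
               })
  expect_equal(computeBIC(structure(list(nMeas = 10L, k = 0L, loglik = -3),
                                    class = "VoxelFit")), 6)

  ## monoexponential data: the 1-parameter ADC model wins on parsimony
  vol <- tinyRawVolume(4, snr = 50, seed = 31)
  b <- bValues(mouseScheme)
  mono <- adcSignal(b, 1e-9)
  sig <- matrix(rep(mono * 1000, each = 4), nrow = 4)
  sig <- addRicianNoise(sig, 20, seed = 32)
  dim(sig) <- c(4, 1, 1, length(b))
  volMono <- dwiVolume(sig, mouseScheme)
  cfgs <- list(
    adc = fitConfig("adc", sigma = 1 / 50),
    verdict = fitConfig("verdict", "mouse", sigma = 1 / 50,
                        nStartsGrid = 2L, nRestarts = 1L)
  )
  cmp <- compareModels(volMono, cfgs)
  expect_lt(cmp$meanBIC["adc"], cmp$meanBIC["verdict"])
  expect_gte(mean(cmp$bestModel[volMono@mask] == "adc"), 0.75)
})
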