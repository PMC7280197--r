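test_that("phantom geometry and parameter fields are valid and seeded", {
  ph <- generatePhantom(shape = c(12, 12, 8), seed = 3)
  expect_s4_class(ph, "PhantomGroundTruth")
  expect_setequal(unique(as.vector(ph@labels)), 0:3)
  inside <- ph@labels > 0
  sums <- ph@params$fSphere[inside] + ph@params$fBall[inside] +
    ph@params$fStick[inside]
  expect_equal(sums, rep(1, sum(inside)), tolerance = 1e-9)
  ## rim has higher sphere fraction than the (necrotic-like) core
  expect_gt(mean(ph@params$fSphere[ph@labels == 2]),
            mean(ph@params$fSphere[ph@labels == 3]))
  ## determinism and SD control
  ph2 <- generatePhantom(shape = c(12, 12, 8), seed = 3)
  expect_identical(ph@params, ph2@params)
  flat <- generatePhantom(shape = c(12, 12, 8),
                          withinSd = list(fSphere = 0, R = 0, dStick = 0),
                          seed = 3)
  expect_equal(length(unique(flat@params$R[flat@labels > 0])), 3)
  expect_error(generatePhantom(shape = c(6, 6, 6)), "at least 8")
  expect_error(generatePhantom(shape = c(12, 12, 8), semiAxes = c(9, 9, 9)),
               "exceeds grid")
})

test_that("synthesised DWI volumes honour S0, SNR and the forward model", {
  ph <- generatePhantom(shape = c(10, 10, 8), seed = 2)
  vol <- synthesizeDwi(ph, mouseScheme, snr = 50, s0 = 1000, seed = 4)
  expect_equal(dim(dwiSignal(vol))[4], 184)
  ## b0 voxel means sit near S0 (Rician mean at SNR 50 is ~S0 + sigma^2/2S0)
  b0 <- isB0(mouseScheme)
  inside <- which(ph@labels > 0)
  sig <- matrix(dwiSignal(vol), nrow = prod(dim(ph@labels)))
  b0bar <- mean(sig[inside, b0])
  se <- (1000 / 50) / sqrt(length(inside) * sum(b0))
  expect_lt(abs(b0bar - 1000), 3 * se + (1000 / 50)^2 / (2 * 1000))
  ## noiseless synthesis reproduces the forward model exactly
  volClean <- synthesizeDwi(ph, mouseScheme, snr = Inf, s0 = 1)
  v <- inside[1]
  p <- lapply(ph@params, function(a) a[v])
  p$dSphere <- 1e-9; p$dBall <- 2e-9
  expect_equal(sig0 <- as.vector(matrix(dwiSignal(volClean),
                                        nrow = prod(dim(ph@labels)))[v, ]),
               verdictSignal(mouseScheme, p))
  ## determinism
  vol2 <- synthesizeDwi(ph, mouseScheme, snr = 50, s0 = 1000, seed = 4)
  expect_identical(dwiSignal(vol), dwiSignal(vol2))
})

test_that("noiseless phantom signals are inverted back to the truth by fitting", {
  ph <- generatePhantom(shape = c(10, 10, 8),
                        withinSd = list(fSphere = 0.02, R = 0.3, dStick = 0),
                        seed = 8)
  vol <- synthesizeDwi(ph, mouseScheme, snr = Inf, s0 = 500)
  ## fit a handful of voxels to keep the check quick
  keep <- which(ph@labels > 0)[c(3, 20, 40)]
  mask <- array(FALSE, dim = dim(ph@labels)); mask[keep] <- TRUE
  vol@mask <- mask
  maps <- fitRoi(vol, fitConfig("verdict", "mouse", sigma = 1e-4, seed = 2))
  expect_equal(parameterMap(maps, "R")[keep], ph@params$R[keep],
               tolerance = 0.02)
  expect_equal(parameterMap(maps, "fSphere")[keep], ph@params$fSphere[keep],
               tolerance = 0.02)
})

test_that("cohort generator anchors the day-9 radius change and baselines", {
  ## zero-SD cohort: means are exactly the trajectory anchors
  zeroSd <- lapply(defaultCohortTrajectories()$sds, function(x) x * 0)
  spec <- cohortSpec(nPerArm = 3, sds = zeroSd, seed = 1)
  coh <- generateCohort(spec)
  tab <- coh$table
  r9 <- tab$value[tab$parameter == "R" & tab$day == 9]
  names(r9) <- tab$arm[tab$parameter == "R" & tab$day == 9]
  expect_equal(unique(r9[names(r9) == "treated"]), 0.46 * 10.6)
  expect_equal(unique(r9[names(r9) == "control"]), 0.91 * 10.6)
  ## baseline equality across arms for every parameter
  base <- tab[tab$day == 0, ]
  for (p in unique(base$parameter)) {
    v <- tapply(base$value[base$parameter == p], base$arm[base$parameter == p],
                mean)
    expect_equal(unname(diff(v)), 0)
  }
  ## subject counts and determinism
  expect_equal(length(unique(tab$subject)), 6)
  expect_identical(generateCohort(spec)$table, tab)

  ## with noise, realised means track the anchors within standard error
  spec12 <- cohortSpec(nPerArm = 12, seed = 33)
  tab12 <- generateCohort(spec12)$table
  fs <- tab12[tab12$parameter == "fSphere" & tab12$day == 0, ]
  expect_equal(mean(fs$value), 0.54, tolerance = 3 * 0.05 / sqrt(24))
  r0 <- tab12[tab12$parameter == "R" & tab12$day == 0, ]
  expect_equal(mean(r0$value), 10.6, tolerance = 3 * 0.6 / sqrt(24))
})

test_that("cohort DWI synthesis produces per-subject voxel signal sets", {
  spec <- cohortSpec(nPerArm = 2, voxelsPerTumour = 5, seed = 2)
  coh <- generateCohort(spec, withDwi = TRUE)
  expect_length(coh$dwi, 4)
  one <- coh$dwi[[1]][["0"]]
  expect_equal(dim(one), c(5, 138))
  expect_true(all(one > 0))
})

test_that("histology images realise their target fraction and are seeded", {
  h <- generateHistologyImage(0.4, shape = c(128, 128), seed = 5)
  expect_equal(h$trueFraction, 0.4, tolerance = 0.02)
  expect_equal(h$trueFraction, mean(h$mask))
  h2 <- generateHistologyImage(0.4, shape = c(128, 128), seed = 5)
  expect_identical(h$image, h2$image)
  expect_error(generateHistologyImage(0), "targetFraction")
  expect_error(generateHistologyImage(0.95), "targetFraction")
})
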