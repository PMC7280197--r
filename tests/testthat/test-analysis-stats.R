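test_that("Holm-Sidak adjustment matches hand values and a brute-force oracle", {
  expect_equal(holmSidakAdjust(0.03, m = 1), 0.03)
  ## step-down: rank-3 value 0.04 inherits the running max 1 - 0.97^2
  expect_equal(holmSidakAdjust(c(0.01, 0.04, 0.03)),
               c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.97^2), tolerance = 1e-12)
  expect_equal(round(holmSidakAdjust(c(0.01, 0.04, 0.03)), 4),
               c(0.0297, 0.0591, 0.0591), tolerance = 1e-3)
  expect_equal(holmSidakAdjust(rep(1, 4)), rep(1, 4))
  expect_error(holmSidakAdjust(c(0.5, 1.2)), "0, 1")
  ## oracle agreement on random small families, incl. m > length(p)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    p <- round(runif(n), 3)
    m <- n + sample(0:3, 1)
    expect_equal(holmSidakAdjust(p, m), bruteHolmSidak(p, m))
  }
  ## monotone: adjusted >= raw, and order-preserving in the sorted sequence
  p <- runif(5)
  a <- holmSidakAdjust(p)
  expect_true(all(a >= p))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
})

test_that("group comparison corrects across the declared family", {
  tab <- generateCohort(cohortSpec(nPerArm = 6, seed = 2))$table
  res <- groupComparison(tab, familySize = 32)
  expect_equal(nrow(res), 32)           # 8 parameters x 4 timepoints
  expect_true(all(res$pAdjusted >= res$p - 1e-15))
  ## radius separates the arms from day 3 on under the default trajectories
  rRes <- res[res$parameter == "R", ]
  expect_false(rRes$significant[rRes$day == 0])
  expect_true(rRes$significant[rRes$day == 3])
  ## identical arms: nothing significant
  nullTraj <- defaultCohortTrajectories()
  nullTraj$trajectories$treated <- nullTraj$trajectories$control
  nullTab <- generateCohort(cohortSpec(nPerArm = 6,
                                       trajectories = nullTraj$trajectories,
                                       sds = nullTraj$sds, seed = 4))$table
  resNull <- groupComparison(nullTab, familySize = 32)
  expect_lte(sum(resNull$significant), 1)
  ## validation
  expect_error(groupComparison(tab[tab$arm == "control", ]), "two arms")
  one <- tab[!(tab$arm == "treated" & tab$subject != "t01"), ]
  expect_error(groupComparison(one), ">= 2 subjects")
})

test_that("effect sizes difference the consecutive timepoints per arm", {
  ## near-zero spread so realised effects sit at the trajectory anchors
  smallSd <- lapply(defaultCohortTrajectories()$sds, function(x) x * 1e-3)
  tab <- generateCohort(cohortSpec(nPerArm = 3, sds = smallSd, seed = 1))$table
  es <- effectSizes(tab, familySize = 28)
  expect_equal(nrow(es), 24)            # 8 parameters x 3 intervals
  traj <- defaultCohortTrajectories()$trajectories
  r30 <- es[es$parameter == "R" & es$interval == "3-0", ]
  expect_equal(r30$effect_control, traj$control$R[2] - traj$control$R[1],
               tolerance = 0.01)
  expect_equal(r30$effect_treated, traj$treated$R[2] - traj$treated$R[1],
               tolerance = 0.01)
  ## opposite-sign radius trajectories make the 3-0 interval significant
  tabN <- generateCohort(cohortSpec(nPerArm = 8, seed = 6))$table
  esN <- effectSizes(tabN, familySize = 28)
  expect_true(esN$significant[esN$parameter == "R" & esN$interval == "3-0"])
  ## identical trajectories: between-arm change test not significant
  nullTraj <- defaultCohortTrajectories()
  nullTraj$trajectories$treated <- nullTraj$trajectories$control
  tabNull <- generateCohort(cohortSpec(nPerArm = 8,
                                       trajectories = nullTraj$trajectories,
                                       sds = nullTraj$sds, seed = 7))$table
  esNull <- effectSizes(tabNull, familySize = 28)
  expect_lte(sum(esNull$significant), 1)
  ## a subject missing one timepoint is excluded from that interval only
  drop <- tabN[!(tabN$subject == "c01" & tabN$day == 6), ]
  expect_warning(effectSizes(drop, familySize = 28), "c01")
})

test_that("Spearman correlation uses mid-ranks and pools timepoints", {
  tab <- data.frame(
    subject = rep(sprintf("s%d", 1:3), each = 2),
    arm = "control", day = 0,
    parameter = rep(c("x", "y"), times = 3),
    value = c(1, 3, 2, 1, 3, 2))
  expect_equal(spearmanCorrelation(tab, "x", "y")$rho, -0.5)
  tab$value[tab$parameter == "y"] <- tab$value[tab$parameter == "x"]
  expect_equal(spearmanCorrelation(tab, "x", "y")$rho, 1)
  tab$value[tab$parameter == "y"] <- -tab$value[tab$parameter == "x"]
  expect_equal(spearmanCorrelation(tab, "x", "y")$rho, -1)
  ## oracle agreement with ties, on pooled cohort values
  coh <- generateCohort(cohortSpec(nPerArm = 4, seed = 9))$table
  got <- spearmanCorrelation(coh, "ADC", "fSphere")
  x <- got$pairs$valueX; y <- got$pairs$valueY
  expect_equal(got$rho, bruteSpearman(x, y))
  expect_equal(got$n, 32)
  tabC <- tab; tabC$value[tabC$parameter == "y"] <- 5
  expect_error(spearmanCorrelation(tabC, "x", "y"), "constant")
})

test_that("repeatability coefficient and Wilcoxon follow their definitions", {
  same <- repeatability(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$rc, 0)
  expect_gte(same$wilcoxonP, 0.99)
  r <- repeatability(c(9.5, 10.5), c(10.5, 9.5))
  expect_equal(r$rc, 1.96 * sqrt(2) * 100 / 10)
  ## scale invariance
  t1 <- c(8, 10, 12, 9); t2 <- c(9, 10, 11, 10)
  expect_equal(repeatability(t1, t2)$rc, repeatability(3 * t1, 3 * t2)$rc)
  ## exact Wilcoxon agrees with full sign enumeration for small n
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(5, 10); b <- a + rnorm(5, 0.3)  # continuous, so no rank ties
    expect_equal(repeatability(a, b)$wilcoxonP, bruteWilcoxonP(a, b))
  }
  expect_error(repeatability(1, numeric(0)), "paired")
  expect_error(repeatability(c(1, -1), c(-1, 1)), "zero")
})
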