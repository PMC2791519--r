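test_that("identical seeds give bitwise-identical simulations", {
  a <- simulateGroupLogev(c(0.6, 0.4), 50, effectSd = 1, noiseSd = 0.5,
                          seed = 14)
  b <- simulateGroupLogev(c(0.6, 0.4), 50, effectSd = 1, noiseSd = 0.5,
                          seed = 14)
  expect_identical(evidence(a$logev), evidence(b$logev))
  expect_identical(trueAssignments(a$truth), trueAssignments(b$truth))

  va <- simulateEvidenceVolumes(seed = 5)
  vb <- simulateEvidenceVolumes(seed = 5)
  expect_identical(volumeData(va$set), volumeData(vb$set))
})

test_that("degenerate frequencies assign every subject to the same model", {
  sim <- simulateGroupLogev(c(1, 0), 30, seed = 2)
  expect_true(all(trueAssignments(sim$truth) == 1L))
})

test_that("the noiseless limit produces exact one-hot evidence rows", {
  sim <- simulateGroupLogev(c(0.5, 0.5), 40, effectMean = 5, effectSd = 0,
                            noiseSd = 0, seed = 3)
  vals <- evidence(sim$logev)
  a <- trueAssignments(sim$truth)
  expect_true(all(vals[cbind(seq_len(40), a)] == 5))
  expect_true(all(vals[cbind(seq_len(40), 3L - a)] == 0))
})

test_that("assignment frequencies converge to the generating simplex", {
  n <- 1e4
  r <- c(0.7, 0.3)
  sim <- simulateGroupLogev(r, n, seed = 99)
  f1 <- mean(trueAssignments(sim$truth) == 1L)
  se <- sqrt(r[1] * r[2] / n)
  expect_lt(abs(f1 - r[1]), 3 * se)
})

test_that("decisive noiseless groups are recovered exactly by the fit", {
  sim <- simulateGroupLogev(c(0.4, 0.6), 25, effectMean = 30, seed = 7)
  fit <- rfxFit(sim$logev, computeExceedance = FALSE)
  a <- trueAssignments(sim$truth)
  oneHot <- matrix(0, 25, 2)
  oneHot[cbind(seq_len(25), a)] <- 1
  expect_equal(unname(assignments(fit)), oneHot, tolerance = 1e-12)
  expect_equal(unname(modelCounts(fit)), unname(table(factor(a, 1:2))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("invalid simplices and sizes are rejected", {
  expect_error(simulateGroupLogev(c(0.7, 0.4), 10), "summing to 1")
  expect_error(simulateGroupLogev(c(0.7, 0.3), 0), ">= 1")
  expect_error(simulateGroupLogev(c(0.7, 0.3), 5, noiseSd = -1), ">= 0")
})

test_that("outlier scenarios have the documented structure", {
  lev <- makeOutlierScenario(12, majorityLogbf = -1, outlierLogbf = 30)
  vals <- evidence(lev)
  expect_equal(dim(vals), c(12L, 2L))
  expect_equal(unname(vals[, 1] - vals[, 2]), c(rep(-1, 11), 30))

  # homogeneous control: FFX and RFX agree on the winner
  hom <- makeOutlierScenario(12, majorityLogbf = -1, outlierLogbf = -1)
  expect_gt(posteriorProbs(ffxPosterior(hom))[[2]], 0.5)
  expect_gt(expectedR(rfxFit(hom))[2], 0.5)

  # boundary size still yields one outlier row
  two <- makeOutlierScenario(2, -1, 30)
  expect_equal(dim(evidence(two)), c(2L, 2L))
  expect_error(makeOutlierScenario(1), ">= 2")
})

test_that("volume scenarios mark exactly the active region", {
  sim <- simulateEvidenceVolumes(gridShape = c(8, 8, 8),
                                 activeRegion = list(min = c(3, 3, 3),
                                                     max = c(5, 5, 5)),
                                 seed = 4)
  expect_equal(sum(sim$truthVolume), 27L)
  expect_true(all(which(sim$truthVolume, arr.ind = TRUE) >= 3 &
                    which(sim$truthVolume, arr.ind = TRUE) <= 5))
  expect_error(
    simulateEvidenceVolumes(activeRegion = list(min = c(3, 3, 3),
                                                max = c(9, 5, 5))),
    "inside the grid"
  )
})

test_that("a null volume scenario is spatially homogeneous per subject", {
  sim <- simulateEvidenceVolumes(
    gridShape = c(4, 4, 4),
    activeRegion = list(min = c(1, 1, 1), max = c(4, 4, 4)),
    rTrueInside = c(0.5, 0.5), rTrueOutside = c(0.5, 0.5), seed = 6
  )
  dat <- volumeData(sim$set)
  for (s in seq_len(dim(dat)[4])) {
    for (m in 1:2) {
      expect_equal(length(unique(as.vector(dat[, , , s, m]))), 1L)
    }
  }
})

test_that("per-voxel assignment mode decorrelates voxels", {
  sim <- simulateEvidenceVolumes(
    gridShape = c(6, 6, 6),
    activeRegion = list(min = c(1, 1, 1), max = c(6, 6, 6)),
    rTrueInside = c(0.5, 0.5), rTrueOutside = c(0.5, 0.5),
    nSubjects = 4, seed = 10, perVoxelAssignments = TRUE
  )
  dat <- volumeData(sim$set)
  # with independent per-voxel draws a subject's model-1 volume must vary
  expect_gt(length(unique(as.vector(dat[, , , 1, 1]))), 1L)
  expect_null(sim$truthInside)
})
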