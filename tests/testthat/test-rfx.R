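test_that("assignment update matches the digamma-weighted softmax", {
  # full symmetry: uniform beliefs
  a <- rfxUpdateAssignments(matrix(0, 1, 4), rep(1, 4))
  expect_equal(unname(assignments(a)[1, ]), rep(0.25, 4), tolerance = 1e-12)

  # decisive evidence: one-hot to machine precision
  a <- rfxUpdateAssignments(matrix(c(30, 0), 1, 2), c(1, 1))
  expect_equal(unname(assignments(a)[1, ]), c(1, 0), tolerance = 1e-12)

  # flat evidence, asymmetric alpha: softmax of the digamma terms
  a <- rfxUpdateAssignments(matrix(0, 1, 2), c(3, 1))
  w <- exp(c(digamma(3) - digamma(4), digamma(1) - digamma(4)))
  expect_equal(unname(assignments(a)[1, ]), w / sum(w), tolerance = 1e-12)

  expect_error(rfxUpdateAssignments(matrix(0, 1, 2), c(1, 0)), "> 0")
  expect_error(rfxUpdateAssignments(matrix(0, 1, 2), c(1, -1)), "> 0")
})

test_that("assignment update survives huge log-evidence differences", {
  a <- rfxUpdateAssignments(rbind(c(5000, 0), c(0, 5000)), c(1, 1))
  expect_equal(unname(assignments(a)), rbind(c(1, 0), c(0, 1)),
               tolerance = 1e-15)
  expect_true(all(is.finite(a@u)))
})

test_that("symmetric groups converge to the symmetric fixed point", {
  fit <- rfxFit(matrix(0, 12, 2))
  expect_true(converged(fit))
  expect_equal(unname(alphaPost(fit)), c(7, 7), tolerance = 1e-10)
  expect_equal(unname(expectedR(fit)), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(exceedance(fit)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("a single decisive subject reaches the alpha = (2, 1) fixed point", {
  fit <- rfxFit(matrix(c(30, 0), 1, 2))
  expect_equal(unname(alphaPost(fit)), c(2, 1), tolerance = 1e-4)
  expect_equal(unname(expectedR(fit)), c(2 / 3, 1 / 3), tolerance = 1e-4)
  expect_equal(unname(modelCounts(fit)), c(1, 0), tolerance = 1e-10)
})

test_that("fit agrees with the brute-force transcription on small groups", {
  cases <- list(
    matrix(c(2, 0), 1, 2),
    rbind(c(1.5, 0), c(-0.5, 0)),
    rbind(c(3, 0), c(-1, 0), c(0.2, 0)),
    rbind(c(-2, 0), c(-2, 0), c(5, 0))
  )
  for (lev in cases) {
    fit <- rfxFit(lev, tol = 1e-10, maxIter = 10000L,
                  computeExceedance = FALSE)
    ref <- rfxFitNaive(lev, tol = 1e-10)
    expect_equal(unname(alphaPost(fit)), ref$alpha, tolerance = 1e-8)
    expect_equal(unname(assignments(fit)), ref$g, tolerance = 1e-8)
    expect_equal(unname(expectedR(fit)), ref$expectedR, tolerance = 1e-8)
  }
})

test_that("counts are conserved and rows stay stochastic across random groups", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(1:15, 1)
    k <- sample(2:5, 1)
    lev <- matrix(rnorm(n * k, sd = 3), n, k)
    alpha0 <- runif(k, 0.5, 2)
    fit <- rfxFit(lev, alpha0 = alpha0, computeExceedance = FALSE)
    g <- assignments(fit)
    expect_true(all(g >= 0 & g <= 1))
    expect_equal(rowSums(g), rep(1, n), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sum(modelCounts(fit)), n, tolerance = 1e-8)
    expect_equal(sum(alphaPost(fit)), sum(alpha0) + n, tolerance = 1e-8)
    expect_equal(sum(expectedR(fit)), 1, tolerance = 1e-10)
  }
})

test_that("permuting model columns permutes every output identically", {
  set.seed(7)
  lev <- matrix(rnorm(12, sd = 2), 4, 3)
  perm <- c(3, 1, 2)
  fit <- rfxFit(lev, epSamples = 2e5, seed = 99)
  fitP <- rfxFit(lev[, perm], epSamples = 2e5, seed = 99)
  expect_equal(unname(alphaPost(fitP)), unname(alphaPost(fit))[perm],
               tolerance = 1e-8)
  expect_equal(unname(expectedR(fitP)), unname(expectedR(fit))[perm],
               tolerance = 1e-8)
  expect_equal(unname(assignments(fitP)), unname(assignments(fit))[, perm],
               tolerance = 1e-8)
  expect_equal(unname(modelCounts(fitP)), unname(modelCounts(fit))[perm],
               tolerance = 1e-8)
  # Monte-Carlo phi under different per-column streams: loose tolerance
  expect_equal(unname(exceedance(fitP)), unname(exceedance(fit))[perm],
               tolerance = 0.01)

  ffx <- posteriorProbs(ffxPosterior(lev))
  ffxP <- posteriorProbs(ffxPosterior(lev[, perm]))
  expect_equal(unname(ffxP), unname(ffx)[perm], tolerance = 1e-12)
})

test_that("per-subject constant offsets leave the fit unchanged", {
  lev <- mixedGroup()
  offset <- c(10, -5, 100, 0, -50, 7)
  shifted <- evidence(lev) + offset
  fit <- rfxFit(lev, computeExceedance = FALSE)
  fitS <- rfxFit(shifted, computeExceedance = FALSE)
  expect_equal(alphaPost(fitS), alphaPost(fit), tolerance = 1e-10)
  expect_equal(unname(assignments(fitS)), unname(assignments(fit)),
               tolerance = 1e-10)
})

test_that("non-convergence is flagged, not thrown", {
  fit <- rfxFit(mixedGroup(), maxIter = 1L)
  expect_false(converged(fit))
  expect_identical(iterations(fit), 1L)
  # invariants still hold on the flagged result
  expect_equal(sum(modelCounts(fit)), 6, tolerance = 1e-8)
})

test_that("invalid priors and degenerate model spaces are rejected", {
  expect_error(rfxFit(matrix(0, 3, 2), alpha0 = c(0, 1)), "> 0")
  expect_error(rfxFit(matrix(0, 3, 1)), "two models")
  expect_error(LogEvidenceMatrix(matrix(0, 0, 2)), "one subject")
})

test_that("expected model probabilities are the normalised alpha", {
  expect_equal(expectedModelProbs(DirichletPosterior(c(1, 1))), c(0.5, 0.5))
  expect_equal(expectedModelProbs(DirichletPosterior(c(3, 1))), c(0.75, 0.25))
  expect_equal(expectedModelProbs(c(2, 1)), c(2, 1) / 3)
})
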