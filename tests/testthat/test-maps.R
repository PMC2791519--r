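test_that("a single-voxel mask reproduces the direct fit exactly", {
  sim <- simulateEvidenceVolumes(seed = 21)
  grid <- gridShape(sim$set)
  mask <- array(FALSE, grid)
  mask[4, 4, 4] <- TRUE
  one <- EvidenceVolumeSet(volumeData(sim$set), affine = affineMatrix(sim$set),
                           mask = mask)
  maps <- voxelwiseRfx(one)
  mat <- matrix(volumeData(sim$set)[4, 4, 4, , ],
                nSubjects(sim$set), nModels(sim$set))
  fit <- rfxFit(mat)
  expect_equal(ppm(maps, 1)[4, 4, 4], expectedR(fit)[1], tolerance = 1e-12)
  expect_equal(epm(maps, 2)[4, 4, 4], exceedance(fit)[2], tolerance = 1e-12)
  expect_equal(alphaMaps(maps)[4, 4, 4, ], alphaPost(fit), tolerance = 1e-12)
  expect_equal(sum(!is.na(ppm(maps, 1))), 1L)
})

test_that("indifferent volumes give uniform PPMs everywhere in the mask", {
  set <- EvidenceVolumeSet(array(1.3, c(5, 4, 3, 6, 3)),
                           affine = diag(c(3, 3, 3, 1)))
  maps <- voxelwiseRfx(set)
  expect_equal(range(ppm(maps)), c(1 / 3, 1 / 3), tolerance = 1e-10)
  fmaps <- voxelwiseFfx(set)
  expect_equal(range(ppm(fmaps)), c(1 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("an active cuboid separates from background in the RFX PPM", {
  grid <- c(6, 6, 6)
  arr <- array(0, c(grid, 12, 2))
  inside <- array(FALSE, grid)
  inside[2:4, 2:4, 2:4] <- TRUE
  for (s in 1:12) {
    v <- arr[, , , s, 1]
    v[inside] <- 3 # every subject carries log BF = +3 for model 1 inside
    arr[, , , s, 1] <- v
  }
  set <- EvidenceVolumeSet(arr, affine = diag(c(3, 3, 3, 1)))
  maps <- voxelwiseRfx(set)
  p1 <- ppm(maps, 1)
  expect_true(all(p1[inside] > 0.5))
  expect_equal(range(p1[!inside]), c(0.5, 0.5), tolerance = 1e-10)
  # all analysed voxels carry a normalised posterior
  expect_equal(range(ppm(maps, 1) + ppm(maps, 2)), c(1, 1),
               tolerance = 1e-8)
  expect_equal(range(epm(maps, 1) + epm(maps, 2)), c(1, 1),
               tolerance = 1e-12)
})

test_that("voxel-wise FFX matches summed-evidence normalisation and has no EPM", {
  sim <- simulateEvidenceVolumes(seed = 13)
  maps <- voxelwiseFfx(sim$set)
  v <- c(3, 5, 2)
  mat <- matrix(volumeData(sim$set)[v[1], v[2], v[3], , ],
                nSubjects(sim$set), nModels(sim$set))
  expect_equal(ppm(maps, 1)[v[1], v[2], v[3]],
               posteriorProbs(ffxPosterior(mat))[[1]], tolerance = 1e-12)
  expect_error(epm(maps), "RFX")
  expect_identical(mapMethod(maps), "ffx")
})

test_that("FFX saturates at least as high as RFX where subjects agree", {
  grid <- c(4, 4, 2)
  arr <- array(0, c(grid, 8, 2))
  arr[, , , , 1] <- 2 # all subjects favour model 1 everywhere
  set <- EvidenceVolumeSet(arr, affine = diag(4))
  pF <- ppm(voxelwiseFfx(set), 1)
  pR <- ppm(voxelwiseRfx(set), 1)
  expect_true(all(pF >= pR))
  expect_true(all(pF > 0.99))
})

test_that("shrinking the mask leaves shared voxels untouched", {
  sim <- simulateEvidenceVolumes(seed = 33)
  full <- voxelwiseRfx(sim$set)
  small <- array(FALSE, gridShape(sim$set))
  small[3:5, 3:5, 3:5] <- TRUE
  sub <- EvidenceVolumeSet(volumeData(sim$set),
                           affine = affineMatrix(sim$set), mask = small)
  subMaps <- voxelwiseRfx(sub)
  expect_equal(ppm(subMaps, 1)[small], ppm(full, 1)[small],
               tolerance = 1e-12)
  expect_true(all(is.na(ppm(subMaps, 1)[!small])))
})

test_that("thresholding keeps strict exceedances and NA elsewhere", {
  vol <- array(c(0.6, 0.8, NA, 0.75), c(2, 2, 1))
  thr <- thresholdMap(vol, 0.75)
  expect_equal(as.vector(thr), c(NA, 0.8, NA, NA)) # 0.75 itself is excluded
  expect_equal(sum(!is.na(thresholdMap(vol, 0))), 3L)
  expect_true(all(is.na(thresholdMap(vol, 1))))
  expect_error(thresholdMap(vol, 1.2), "\\[0, 1\\]")
  expect_error(thresholdMap(vol, -0.1), "\\[0, 1\\]")
})

test_that("log-odds transform is exact, monotone and edge-aware", {
  expect_equal(toLogOdds(0.5), 0)
  expect_equal(toLogOdds(0.95), log(19), tolerance = 1e-12)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(toLogOdds(p)) > 0))
  expect_identical(toLogOdds(c(0, 1)), c(-Inf, Inf))
  expect_error(toLogOdds(1.5), "\\[0, 1\\]")
})

test_that("written maps round-trip with their affine and sidecar", {
  sim <- simulateEvidenceVolumes(gridShape = c(5, 5, 5),
                                 activeRegion = list(min = c(2, 2, 2),
                                                     max = c(4, 4, 4)),
                                 seed = 8)
  maps <- voxelwiseRfx(sim$set)
  out <- withr::local_tempdir()
  manifest <- writeMaps(maps, out)
  # K = 2 RFX: 2 ppm + 2 epm + 2 alpha + sidecar
  expect_equal(nrow(manifest), 7L)
  expect_true(all(file.exists(manifest$path)))

  ppmPath <- manifest$path[manifest$type == "ppm"][1]
  vol <- BMSmaps:::readVolume(ppmPath)
  got <- vol$data
  want <- ppm(maps, 1)
  nifti_na <- is.na(want)
  expect_equal(got[!nifti_na], want[!nifti_na], tolerance = 1e-6)
  expect_equal(vol$affine, affineMatrix(sim$set), tolerance = 1e-6,
               ignore_attr = TRUE)

  sidecar <- jsonlite::read_json(file.path(out, "bms_run.json"),
                                 simplifyVector = TRUE)
  expect_identical(sidecar$method, "rfx")
  expect_equal(sidecar$nAnalysed, 125L)
  expect_equal(unlist(sidecar$alpha0), c(1, 1))
})
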