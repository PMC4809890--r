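test_that("phantom generation is deterministic and anatomically complete", {
  s <- phantomSpec(dims = c(40, 40, 40), seed = 5, nLesions = 1, nPockets = 1,
                   pocketVolumeMm3 = 100)
  b1 <- generatePhantom(s)
  b2 <- generatePhantom(s)
  expect_identical(voxelData(b1@t2), voxelData(b2@t2))
  expect_identical(voxelData(b1@truth), voxelData(b2@truth))
  expect_identical(voxelData(b1@priors), voxelData(b2@priors))

  ## all eight classes present; truth covers exactly the brain mask
  expect_setequal(unique(as.vector(voxelData(b1@truth))), 0:8)
  expect_identical(voxelData(b1@truth) > 0, voxelData(b1@brainMask) == 1L)

  ## T2 intensity ordering: CSF > WM > cortical GM (on class means)
  t2 <- voxelData(b1@t2); tr <- voxelData(b1@truth)
  expect_gt(mean(t2[tr == 4]), mean(t2[tr == 2]))
  expect_gt(mean(t2[tr == 2]), mean(t2[tr == 1]))
})

test_that("noise-free unblurred phantom: argmax of priors reproduces truth", {
  s <- phantomSpec(dims = c(40, 40, 40), noiseSd = 0, biasAmplitude = 0,
                   priorBlurMm = 0, seed = 2)
  b <- generatePhantom(s)
  lab <- voxelData(hardLabels(b@priors))
  expect_identical(lab, voxelData(b@truth))
})

test_that("prior blur behaves like a smoothed step at a class interface", {
  ## two-class half-space: the interface-straddling prior averages to 0.5
  d <- c(24L, 8L, 8L)
  lab <- array(2L, d); lab[13:24, , ] <- 1L
  truth <- LabelVolume(lab, codeTable = tissueClassTable())
  pm <- makePriors(truth, blurMm = 2)
  wm <- classMap(pm, "white_matter")
  expect_equal((wm[12, 4, 4] + wm[13, 4, 4]) / 2, 0.5, tolerance = 0.02)
  ## per-voxel sums are 1 in-mask
  sums <- mantis:::.probSums(voxelData(pm))
  expect_true(max(abs(sums[lab > 0] - 1)) < 1e-6)
  ## blur 0 gives exact one-hot priors
  pm0 <- makePriors(truth, blurMm = 0)
  expect_identical(classMap(pm0, "white_matter"), array(as.numeric(lab == 2L), d))
  expect_error(makePriors(truth, blurMm = -1), ">= 0")
})

test_that("planted pathology is isolated and volume-accurate", {
  s <- phantomSpec(seed = 8, nLesions = 2, nPockets = 2, pocketVolumeMm3 = 300)
  b <- generatePhantom(s)
  tr <- voxelData(b@truth)
  csf <- tr == 4L

  ## pocket volume within one voxel-volume of the requested 300 mm^3
  for (p in b@manifest$pockets)
    expect_lte(abs(p$volumeMm3 - 300), prod(voxelSpacing(b@t2)))

  ## pockets are isolated CSF components (face connectivity)
  cc <- connectedComponents(csf, 6L)
  for (p in b@manifest$pockets) {
    ids <- unique(cc[p$voxels])
    expect_length(ids, 1L)
    expect_equal(sum(cc == ids), p$nVoxels)
  }

  ## lesions are bright WM, strictly between WM and CSF means, and
  ## face-disconnected from all CSF
  t2 <- voxelData(b@t2)
  offs <- connectivityOffsets(6L)
  for (l in b@manifest$lesions) {
    expect_true(all(tr[l$voxels] == 2L))
    lesMask <- array(FALSE, dim(tr)); lesMask[l$voxels] <- TRUE
    near <- lesMask
    for (r in seq_len(nrow(offs)))
      near <- near | oshift(lesMask, offs[r, ], FALSE)
    expect_equal(sum(near & csf), 0)
  }

  ## ventricle enlargement: truth ventricle volume tracks the scale factor
  s3 <- phantomSpec(seed = 8, ventricleScale = 3)
  b3 <- generatePhantom(s3)
  ratio <- b3@manifest$ventricle$nVoxels / b3@manifest$ventriclePrior$nVoxels
  expect_lt(abs(ratio - 3) / 3, 0.1)
})

test_that("intensity separability: low-noise phantom is ML-classifiable >= 95%", {
  ## noise SD at most a quarter of the smallest between-class mean gap
  means <- mantis:::.defaultIntensities()
  gap <- min(diff(sort(means)))
  s <- phantomSpec(seed = 4, noiseSd = gap / 4, biasAmplitude = 0)
  b <- generatePhantom(s)
  tr <- voxelData(b@truth); t2 <- voxelData(b@t2)
  msk <- tr > 0
  ## no-prior maximum-likelihood classification with the generating params
  codes <- as.integer(names(tissueClassTable()))
  mu <- means[tissueClassTable()]
  ll <- vapply(seq_along(codes), function(i)
    dnorm(t2[msk], mu[i], gap / 4, log = TRUE), numeric(sum(msk)))
  got <- codes[max.col(ll, ties.method = "first")]
  expect_gte(mean(got == tr[msk]), 0.95)
})

test_that("infeasible phantoms fail with the violated constraint named", {
  expect_error(generatePhantom(phantomSpec(ventricleScale = 60)),
               "rim")
  expect_error(generatePhantom(phantomSpec(dims = c(24, 24, 24),
                                           nPockets = 3,
                                           pocketVolumeMm3 = 400)),
               "pocket")
  expect_error(phantomSpec(ventricleScale = 0.5), "ventricleScale")
  expect_error(phantomSpec(lesionIntensity = 400, nLesions = 1),
               "strictly between")
  expect_error(phantomSpec(intensityMeans = replace(
    mantis:::.defaultIntensities(), "csf", 90)), "ordering")
})

test_that("anisotropic coronal-style grids produce a proportionate phantom", {
  b <- generatePhantom(phantomSpec(dims = c(96, 96, 24),
                                   spacing = c(0.35, 0.35, 2.0), seed = 3))
  expect_equal(voxelSpacing(b@t2), c(0.35, 0.35, 2.0))
  expect_setequal(unique(as.vector(voxelData(b@truth))), 0:8)
  ## physical ventricle volume scales with the (33.6 mm / 64 mm) FOV factor
  expect_lt(abs(b@manifest$ventricle$volumeMm3 / (1319 * (33.6 / 64)^3) - 1),
            0.25)
})

test_that("phantom bundles round-trip to disk", {
  b <- generatePhantom(phantomSpec(dims = c(32, 32, 32), seed = 6))
  dir <- tempfile()
  writePhantom(b, dir)
  expect_true(file.exists(file.path(dir, "t2.nii.gz")))
  back <- loadVolume(file.path(dir, "truth.nii.gz"), "label")
  expect_identical(voxelData(back), voxelData(b@truth))
  expect_identical(codeTable(back), tissueClassTable())
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$ventricle$nVoxels, b@manifest$ventricle$nVoxels)
})
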