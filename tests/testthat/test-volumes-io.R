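test_that("NIfTI round-trip preserves data and geometry", {
  set.seed(42)
  d <- c(8L, 8L, 8L)
  vol <- ScalarVolume(array(rnorm(prod(d)), d), spacing = c(1, 1, 1))
  p <- tempfile(fileext = ".nii")
  writeVolume(vol, p)
  back <- loadVolume(p, "scalar")
  expect_equal(voxelData(back), voxelData(vol), tolerance = 1e-6)
  expect_equal(voxelSpacing(back), voxelSpacing(vol))

  ## float64 round-trip is exact
  writeVolume(vol, p, datatype = 64L)
  expect_identical(voxelData(loadVolume(p, "scalar")), voxelData(vol))

  ## integer labels round-trip bit-exactly, with the code-table sidecar
  lab <- LabelVolume(array(sample(0:8, prod(d), TRUE), d),
                     spacing = c(1, 1, 1), codeTable = tissueClassTable())
  pl <- tempfile(fileext = ".nii.gz")
  writeVolume(lab, pl)
  backL <- loadVolume(pl, "label")
  expect_identical(voxelData(backL), voxelData(lab))
  expect_identical(codeTable(backL), tissueClassTable())
})

test_that("anisotropic NeoBrainS12-style spacing survives a round-trip", {
  d <- c(12L, 12L, 6L)
  vol <- ScalarVolume(array(runif(prod(d)), d), spacing = c(0.35, 0.35, 2.0))
  p <- tempfile(fileext = ".nii.gz")
  writeVolume(vol, p)
  back <- loadVolume(p, "scalar")
  expect_equal(voxelSpacing(back), c(0.35, 0.35, 2.0), tolerance = 1e-6)
  expect_equal(voxelData(back), voxelData(vol), tolerance = 1e-6)
})

test_that("loader rejects contract violations", {
  expect_error(loadVolume(tempfile(), "scalar"), "not found")

  ## non-integral values are not a label volume
  p <- tempfile(fileext = ".nii")
  writeVolume(ScalarVolume(array(c(0.5, runif(26)), c(3, 3, 3))), p)
  expect_error(loadVolume(p, "label"), "non-integral")

  ## a truncated file is not NIfTI
  bad <- tempfile(fileext = ".nii")
  writeBin(raw(100), bad)
  expect_error(loadVolume(bad, "scalar"), "NIfTI")
})

test_that("nibabel agrees with the hand-rolled NIfTI writer and a 4D file errors", {
  py <- Sys.which("python")
  d <- c(5L, 6L, 7L)
  vol <- ScalarVolume(array(round(rnorm(prod(d)), 4), d),
                      spacing = c(0.7, 1, 1.4))
  p <- tempfile(fileext = ".nii")
  writeVolume(vol, p, datatype = 64L)
  out <- tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import nibabel, numpy as np\n",
    "img = nibabel.load('%s')\n",
    "d = np.asanyarray(img.dataobj)\n",
    "np.savetxt('%s', np.r_[d.shape, img.header.get_zooms(),",
    " [float(d.sum())], [float(d[2,3,4])]])\n",
    "nibabel.Nifti1Image(np.zeros((4,4,4,2)), np.eye(4)).to_filename('%s')\n"),
    p, out, paste0(p, "_4d.nii"))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2(py, sf, stdout = TRUE, stderr = TRUE)
  vals <- scan(out, quiet = TRUE)
  expect_equal(vals[1:3], as.numeric(d))
  expect_equal(vals[4:6], c(0.7, 1, 1.4), tolerance = 1e-5)
  expect_equal(vals[7], sum(voxelData(vol)), tolerance = 1e-8)
  expect_equal(vals[8], voxelData(vol)[3, 4, 5], tolerance = 1e-10)
  ## nibabel-written 4D volume is rejected with a clear message
  expect_error(loadVolume(paste0(p, "_4d.nii"), "scalar"), "expected 3D")
})

test_that("canonical reorientation round-trips through arbitrary axis flips", {
  set.seed(7)
  d <- c(6L, 5L, 4L)
  a <- array(rnorm(prod(d)), d)
  ## an affine with permuted, flipped axes: x->-z, y->x, z->y
  A <- matrix(0, 4, 4); A[4, 4] <- 1
  A[3, 1] <- -2; A[1, 2] <- 1; A[2, 3] <- 1.5
  A[1:3, 4] <- c(10, -4, 3)
  cano <- mantis:::.canonicalize(a, A)
  ## canonical affine has positive diagonal-dominant axes
  expect_true(all(diag(cano$affine[1:3, 1:3]) > 0))
  back <- mantis:::.decanonicalize(cano$data, cano$affine, cano$undo)
  expect_identical(back$data, a)
  expect_equal(back$affine, A)
})

test_that("resampling: identity, constancy and a linear-ramp oracle", {
  d <- c(16L, 16L, 16L)
  ramp <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d) * 2.5
  vol <- ScalarVolume(ramp, spacing = c(1, 1, 1))
  expect_equal(voxelData(resampleTo(vol, vol)), ramp, tolerance = 1e-12)

  ## constant probability map stays 1 inside the overlap
  pm <- ProbabilityMaps(array(1, c(d, 1L)), classes = "csf")
  ref <- ScalarVolume(array(0, c(8L, 8L, 8L)), spacing = c(1.5, 1.5, 1.5))
  rs <- resampleTo(ref, pm)
  expect_true(all(abs(voxelData(rs)[1:7, 1:7, 1:7, 1] - 1) < 1e-9))

  ## downsample by 2: values equal the ramp evaluated at new voxel centers
  ref2 <- ScalarVolume(array(0, c(8L, 8L, 8L)), spacing = c(2, 2, 2),
                       affine = diag(c(2, 2, 2, 1)))
  out <- voxelData(resampleTo(ref2, vol))
  expected <- array(rep((seq_len(8) - 1) * 2, times = 64), c(8, 8, 8)) * 2.5
  expect_equal(out, expected, tolerance = 1e-9)

  ## degenerate affine is rejected
  degen <- ScalarVolume(array(0, c(4L, 4L, 4L)), affine = matrix(0, 4, 4))
  expect_error(resampleTo(vol, degen), "degenerate")
})

test_that("probability maps stay valid after resampling", {
  set.seed(11)
  d <- c(10L, 10L, 10L)
  raw <- array(runif(prod(d) * 3), c(d, 3L))
  sums <- mantis:::.probSums(raw)
  for (k in 1:3) raw[, , , k] <- raw[, , , k] / pmax(sums, 1)
  pm <- ProbabilityMaps(raw, classes = c("a", "b", "c"))
  ref <- ScalarVolume(array(0, c(7L, 7L, 7L)), spacing = c(1.4, 1.4, 1.4),
                      affine = diag(c(1.4, 1.4, 1.4, 1)))
  rs <- resampleTo(ref, pm)
  arr <- voxelData(rs)
  expect_true(all(arr >= 0 & arr <= 1))
  expect_true(max(mantis:::.probSums(arr)) <= 1 + 1e-6)
})
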