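test_that("reconstruction by dilation: fixed cases", {
  ## marker == mask is a fixed point
  set.seed(1)
  m <- array(runif(27), c(3, 3, 3))
  expect_equal(as.vector(reconstructByDilation(m, m)), as.vector(m))

  ## 1D: isolated high value 3 is suppressed to the surrounding level 1
  mask <- c(0, 5, 1, 3, 1)
  marker <- c(0, 5, 0, 0, 0)
  out <- reconstructByDilation(marker, mask)
  expect_equal(as.vector(out), c(0, 5, 1, 1, 1))

  ## all-zero marker on a non-negative mask stays zero
  expect_equal(as.vector(reconstructByDilation(rep(0, 5), mask)), rep(0, 5))

  ## marker above mask: clipped with a warning, or an error if clip = FALSE
  expect_warning(reconstructByDilation(c(0, 6, 0, 0, 0), mask), "clipping")
  expect_error(reconstructByDilation(c(0, 6, 0, 0, 0), mask, clip = FALSE),
               "exceeds")
  expect_error(reconstructByDilation(array(0, c(2, 2, 2)), array(1, c(3, 3, 3))),
               "geometry")
})

test_that("reconstruction is idempotent, anti-extensive and matches the oracle", {
  set.seed(202)
  for (conn in c(6L, 26L)) {
    offs <- connectivityOffsets(conn)
    for (i in 1:15) {
      d <- randDims(4L, 10L)
      mask <- randControl(d, 6L)
      marker <- pmin(mask, randControl(d, 6L))
      out <- voxelData(
        reconstructByDilation(ScalarVolume(marker), ScalarVolume(mask), conn))
      expect_identical(out, oracleReconstruct(marker, mask, offs))
      expect_true(all(out <= mask) && all(out >= marker))
      ## idempotent: reconstructing from the result returns the result
      expect_identical(voxelData(reconstructByDilation(
        ScalarVolume(out), ScalarVolume(mask), conn)), out)
    }
  }
})

test_that("watershed from markers: fixed cases and the documented tie rule", {
  ## a single marker floods the whole domain
  seeds <- array(0L, c(4, 4, 4)); seeds[2, 2, 2] <- 5L
  ws <- watershedFromMarkers(array(runif(64), c(4, 4, 4)), seeds)
  expect_true(all(ws == 5L))

  ## 1D ridge: flooding from both ends, ridge voxel assigned by the
  ## FIFO/label-order tie rule (seed A pushed first wins the ridge)
  control <- c(0, 1, 9, 1, 0)
  seeds <- c(1L, 0L, 0L, 0L, 2L)
  out <- as.vector(watershedFromMarkers(control, seeds))
  expect_equal(out, c(1L, 1L, 1L, 2L, 2L))
  expect_identical(array(out, c(5L, 1L, 1L)),
                   oracleWatershed(array(control, c(5, 1, 1)),
                                   array(seeds, c(5, 1, 1)),
                                   connectivityOffsets(6L)))

  ## 2D: a high ridge in column 3 separates left and right floods
  ctl <- array(0, c(5, 5, 1)); ctl[3, , 1] <- 9
  sd2 <- array(0L, c(5, 5, 1)); sd2[1, 3, 1] <- 1L; sd2[5, 3, 1] <- 2L
  lab <- array(as.vector(watershedFromMarkers(ctl, sd2)), c(5, 5, 1))
  expect_true(all(lab[1:2, , ] == 1L))
  expect_true(all(lab[4:5, , ] == 2L))
  expect_true(all(lab %in% c(1L, 2L)))
  expect_identical(lab, oracleWatershed(ctl, sd2, connectivityOffsets(6L)))

  expect_error(watershedFromMarkers(ctl, array(0L, c(5, 5, 1))), "empty marker")
})

test_that("watershed matches the priority-flood oracle and is monotone-invariant", {
  set.seed(303)
  for (conn in c(6L, 26L)) {
    offs <- connectivityOffsets(conn)
    for (i in 1:15) {
      d <- randDims(4L, 9L)
      ctl <- randControl(d, 4L)
      seeds <- array(0L, d)
      nSeeds <- sample(2:3, 1)
      pos <- sample(prod(d), nSeeds)
      seeds[pos] <- seq_len(nSeeds)
      out <- voxelData(watershedFromMarkers(ScalarVolume(ctl),
                                            LabelVolume(seeds), conn))
      expect_identical(out, oracleWatershed(ctl, seeds, offs))
      ## complete partition, seeds keep their labels
      expect_true(all(out > 0L))
      expect_identical(out[pos], seq_len(nSeeds))
      ## invariant under the monotone transform x -> x^3
      out2 <- voxelData(watershedFromMarkers(ScalarVolume(ctl^3),
                                             LabelVolume(seeds), conn))
      expect_identical(out2, out)
    }
  }
})

test_that("small-component filtering uses physical volume", {
  d <- c(30L, 12L, 12L)
  m <- array(FALSE, d)
  m[1:5, 1:10, 1:8] <- TRUE     # 400 voxels
  m[11:16, 1:10, 1:10] <- TRUE  # 600 voxels
  out <- filterSmallComponents(m, 500, spacing = c(1, 1, 1))
  expect_equal(sum(out), 600)
  expect_true(all(which(out) > 5 * 1))  # only the second blob survives

  ## at (1, 1, 2) mm the same blobs are 800 and 1200 mm^3: both survive
  out2 <- filterSmallComponents(m, 500, spacing = c(1, 1, 2))
  expect_equal(sum(out2), 1000)

  expect_equal(sum(filterSmallComponents(array(FALSE, d), 500)), 0)
  expect_error(filterSmallComponents(m, 0), "positive")
  expect_error(filterSmallComponents(m, -5), "positive")
})

test_that("connected components match the flood-fill oracle", {
  set.seed(404)
  for (conn in c(6L, 18L, 26L)) {
    offs <- connectivityOffsets(conn)
    for (i in 1:8) {
      d <- randDims(4L, 9L)
      m <- array(runif(prod(d)) < 0.4, d)
      cc <- connectedComponents(m, conn)
      oc <- oracleComponents(m, offs)
      expect_identical(cc, oc)
      expect_true(all((cc > 0L) == m))  # background never relabeled
    }
  }
})

test_that("multiscale gradient: zero on constants, closed-form step response", {
  cst <- array(7, c(10, 10, 10))
  g <- multiscaleGradient(cst, c(1))
  expect_true(max(abs(g)) < 1e-10)
  expect_true(all(voxelData(multiscaleGradient(
    ScalarVolume(array(runif(1000), c(10, 10, 10))), c(0.5, 1))) >= 0))

  ## 1D step of height h: peak response h / (sigma * sqrt(2 * pi)) per scale
  n <- 61L
  h <- 4
  step <- array(rep(c(0, h), c(30, 31)), c(n, 1, 1))
  for (sig in c(2, 3)) {
    g <- as.vector(multiscaleGradient(step, sig))
    expect_lt(abs(max(g) - h / (sig * sqrt(2 * pi))) / (h / (sig * sqrt(2 * pi))),
              0.05)
    expect_equal(which.max(g) %in% c(30L, 31L), TRUE)  # peak at the edge
  }

  ## default scales are 0.25 mm and the minimum voxel dimension
  set.seed(5)
  vol <- ScalarVolume(array(runif(6^3), c(6, 6, 6)), spacing = c(1, 1, 2))
  expect_equal(voxelData(multiscaleGradient(vol)),
               voxelData(multiscaleGradient(vol, c(0.25, 1))))

  ## physical units: a ramp of slope s per mm responds with s on any axis
  d <- c(20L, 4L, 20L)
  rampZ <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d) * 2 * 3  # 3/mm at dz=2
  vol <- ScalarVolume(rampZ, spacing = c(1, 1, 2))
  g <- voxelData(multiscaleGradient(vol, 2))
  expect_lt(abs(g[10, 2, 10] - 3) / 3, 0.02)

  expect_error(multiscaleGradient(cst, numeric(0)), "at least one")
  expect_error(multiscaleGradient(cst, c(1, -1)), "positive")
})
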