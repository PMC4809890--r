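test_that("Dice: fixed cases, symmetry, both-empty convention", {
  d <- c(6L, 6L, 6L)
  a <- array(FALSE, d); a[1:2, 1:2, 1:2] <- TRUE      # 8 voxels
  b <- array(FALSE, d); b[1:2, 1:2, 2:3] <- TRUE      # 8 voxels, 4 shared
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, b), 0.5)
  expect_equal(diceCoefficient(a, !a & FALSE), 0)     # disjoint
  expect_equal(diceCoefficient(array(FALSE, d), array(FALSE, d)), 1)
  set.seed(1)
  x <- array(runif(prod(d)) < 0.3, d); y <- array(runif(prod(d)) < 0.3, d)
  expect_equal(diceCoefficient(x, y), diceCoefficient(y, x))
  expect_error(diceCoefficient(a, array(FALSE, c(2, 2, 2))), "mismatch")
})

test_that("surface distances: fixed cases and spacing linearity", {
  d <- c(10L, 6L, 6L)
  a <- array(FALSE, d); a[2, 3, 3] <- TRUE
  b <- array(FALSE, d); b[5, 3, 3] <- TRUE            # 3 voxels apart on x
  sd1 <- surfaceDistances(a, b, spacing = c(1, 1, 1))
  expect_equal(unname(sd1), c(3, 3))
  expect_equal(unname(surfaceDistances(a, a, spacing = c(1, 1, 1))), c(0, 0))
  ## doubling the spacing doubles every mm distance
  sd2 <- surfaceDistances(a, b, spacing = c(2, 2, 2))
  expect_equal(unname(sd2), 2 * unname(sd1))
  expect_error(surfaceDistances(a, array(FALSE, d), spacing = c(1, 1, 1)),
               "undefined surface distance")
})

test_that("surface distances match the exhaustive all-pairs oracle", {
  set.seed(21)
  for (i in 1:10) {
    d <- c(12L, 12L, 12L)
    a <- array(runif(prod(d)) < 0.25, d)
    b <- array(runif(prod(d)) < 0.25, d)
    if (!any(a) || !any(b)) next
    sp <- c(1, 1.3, 0.8)
    got <- surfaceDistances(a, b, spacing = sp)
    want <- oracleSurfaceDistances(a, b, sp)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("sensitivity/specificity within the evaluation domain", {
  d <- c(10L, 10L, 1L)
  domain <- array(TRUE, d)
  ref <- array(FALSE, d); cand <- array(FALSE, d)
  ## printed-count fixture: TP=40, FN=10, TN=45, FP=5 on a 100-voxel domain
  ref[1:50] <- TRUE
  cand[1:40] <- TRUE        # TP = 40, FN = 10
  cand[51:55] <- TRUE       # FP = 5, TN = 45
  ss <- sensitivitySpecificity(cand, ref, domain)
  expect_equal(unname(ss), c(0.8, 0.9))

  expect_equal(unname(sensitivitySpecificity(ref, ref, domain)), c(1, 1))
  ## labeling the whole domain: perfect sensitivity, zero specificity
  expect_equal(unname(sensitivitySpecificity(domain, ref, domain)), c(1, 0))
  ## empty reference: NaN sensitivity with warning
  expect_warning(ss0 <- sensitivitySpecificity(cand, array(FALSE, d), domain),
                 "undefined")
  expect_true(is.nan(ss0["sensitivity"]))
  expect_error(sensitivitySpecificity(cand, ref, array(FALSE, d)), "empty")
})

test_that("confusion matrix: fixed cases and exhaustive tally oracle", {
  tab <- tissueClassTable()
  d <- c(10L, 10L, 10L)
  set.seed(8)
  ca <- array(sample(0:8, prod(d), TRUE), d)
  cm <- confusionMatrix(ca, ca)
  diagOk <- vapply(seq_len(8), function(i)
    if (any(ca == i)) cm[i, i] == 100 else TRUE, logical(1))
  expect_true(all(diagOk))

  ## candidate all class 1, reference half 1 / half 2
  ca1 <- array(1L, d)
  re <- array(rep(c(1L, 2L), each = prod(d) / 2), d)
  cm2 <- confusionMatrix(ca1, re)
  expect_equal(unname(cm2[1, 1:2]), c(50, 50))

  ## random labels vs the tally oracle; rows sum to 100
  re2 <- array(sample(0:8, prod(d), TRUE), d)
  got <- confusionMatrix(ca, re2)
  want <- oracleConfusion(ca, re2, 1:8)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  rs <- rowSums(got)[rowSums(got) > 0]
  expect_true(all(abs(rs - 100) < 0.1))
})

test_that("full evaluation: identity, merging and a shifted-cube closed form", {
  tab <- tissueClassTable()
  d <- c(16L, 16L, 16L)
  set.seed(3)
  lab <- array(sample(0:8, prod(d), TRUE, prob = c(2, rep(1, 8))), d)
  ref <- LabelVolume(lab, codeTable = tab)
  rep0 <- evaluateSegmentation(ref, ref)
  expect_true(all(rep0@perClass$dice == 1))
  expect_true(all(rep0@perClass$msd == 0, na.rm = TRUE))
  expect_true(all(rep0@perClass$hausdorff >= rep0@perClass$msd, na.rm = TRUE))

  ## merged evaluation folds hippocampus/amygdala into cortical GM
  repM <- evaluateSegmentation(ref, ref, mergeNeoBrainS = TRUE)
  expect_false(any(c("hippocampus", "amygdala") %in% repM@perClass$class))
  expect_equal(nrow(repM@perClass), 6L)
  expect_true(all(repM@perClass$dice == 1))

  ## cube shifted by one voxel: Dice = 2*7*64 / (512 + 512) = 0.875;
  ## distances must match the exhaustive oracle
  a <- array(0L, d); a[5:12, 5:12, 5:12] <- 4L
  b <- array(0L, d); b[6:13, 5:12, 5:12] <- 4L
  ca <- LabelVolume(a, codeTable = tab); cb <- LabelVolume(b, codeTable = tab)
  repS <- evaluateSegmentation(ca, cb)
  i <- which(repS@perClass$class == "csf")
  expect_equal(repS@perClass$dice[i], 0.875)
  want <- oracleSurfaceDistances(a == 4L, b == 4L, c(1, 1, 1))
  expect_equal(repS@perClass$msd[i], unname(want["msd"]), tolerance = 1e-12)
  expect_equal(repS@perClass$hausdorff[i], unname(want["hausdorff"]),
               tolerance = 1e-12)

  ## report serialization writes JSON + CSVs
  pre <- tempfile()
  paths <- writeMetricsReport(repS, pre)
  expect_true(all(file.exists(paths)))
})
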