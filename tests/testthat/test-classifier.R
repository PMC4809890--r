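## small helpers to build classifier inputs on a cube grid
cubePriors <- function(maps, classes, spacing = c(1, 1, 1)) {
  ProbabilityMaps(maps, classes = classes, spacing = spacing)
}

test_that("mixture initialization: closed forms and degenerate priors", {
  set.seed(9)
  d <- c(8L, 8L, 8L)
  y <- array(rnorm(prod(d), 100, 10), d)
  img <- ScalarVolume(y)
  msk <- array(TRUE, d)
  w <- array(runif(prod(d)), d)

  ## single component: mean equals the prior-weighted intensity mean
  pm <- cubePriors(list(w), "csf")
  mix <- initializeMixture(img, msk, pm, classifierConfig(gaussiansPerClass = 1))
  expect_equal(mix$means[1, 1], sum(w * y) / sum(w), tolerance = 1e-12)

  ## two components: means at the 25th/75th prior-weighted percentiles
  ## (independent direct computation)
  mix2 <- initializeMixture(img, msk, pm, classifierConfig(gaussiansPerClass = 2))
  ord <- order(as.vector(y))
  cw <- cumsum(as.vector(w)[ord]) / sum(w)
  q25 <- as.vector(y)[ord][which(cw >= 0.25)[1]]
  q75 <- as.vector(y)[ord][which(cw >= 0.75)[1]]
  expect_equal(unname(mix2$means[1, ]), c(q25, q75))

  ## zero prior mass falls back to epsilon with a warning
  pm0 <- cubePriors(list(w, array(0, d)), c("a", "b"))
  expect_warning(initializeMixture(img, msk, pm0, classifierConfig()),
                 "zero total prior mass")
})

test_that("hard labels: argmax, documented tie rule, out-of-mask zero", {
  d <- c(2L, 2L, 1L)
  tab <- tissueClassTable()
  arr <- array(0, c(d, 8L))
  arr[1, 1, 1, 4] <- 1                      # one-hot CSF
  arr[2, 1, 1, 2] <- 0.5; arr[2, 1, 1, 4] <- 0.5  # exact WM/CSF tie
  arr[1, 2, 1, 1] <- 0.4; arr[1, 2, 1, 2] <- 0.35; arr[1, 2, 1, 3] <- 0.25
  ## [2, 2, 1] all zero: out of mask
  pm <- cubePriors(array(arr, c(d, 8L)), unname(tab))
  lab <- voxelData(hardLabels(pm))
  expect_equal(lab[1, 1, 1], 4L)
  expect_equal(lab[2, 1, 1], 2L)   # tie broken toward the lower code (WM)
  expect_equal(lab[1, 2, 1], 1L)   # plain argmax
  expect_equal(lab[2, 2, 1], 0L)
})

test_that("EM recovers a two-class mixture with flat priors", {
  set.seed(31)
  d <- c(12L, 12L, 12L)
  n <- prod(d)
  z <- runif(n) < 0.5
  y <- ifelse(z, rnorm(n, 100, 5), rnorm(n, 150, 5))
  img <- ScalarVolume(array(y, d))
  msk <- array(TRUE, d)
  pm <- cubePriors(list(array(0.5, d), array(0.5, d)), c("a", "b"))
  cfg <- classifierConfig(gaussiansPerClass = 1L, biasOrder = 0L,
                          maxIterations = 60L, tolerance = 1e-8)
  fit <- fitTissueClassifier(img, msk, pm, cfg)
  mu <- sort(fit@mixture$means[, 1])
  expect_lt(abs(mu[1] - 100) / 100, 0.02)
  expect_lt(abs(mu[2] - 150) / 150, 0.02)
  ## log-likelihood trace is non-decreasing (within relative slack)
  ll <- fit@logLik
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
})

test_that("well-separated classes sampled from priors are recovered >= 99%", {
  set.seed(77)
  d <- c(16L, 16L, 16L)
  n <- prod(d)
  ## three one-hot spatial blocks as priors; means separated by >= 10 SD
  lab <- array(1L, d); lab[, , 6:10] <- 2L; lab[, , 11:16] <- 3L
  maps <- lapply(1:3, function(k) array(as.numeric(lab == k), d))
  pm <- cubePriors(maps, c("a", "b", "c"))
  means <- c(50, 150, 250); sdv <- 5
  y <- array(rnorm(n, means[lab], sdv), d)
  msk <- array(TRUE, d)
  fit <- fitTissueClassifier(ScalarVolume(y), msk, pm,
                             classifierConfig(biasOrder = 0L))
  got <- voxelData(hardLabels(fit@posteriors))
  expect_gte(mean(got == lab), 0.99)

  ## posterior normalization: sums 1 in-mask
  sums <- mantis:::.probSums(voxelData(fit@posteriors))
  expect_true(max(abs(sums - 1)) < 1e-6)
})

test_that("posteriors are zero outside the mask and errors are explicit", {
  set.seed(13)
  d <- c(8L, 8L, 8L)
  y <- array(rnorm(prod(d), 100, 10), d)
  msk <- array(FALSE, d); msk[3:6, 3:6, 3:6] <- TRUE
  pm <- cubePriors(list(array(1, d)), "a")
  fit <- fitTissueClassifier(ScalarVolume(y), msk, pm,
                             classifierConfig(biasOrder = 0L))
  post <- voxelData(fit@posteriors)[, , , 1]
  expect_true(all(post[!msk] == 0))
  expect_true(all(abs(post[msk] - 1) < 1e-9))

  expect_error(fitTissueClassifier(ScalarVolume(y), array(FALSE, d), pm),
               "empty brain mask")
  expect_error(
    fitTissueClassifier(ScalarVolume(array(5, d)), msk, pm),
    "constant")
})

test_that("a known smooth multiplicative bias field is recovered", {
  set.seed(19)
  d <- c(24L, 24L, 24L)
  n <- prod(d)
  lab <- array(sample(1:2, n, TRUE), d)
  means <- c(100, 200)
  y0 <- rnorm(n, means[lab], 4)
  ## smooth +-20% bias: low-order polynomial in normalized coords
  co <- (arrayInd(seq_len(n), d) - (d[1] + 1) / 2) / ((d[1] - 1) / 2)
  lb <- 0.12 * co[, 1] - 0.1 * co[, 2] + 0.08 * co[, 3]^2 +
    0.06 * co[, 1] * co[, 2]
  lb <- lb - mean(lb)
  bias <- exp(lb / max(abs(lb)) * log(1.2))
  y <- array(y0 * bias, d)
  msk <- array(TRUE, d)
  pm <- cubePriors(list(array(as.numeric(lab == 1), d),
                        array(as.numeric(lab == 2), d)), c("a", "b"))
  fit <- fitTissueClassifier(ScalarVolume(y), msk, pm,
                             classifierConfig(gaussiansPerClass = 1L,
                                              maxIterations = 40L))
  est <- as.vector(voxelData(fit@biasField))
  expect_gt(cor(est, bias), 0.95)
})

test_that("externally supplied posteriors can stand in for phase 1", {
  d <- c(6L, 6L, 6L)
  tab <- tissueClassTable()
  arr <- array(0, c(d, 8L))
  arr[, , , 2] <- 1
  pm <- cubePriors(array(arr, c(d, 8L)), unname(tab))
  res <- classifierResultFromPosteriors(pm, array(TRUE, d))
  expect_s4_class(res, "ClassifierResult")
  expect_true(all(voxelData(hardLabels(res@posteriors)) == 2L))
  expect_true(all(voxelData(res@biasField) == 1))
})
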