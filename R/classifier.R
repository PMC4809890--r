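#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Atlas-prior Gaussian-mixture EM tissue classification with smooth
## multiplicative bias correction: the simplified stand-in for unified
## segmentation used by phases 1 and 4. The registration sub-model is not
## reimplemented; priors are assumed grid-aligned (or pre-aligned with
## resampleTo()).
## ---------------------------------------------------------------------------

#' Classifier configuration
#'
#' Defaults mirror the pipeline's standard settings: 2 Gaussians per tissue
#' class, very light bias regularization (1e-4) and a 60 mm bias smoothness
#' scale. The smoothness scale is recorded for provenance; the bias model
#' here is a low-order polynomial (total degree `biasOrder`) over the brain
#' bounding box, whose effective smoothness for typical neonatal fields of
#' view corresponds to fields of roughly that FWHM.
#'
#' @slot gaussiansPerClass components per tissue class (>= 1; default 2).
#' @slot biasOrder polynomial total degree of the log-bias field (default 3;
#'   0 disables bias correction).
#' @slot biasFwhmMm smoothness analog in mm (default 60; recorded).
#' @slot biasRegularization ridge penalty on the bias fit (default 1e-4).
#' @slot maxIterations EM iteration cap (default 30).
#' @slot tolerance relative convergence tolerance on the mean
#'   log-likelihood (default 1e-5).
#' @slot varianceFloorFrac variance floor as a fraction of the in-mask
#'   intensity variance (default 1e-6).
#' @slot seed RNG seed recorded for provenance (the fit itself is
#'   deterministic).
#' @export
setClass("ClassifierConfig",
  representation(gaussiansPerClass = "integer", biasOrder = "integer",
                 biasFwhmMm = "numeric", biasRegularization = "numeric",
                 maxIterations = "integer", tolerance = "numeric",
                 varianceFloorFrac = "numeric", seed = "integer"))

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (object@gaussiansPerClass < 1L) msg <- c(msg, "gaussiansPerClass must be >= 1")
  if (object@tolerance <= 0) msg <- c(msg, "tolerance must be > 0")
  if (object@biasRegularization < 0) msg <- c(msg, "biasRegularization must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a ClassifierConfig
#'
#' @param gaussiansPerClass,biasOrder,biasFwhmMm,biasRegularization,maxIterations,tolerance,varianceFloorFrac,seed
#'   see [ClassifierConfig-class].
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(gaussiansPerClass = 2L, biasOrder = 3L,
                             biasFwhmMm = 60, biasRegularization = 1e-4,
                             maxIterations = 30L, tolerance = 1e-5,
                             varianceFloorFrac = 1e-6, seed = 1L) {
  new("ClassifierConfig",
      gaussiansPerClass = as.integer(gaussiansPerClass),
      biasOrder = as.integer(biasOrder), biasFwhmMm = biasFwhmMm,
      biasRegularization = biasRegularization,
      maxIterations = as.integer(maxIterations), tolerance = tolerance,
      varianceFloorFrac = varianceFloorFrac, seed = as.integer(seed))
}

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf(paste0("ClassifierConfig: %d Gaussians/class, bias order %d ",
                     "(%g mm analog, reg %g), <= %d iterations, tol %g\n"),
              object@gaussiansPerClass, object@biasOrder, object@biasFwhmMm,
              object@biasRegularization, object@maxIterations,
              object@tolerance))
})

#' Result of a tissue classification fit
#'
#' @slot posteriors [ProbabilityMaps-class]; per-voxel sums are 1 inside the
#'   brain mask and 0 outside.
#' @slot biasField [ScalarVolume-class]; multiplicative, mean 1 in-mask.
#' @slot mixture list with per-class component weights, means, variances.
#' @slot logLik numeric log-likelihood trace (non-decreasing within
#'   tolerance).
#' @slot mask [LabelVolume-class] binary brain mask used for the fit.
#' @export
setClass("ClassifierResult",
  representation(posteriors = "ProbabilityMaps", biasField = "ScalarVolume",
                 mixture = "list", logLik = "numeric", mask = "LabelVolume"))

setMethod("show", "ClassifierResult", function(object) {
  cat(sprintf("ClassifierResult: %d classes, %d EM iterations, logLik %.4g\n",
              length(classNames(object@posteriors)), length(object@logLik),
              if (length(object@logLik)) tail(object@logLik, 1) else NA_real_))
})

## polynomial design matrix: total degree <= order over normalized coords
.biasBasis <- function(coords, order) {
  pows <- expand.grid(px = 0:order, py = 0:order, pz = 0:order)
  pows <- pows[rowSums(pows) <= order, , drop = FALSE]
  pows <- pows[order(rowSums(pows), pows$pz, pows$py, pows$px), , drop = FALSE]
  X <- matrix(1, nrow(coords), nrow(pows))
  for (c in seq_len(nrow(pows))) {
    X[, c] <- coords[, 1]^pows$px[c] * coords[, 2]^pows$py[c] *
      coords[, 3]^pows$pz[c]
  }
  X
}

## normalized [-1, 1] coordinates of the mask voxels w.r.t. the mask bbox
.normCoords <- function(maskIdx, dims) {
  co <- arrayInd(maskIdx, dims)
  out <- matrix(0, length(maskIdx), 3L)
  for (k in 1:3) {
    r <- range(co[, k])
    den <- max(r[2] - r[1], 1L)
    out[, k] <- 2 * (co[, k] - r[1]) / den - 1
  }
  out
}

## weighted quantile: smallest value with cumulative weight >= q * total
.weightedQuantile <- function(x, w, q) {
  o <- order(x)
  cw <- cumsum(w[o])
  tot <- cw[length(cw)]
  vapply(q, function(qq) x[o][which(cw >= qq * tot)[1L]], numeric(1))
}

#' Initialize mixture parameters from prior-weighted intensities
#'
#' Per class, component means are placed at evenly spaced prior-weighted
#' intensity quantiles ((2j - 1) / (2m) for m >= 2 components; the
#' prior-weighted mean for a single component), variances at the
#' prior-weighted class variance, and component weights uniform. Classes
#' with zero total prior mass fall back to uniform epsilon weighting with a
#' warning. Fully deterministic.
#'
#' @param image [ScalarVolume-class].
#' @param mask binary [LabelVolume-class] (or logical array).
#' @param priors [ProbabilityMaps-class] on the image grid.
#' @param config a [ClassifierConfig-class].
#' @return list with matrices `weights`, `means`, `variances`
#'   (class x component) and `classes`.
#' @export
initializeMixture <- function(image, mask, priors,
                              config = classifierConfig()) {
  y <- as.numeric(voxelData(image))
  msk <- .as3d(mask) != 0
  inIdx <- which(msk)
  y <- y[inIdx]
  arr <- voxelData(priors)
  K <- dim(arr)[4L]; m <- config@gaussiansPerClass
  W <- matrix(as.numeric(arr), ncol = K)[inIdx, , drop = FALSE]
  gvar <- stats::var(y)
  means <- vars <- matrix(0, K, m)
  for (k in seq_len(K)) {
    w <- W[, k]
    if (sum(w) <= 0) {
      warning("class '", classNames(priors)[k],
              "' has zero total prior mass; uniform epsilon fallback")
      w <- rep(1e-6, length(w))
    }
    if (m == 1L) means[k, ] <- sum(w * y) / sum(w)
    else means[k, ] <- .weightedQuantile(y, w, (2 * seq_len(m) - 1) / (2 * m))
    mu <- sum(w * y) / sum(w)
    v <- sum(w * (y - mu)^2) / sum(w)
    vars[k, ] <- max(v, config@varianceFloorFrac * gvar, 1e-12)
    W[, k] <- w
  }
  ## Symmetry tie-break: classes whose prior weighting is identical (e.g.
  ## flat priors) would start EM at the same parameters and never separate.
  ## Spread each such group across its quantile range, deterministically in
  ## class order.
  key <- apply(cbind(means, vars), 1L, function(r)
    paste(signif(r, 12), collapse = "|"))
  for (kk in unique(key)) {
    grp <- which(key == kk)
    G <- length(grp)
    if (G < 2L) next
    for (g in seq_len(G)) {
      k <- grp[g]
      q <- ((g - 1) + (2 * seq_len(m) - 1) / (2 * m)) / G
      means[k, ] <- .weightedQuantile(y, W[, k], q)
    }
  }
  list(weights = matrix(1 / m, K, m), means = means, variances = vars,
       classes = classNames(priors))
}

## log joint density matrix: rows = voxels, cols = (class, comp) pairs,
## including the class prior. Returns list(logJoint (m x K*J), perClass).
.logJoint <- function(yc, logPrior, mix) {
  K <- nrow(mix$means); J <- ncol(mix$means)
  out <- matrix(-Inf, length(yc), K * J)
  for (k in seq_len(K)) {
    lp <- logPrior[, k]
    finite <- is.finite(lp)
    if (!any(finite)) next
    for (j in seq_len(J)) {
      col <- (k - 1L) * J + j
      out[finite, col] <- lp[finite] + log(mix$weights[k, j]) +
        dnorm(yc[finite], mix$means[k, j], sqrt(mix$variances[k, j]),
              log = TRUE)
    }
  }
  out
}

#' Fit the atlas-prior Gaussian-mixture tissue classifier
#'
#' EM alternates (i) responsibilities proportional to
#' `prior_k(voxel) * sum_j w_kj N(y / b; mu_kj, sigma^2_kj)`, (ii) M-step
#' updates of the weights, means and variances, and (iii) re-estimation of
#' the multiplicative bias field as a ridge-regularized polynomial fit to
#' the log-ratio of observed to predicted intensity. A bias update is kept
#' only if it does not decrease the observed-data log-likelihood, so the
#' trace is monotone. Deterministic given the configuration.
#'
#' @param image [ScalarVolume-class] (brain-extracted T2-weighted image).
#' @param mask binary brain mask ([LabelVolume-class] or logical array);
#'   must be non-empty.
#' @param priors [ProbabilityMaps-class] on the image grid (one map per
#'   tissue class; a zero prior gates the posterior to zero).
#' @param config a [ClassifierConfig-class].
#' @param verbose print per-iteration log-likelihoods.
#' @return a [ClassifierResult-class].
#' @export
fitTissueClassifier <- function(image, mask, priors,
                                config = classifierConfig(),
                                verbose = FALSE) {
  stopifnot(is(image, "ScalarVolume"), is(priors, "ProbabilityMaps"))
  dims <- dim(voxelData(image))
  msk <- .as3d(mask) != 0
  if (!identical(dim(msk), dims) ||
      !identical(dim(voxelData(priors))[1:3], dims))
    stop("geometry mismatch: image, mask and priors must share the grid")
  inIdx <- which(msk)
  if (length(inIdx) == 0L) stop("empty brain mask")
  y <- as.numeric(voxelData(image))[inIdx]
  if (stats::var(y) <= 0)
    stop("degenerate input: image is constant inside the mask")

  arr <- voxelData(priors)
  K <- dim(arr)[4L]
  P <- matrix(as.numeric(arr), ncol = K)[inIdx, , drop = FALSE]
  ## renormalize priors over the tissue classes inside the brain mask
  zeroMass <- colSums(P) <= 0
  if (any(zeroMass)) {
    warning("classes with zero total prior mass: ",
            paste(classNames(priors)[zeroMass], collapse = ", "),
            "; uniform epsilon fallback")
    P[, zeroMass] <- 1e-6
  }
  rs <- rowSums(P)
  flat <- rs <= 0
  if (any(flat)) P[flat, ] <- 1 / K
  rs[flat] <- 1
  P <- P / rs
  logPrior <- log(P)   # -Inf where the prior is exactly zero

  mix <- initializeMixture(image, msk, priors, config)
  gvar <- stats::var(y)
  floorVar <- max(config@varianceFloorFrac * gvar, 1e-12)
  m <- length(y)
  J <- config@gaussiansPerClass

  useBias <- config@biasOrder >= 1L
  b <- rep(1, m)
  if (useBias) {
    X <- .biasBasis(.normCoords(inIdx, dims), config@biasOrder)
    lambda <- config@biasRegularization * m
    XtX <- crossprod(X)
  }

  loglikOf <- function(bField, mixState) {
    yc <- y / bField
    lj <- .logJoint(yc, logPrior, mixState)
    sum(.logRowSumExp(lj)) - sum(log(bField))
  }

  trace <- numeric(0)
  ll <- loglikOf(b, mix)
  for (it in seq_len(config@maxIterations)) {
    yc <- y / b
    lj <- .logJoint(yc, logPrior, mix)
    tot <- .logRowSumExp(lj)
    resp <- exp(lj - tot)                 # m x (K*J)

    ## M-step
    nkj <- colSums(resp)
    for (k in seq_len(K)) {
      cols <- (k - 1L) * J + seq_len(J)
      nk <- sum(nkj[cols])
      if (nk <= 0) next
      mix$weights[k, ] <- pmax(nkj[cols], 1e-12) / max(nk, 1e-12)
      for (j in seq_len(J)) {
        col <- cols[j]
        if (nkj[col] <= 1e-12) next
        mu <- sum(resp[, col] * yc) / nkj[col]
        v <- sum(resp[, col] * (yc - mu)^2) / nkj[col]
        mix$means[k, j] <- mu
        mix$variances[k, j] <- max(v, floorVar)
      }
    }

    llNew <- loglikOf(b, mix)

    ## bias step: log b ~ log y - log(predicted intensity); the update is
    ## kept only if it does not decrease the log-likelihood
    if (useBias) {
      pred <- as.numeric(resp %*% as.numeric(t(mix$means)))
      ok <- y > 0 & pred > 0
      if (sum(ok) > ncol(X)) {
        t_i <- log(y[ok]) - log(pred[ok])
        beta <- solve(crossprod(X[ok, , drop = FALSE]) +
                        diag(lambda, ncol(X)),
                      crossprod(X[ok, , drop = FALSE], t_i))
        lb <- as.numeric(X %*% beta)
        lb <- lb - mean(lb)
        bNew <- exp(lb)
        llBias <- loglikOf(bNew, mix)
        if (llBias >= llNew - 1e-9 * abs(llNew)) {
          b <- bNew
          llNew <- llBias
        }
      }
    }
    trace <- c(trace, llNew)
    .msg(verbose, sprintf("EM iteration %d: logLik %.6f", it, llNew))
    if (it > 1L && abs(llNew - ll) <= config@tolerance * abs(ll)) {
      ll <- llNew
      break
    }
    ll <- llNew
  }

  ## final responsibilities on the converged parameters
  yc <- y / b
  lj <- .logJoint(yc, logPrior, mix)
  tot <- .logRowSumExp(lj)
  resp <- exp(lj - tot)
  post <- array(0, c(dims, K))
  flat3 <- prod(dims)
  for (k in seq_len(K)) {
    cols <- (k - 1L) * J + seq_len(J)
    pk <- rowSums(resp[, cols, drop = FALSE])
    slab <- numeric(flat3)
    slab[inIdx] <- pk
    post[, , , k] <- slab
  }
  ## normalize the mean of the bias field to 1 inside the mask
  b <- b / mean(b)
  bf <- rep(1, flat3); bf[inIdx] <- b
  maskLab <- LabelVolume(array(as.integer(msk), dims),
                         spacing = voxelSpacing(image),
                         codeTable = c("1" = "brain"),
                         affine = voxelAffine(image))
  new("ClassifierResult",
      posteriors = ProbabilityMaps(post, classes = classNames(priors),
                                   spacing = voxelSpacing(image),
                                   affine = voxelAffine(image)),
      biasField = ScalarVolume(array(bf, dims),
                               spacing = voxelSpacing(image),
                               affine = voxelAffine(image)),
      mixture = mix, logLik = trace, mask = maskLab)
}

#' Wrap externally produced posteriors as a ClassifierResult
#'
#' Interface contract for substituting probability maps computed by an
#' external implementation of unified segmentation for phase 1.
#'
#' @param posteriors [ProbabilityMaps-class].
#' @param mask binary brain mask.
#' @return a [ClassifierResult-class] with unit bias field and no mixture.
#' @export
classifierResultFromPosteriors <- function(posteriors, mask) {
  dims <- dim(voxelData(posteriors))[1:3]
  msk <- .as3d(mask) != 0
  maskLab <- LabelVolume(array(as.integer(msk), dims),
                         spacing = voxelSpacing(posteriors),
                         codeTable = c("1" = "brain"),
                         affine = voxelAffine(posteriors))
  new("ClassifierResult", posteriors = posteriors,
      biasField = ScalarVolume(array(1, dims),
                               spacing = voxelSpacing(posteriors),
                               affine = voxelAffine(posteriors)),
      mixture = list(), logLik = numeric(0), mask = maskLab)
}

#' Hard labels from probability maps
#'
#' Per-voxel argmax over the classes; voxels with zero total probability
#' (outside the mask) get 0. Exact ties are broken toward the lowest class
#' code.
#'
#' @param posteriors [ProbabilityMaps-class] with classes ordered by
#'   ascending tissue code.
#' @param table code table (named character, code -> class name); defaults
#'   to [tissueClassTable()] matched against the posterior class names.
#' @return a [LabelVolume-class].
#' @export
hardLabels <- function(posteriors, table = NULL) {
  stopifnot(is(posteriors, "ProbabilityMaps"))
  arr <- voxelData(posteriors)
  d <- dim(arr)
  M <- matrix(as.numeric(arr), ncol = d[4L])
  cls <- classNames(posteriors)
  if (is.null(table)) {
    full <- tissueClassTable()
    codes <- suppressWarnings(as.integer(names(full)[match(cls, full)]))
    if (anyNA(codes)) codes <- seq_along(cls)
    table <- stats::setNames(cls, codes)
  } else {
    codes <- suppressWarnings(as.integer(names(table)[match(cls, table)]))
    if (anyNA(codes)) stop("posterior classes missing from code table")
  }
  ## order columns by ascending code so ties.method = "first" breaks ties
  ## toward the lowest class code
  ord <- order(codes)
  win <- max.col(M[, ord, drop = FALSE], ties.method = "first")
  lab <- codes[ord][win]
  lab[rowSums(M) <= 0] <- 0L
  LabelVolume(array(as.integer(lab), d[1:3]),
              spacing = voxelSpacing(posteriors), codeTable = table,
              affine = voxelAffine(posteriors))
}
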