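## Independent brute-force oracles. These deliberately avoid the package's
## C++ paths and internal helpers: shifts, queues and distances are
## implemented from scratch so agreement with the fast implementations is
## meaningful.

## shift a 3D array by (dx, dy, dz), padding with `fill`
oshift <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  ix <- list()
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    ix[[k]] <- if (o >= 0) list(dst = (1 + o):d[k], src = 1:(d[k] - o))
               else list(dst = 1:(d[k] + o), src = (1 - o):d[k])
  }
  out[ix[[1]]$dst, ix[[2]]$dst, ix[[3]]$dst] <-
    a[ix[[1]]$src, ix[[2]]$src, ix[[3]]$src]
  out
}

## grayscale reconstruction by dilation: iterate unit-dilate + voxelwise
## minimum with the mask until stable
oracleReconstruct <- function(marker, mask, offsets) {
  cur <- pmin(marker, mask)
  repeat {
    dil <- cur
    for (r in seq_len(nrow(offsets)))
      dil <- pmax(dil, oshift(cur, offsets[r, ], -Inf))
    nxt <- pmin(dil, mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

## priority flood from markers with the documented deterministic ordering:
## min (priority, insertion counter); seeds pushed in label order then
## linear-index order; neighbors enumerated in offset-row order
oracleWatershed <- function(control, seeds, offsets) {
  d <- dim(control)
  n <- prod(d)
  lab <- integer(n)
  qPrio <- numeric(0); qCnt <- numeric(0); qIdx <- integer(0); qLab <- integer(0)
  cnt <- 0
  push <- function(prio, idx, l) {
    qPrio[length(qPrio) + 1L] <<- prio
    qCnt[length(qCnt) + 1L] <<- cnt; cnt <<- cnt + 1
    qIdx[length(qIdx) + 1L] <<- idx
    qLab[length(qLab) + 1L] <<- l
  }
  for (l in sort(unique(seeds[seeds > 0])))
    for (i in which(seeds == l)) push(control[i], i, l)
  stopifnot(cnt > 0)
  nbOf <- function(i) {
    co <- arrayInd(i, d)
    out <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      p <- co + offsets[r, ]
      if (all(p >= 1) && all(p <= d))
        out <- c(out, p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1)))
    }
    out
  }
  while (length(qPrio)) {
    best <- which(qPrio == min(qPrio))
    best <- best[which.min(qCnt[best])]
    i <- qIdx[best]; l <- qLab[best]
    keep <- -best
    qPrio <- qPrio[keep]; qCnt <- qCnt[keep]; qIdx <- qIdx[keep]; qLab <- qLab[keep]
    if (lab[i] != 0L) next
    lab[i] <- l
    for (q in nbOf(i)) if (lab[q] == 0L) push(control[q], q, l)
  }
  array(lab, d)
}

## connected components by repeated flood fill
oracleComponents <- function(mask, offsets) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    front <- i
    lab[i] <- nxt
    while (length(front)) {
      newFront <- integer(0)
      for (p in front) {
        co <- arrayInd(p, d)
        for (r in seq_len(nrow(offsets))) {
          q <- co + offsets[r, ]
          if (all(q >= 1) && all(q <= d)) {
            qi <- q[1] + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1))
            if (mask[qi] && lab[qi] == 0L) { lab[qi] <- nxt; newFront <- c(newFront, qi) }
          }
        }
      }
      front <- newFront
    }
  }
  lab
}

## exhaustive all-pairs boundary distances
oracleSurfaceDistances <- function(a, b, spacing) {
  ## boundary: foreground voxel with some face neighbor background/outside
  bvox <- function(m) {
    d <- dim(m)
    res <- array(FALSE, d)
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
      res <- res | (m & !oshift(m, off, FALSE))
    which(res)
  }
  ca <- arrayInd(bvox(a), dim(a)); cb <- arrayInd(bvox(b), dim(b))
  ca <- sweep(ca, 2, spacing, `*`); cb <- sweep(cb, 2, spacing, `*`)
  D <- sqrt(outer(ca[, 1], cb[, 1], `-`)^2 + outer(ca[, 2], cb[, 2], `-`)^2 +
            outer(ca[, 3], cb[, 3], `-`)^2)
  ab <- apply(D, 1, min); ba <- apply(D, 2, min)
  c(msd = (mean(ab) + mean(ba)) / 2, hausdorff = max(max(ab), max(ba)))
}

## exhaustive confusion tally
oracleConfusion <- function(ca, re, codes) {
  out <- matrix(0, length(codes), length(codes) + 1L)
  for (i in seq_along(codes)) {
    sel <- which(ca == codes[i])
    if (!length(sel)) next
    for (j in seq_along(codes)) out[i, j] <- sum(re[sel] == codes[j])
    out[i, length(codes) + 1L] <- sum(!re[sel] %in% codes)
    out[i, ] <- 100 * out[i, ] / length(sel)
  }
  out
}

## random test volume with plateaus (integer-valued, so ties are common and
## the deterministic tie rules are genuinely exercised)
randControl <- function(dims, maxVal = 5L) {
  array(sample.int(maxVal + 1L, prod(dims), replace = TRUE) - 1L, dims) * 1.0
}

randDims <- function(lo = 4L, hi = 12L) sample(lo:hi, 3L, replace = TRUE)
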