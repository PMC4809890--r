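## Internal helpers shared across modules.

#' @importFrom stats dnorm quantile rnorm runif median sd
#' @importFrom utils head tail
NULL

## log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows.
.logRowSumExp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Neighborhood offsets for a given 3D connectivity, in the canonical
## order shared by the C++ operators and the pure-R oracles: sorted
## lexicographically by (dz, dy, dx). Returns an integer matrix with
## columns dx, dy, dz.
#' Neighborhood offsets for a 3D connectivity
#'
#' The three supported neighborhoods are face (6 neighbors), face-edge (18)
#' and full (26). The row order is canonical (sorted by dz, then dy, then
#' dx) and is relied upon by the deterministic tie-breaking of
#' [watershedFromMarkers()].
#'
#' @param connectivity integer; one of 6, 18, 26.
#' @return integer matrix with one row per neighbor and columns dx, dy, dz.
#' @export
connectivityOffsets <- function(connectivity = 6L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1L,
    "18" = ord <= 2L,
    "26" = rep(TRUE, nrow(g)))
  g <- g[keep, , drop = FALSE]
  g <- g[order(g$dz, g$dy, g$dx), , drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(m) <- "integer"
  m
}

## Shift a 3D array by an (dx, dy, dz) offset, padding with `fill`.
.shiftArray <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- seq_len(d[k] - o) + o; src[[k]] <- seq_len(d[k] - o) }
    else        { dst[[k]] <- seq_len(d[k] + o);     src[[k]] <- seq_len(d[k] + o) - o }
    if (d[k] + -abs(o) <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Fold hippocampus (7) and amygdala (8) into cortical GM (1); used by the
## NeoBrainS12-style merged evaluation.
.mergeHippoAmygdala <- function(lab) {
  lab[lab %in% c(7L, 8L)] <- 1L
  lab
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
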