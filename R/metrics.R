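#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Evaluation protocol: per-class overlap (Dice, sensitivity, specificity),
## surface distances (mean and Hausdorff, mm), and a row-normalized
## confusion matrix between a candidate and a reference segmentation.
## ---------------------------------------------------------------------------

.binData <- function(x) {
  if (is(x, "LabelVolume") || is(x, "ScalarVolume")) voxelData(x) != 0
  else .as3d(x) != 0
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty (perfect agreement on absence).
#'
#' @param a,b binary masks on the same grid.
#' @return Dice score in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  da <- .binData(a); db <- .binData(b)
  if (!identical(dim(da), dim(db))) stop("grid mismatch between masks")
  sa <- sum(da); sb <- sum(db)
  if (sa + sb == 0) return(1)
  2 * sum(da & db) / (sa + sb)
}

## boundary voxels: foreground with at least one face-neighbor that is
## background or outside the grid
.boundaryMask <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  offs <- connectivityOffsets(6L)
  inner <- m
  for (r in seq_len(nrow(offs))) {
    nb <- .shiftArray(m, offs[r, ], FALSE)   # out-of-grid counts as background
    out <- out | (m & !nb)
  }
  out
}

.boundaryCoordsMm <- function(m, spacing) {
  idx <- which(.boundaryMask(m))
  co <- arrayInd(idx, dim(m))
  sweep(co, 2L, spacing, `*`)
}

#' Symmetric mean and Hausdorff surface distances
#'
#' Boundary voxels are foreground voxels with at least one face-neighbor
#' outside the mask; distances are Euclidean in mm between the voxel-center
#' boundary point sets. The mean surface distance is the average of the two
#' directed means; the Hausdorff distance is the maximum of the two
#' directed maxima.
#'
#' @param a,b non-empty binary masks on the same grid.
#' @param spacing mm per axis for plain-array input.
#' @return named numeric: `msd`, `hausdorff` (mm).
#' @export
surfaceDistances <- function(a, b, spacing = NULL) {
  da <- .binData(a); db <- .binData(b)
  if (!identical(dim(da), dim(db))) stop("grid mismatch between masks")
  if (!any(da) || !any(db))
    stop("undefined surface distance: empty mask")
  sp <- .spacingOf(a, spacing)
  A <- .boundaryCoordsMm(da, sp); B <- .boundaryCoordsMm(db, sp)
  ab <- cpp_directed_min_dists(A, B)
  ba <- cpp_directed_min_dists(B, A)
  c(msd = (mean(ab) + mean(ba)) / 2, hausdorff = max(max(ab), max(ba)))
}

#' Sensitivity and specificity within an evaluation domain
#'
#' True/false positive/negative counts are restricted to the evaluation
#' domain (defaults to the brain mask rather than the full field of view).
#'
#' @param candidate,reference binary masks.
#' @param domain binary evaluation domain (non-empty).
#' @return named numeric: `sensitivity`, `specificity`; sensitivity is NaN
#'   with a warning when the reference is empty within the domain.
#' @export
sensitivitySpecificity <- function(candidate, reference, domain) {
  ca <- .binData(candidate); re <- .binData(reference); do <- .binData(domain)
  if (!identical(dim(ca), dim(re)) || !identical(dim(ca), dim(do)))
    stop("grid mismatch")
  if (!any(do)) stop("empty evaluation domain")
  ca <- ca[do]; re <- re[do]
  tp <- sum(ca & re); fn <- sum(!ca & re)
  tn <- sum(!ca & !re); fp <- sum(ca & !re)
  sens <- if (tp + fn == 0) {
    warning("reference empty within domain; sensitivity undefined (NaN)")
    NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) NaN else tn / (tn + fp)
  c(sensitivity = sens, specificity = spec)
}

#' Row-normalized confusion matrix between label volumes
#'
#' Entry (i, j) is the percentage of candidate-class-i voxels whose
#' reference label is j; the reference background (0) is included as the
#' last column, so every non-empty row sums to 100.
#'
#' @param candidate,reference [LabelVolume-class] (or integer arrays) on
#'   the same grid.
#' @param table code table; defaults to [tissueClassTable()].
#' @return numeric matrix, rows = candidate classes, columns = reference
#'   classes plus `background`.
#' @export
confusionMatrix <- function(candidate, reference, table = tissueClassTable()) {
  ca <- .as3d(candidate); re <- .as3d(reference)
  if (!identical(dim(ca), dim(re))) stop("grid mismatch")
  codes <- as.integer(names(table))
  out <- matrix(0, length(codes), length(codes) + 1L,
                dimnames = list(unname(table), c(unname(table), "background")))
  for (i in seq_along(codes)) {
    sel <- ca == codes[i]
    n <- sum(sel)
    if (n == 0) next
    ref <- re[sel]
    cnt <- c(vapply(codes, function(cj) sum(ref == cj), numeric(1)),
             sum(!ref %in% codes))
    out[i, ] <- 100 * cnt / n
  }
  out
}

#' MetricsReport: full per-class evaluation
#'
#' @slot perClass data.frame with one row per class: dice, sensitivity,
#'   specificity, msd (mm), hausdorff (mm), candidate and reference voxel
#'   counts.
#' @slot confusion row-normalized confusion matrix (percent).
#' @slot merged logical; TRUE when hippocampus/amygdala were folded into
#'   cortical gray matter.
#' @export
setClass("MetricsReport",
  representation(perClass = "data.frame", confusion = "matrix",
                 merged = "logical"))

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport", if (object@merged) "(hippocampus/amygdala merged)", "\n")
  df <- object@perClass
  df[, -1] <- round(df[, -1, drop = FALSE], 3)
  print(df, row.names = FALSE)
})

#' Evaluate a candidate segmentation against a reference
#'
#' Computes Dice, sensitivity, specificity (within `domain`), mean surface
#' distance and Hausdorff distance per tissue class, plus the
#' row-normalized confusion matrix. With `mergeNeoBrainS = TRUE` the
#' hippocampus and amygdala are folded into cortical gray matter before
#' evaluation (the convention used for NeoBrainS12-style comparison).
#'
#' @param candidate,reference [LabelVolume-class] on the same grid.
#' @param domain binary evaluation domain for sensitivity/specificity;
#'   defaults to `reference != 0 | candidate != 0` (the union brain mask).
#' @param table code table; defaults to [tissueClassTable()].
#' @param mergeNeoBrainS fold hippocampus/amygdala into cortical GM.
#' @return a [MetricsReport-class].
#' @export
evaluateSegmentation <- function(candidate, reference, domain = NULL,
                                 table = tissueClassTable(),
                                 mergeNeoBrainS = FALSE) {
  ca <- .as3d(candidate); re <- .as3d(reference)
  if (!identical(dim(ca), dim(re))) stop("grid mismatch")
  sp <- .spacingOf(candidate, NULL)
  if (mergeNeoBrainS) {
    ca <- .mergeHippoAmygdala(ca); re <- .mergeHippoAmygdala(re)
    table <- table[!table %in% c("hippocampus", "amygdala")]
  }
  if (is.null(domain)) domain <- ca != 0 | re != 0
  do <- .binData(domain)

  codes <- as.integer(names(table))
  rows <- lapply(seq_along(codes), function(i) {
    cm <- ca == codes[i]; rm <- re == codes[i]
    dice <- diceCoefficient(cm, rm)
    ss <- suppressWarnings(sensitivitySpecificity(cm, rm, do))
    sd <- if (any(cm) && any(rm)) surfaceDistances(cm, rm, spacing = sp)
          else c(msd = NA_real_, hausdorff = NA_real_)
    data.frame(class = unname(table[i]), dice = dice,
               sensitivity = unname(ss["sensitivity"]),
               specificity = unname(ss["specificity"]),
               msd = unname(sd["msd"]), hausdorff = unname(sd["hausdorff"]),
               nCandidate = sum(cm), nReference = sum(rm))
  })
  perClass <- do.call(rbind, rows)
  conf <- confusionMatrix(ca, re, table)
  new("MetricsReport", perClass = perClass, confusion = conf,
      merged = mergeNeoBrainS)
}

#' Write a MetricsReport to JSON and CSV
#'
#' @param report a [MetricsReport-class].
#' @param prefix output path prefix; writes `<prefix>.json`,
#'   `<prefix>_per_class.csv` and `<prefix>_confusion.csv`.
#' @return invisibly, the paths written.
#' @export
writeMetricsReport <- function(report, prefix) {
  jsonPath <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(perClass = report@perClass,
         confusion = as.data.frame(report@confusion),
         merged = report@merged),
    jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  csv1 <- paste0(prefix, "_per_class.csv")
  utils::write.csv(report@perClass, csv1, row.names = FALSE)
  csv2 <- paste0(prefix, "_confusion.csv")
  utils::write.csv(report@confusion, csv2)
  invisible(c(jsonPath, csv1, csv2))
}
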