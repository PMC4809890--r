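#' @include AllClasses.R
NULL

#' The canonical eight-class tissue code table
#'
#' Codes are stable across all pipeline stages and serialized outputs:
#' 0 background, 1 cortical gray matter, 2 white matter, 3 deep nuclear gray
#' matter, 4 CSF, 5 brainstem, 6 cerebellum, 7 hippocampus, 8 amygdala.
#'
#' @return named character vector mapping code (name, as string) to class
#'   name; background (0) is not included since label 0 means "no class".
#' @export
tissueClassTable <- function() {
  c("1" = "cortical_gm",
    "2" = "white_matter",
    "3" = "deep_gm",
    "4" = "csf",
    "5" = "brainstem",
    "6" = "cerebellum",
    "7" = "hippocampus",
    "8" = "amygdala")
}

#' Numeric code of a tissue class
#'
#' @param name class name as in [tissueClassTable()].
#' @return integer code.
#' @export
tissueCode <- function(name) {
  tab <- tissueClassTable()
  i <- match(name, tab)
  if (anyNA(i)) stop("unknown tissue class: ", paste(name[is.na(i)], collapse = ", "))
  as.integer(names(tab)[i])
}

#' Marker codes used by the watershed phase
#'
#' @return named character vector: 1 csf_seed, 2 gm_seed, 3 background_seed.
#' @export
markerCodeTable <- function() {
  c("1" = "csf_seed", "2" = "gm_seed", "3" = "background_seed")
}
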