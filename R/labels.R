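#' The seven anterior-posterior parcel labels
#'
#' Fixed order along the anterior-posterior axis; label 1 is the most
#' anterior. The same codes are used for cortical parcels (per hemisphere)
#' and for the callosal parcels they project onto.
#'
#' @return Named integer vector of length 7.
#' @export
cc_parcels <- function() {
  c(frontopolar = 1L, anterior_prefrontal = 2L, posterior_prefrontal = 3L,
    precentral = 4L, postcentral = 5L, parietal = 6L, occipital = 7L)
}

parcel_names <- function() names(cc_parcels())

## resolve "postcentral" / 5 / "total" -> canonical surface name
resolve_surface <- function(surface) {
  if (is.numeric(surface)) {
    stopifnot(surface %in% 1:7)
    return(parcel_names()[surface])
  }
  surface <- as.character(surface)
  if (surface %in% c("total", "cc_total")) return("total")
  if (!surface %in% parcel_names())
    stop("unknown surface '", surface, "'")
  surface
}

## cohort-table column holding a callosal surface (vectorised)
ccps_column <- function(surface) {
  ifelse(surface == "total", "cc_total_mm2", sprintf("ccps_%s_mm2", surface))
}

cxps_column <- function(surface) sprintf("cxps_%s_cm2", surface)
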