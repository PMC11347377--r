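#' Depot volume in liters
#'
#' Counts the voxels carrying a depot code and converts to liters using the
#' voxel geometry. An absent depot yields 0 L.
#'
#' @param mask a \code{\link{label_mask}}.
#' @param depot_code 1 (SAT) or 2 (VAT); the constants \code{SAT}/\code{VAT}.
#' @return Volume in liters.
#' @export
depot_volume <- function(mask, depot_code) {
  depot_code <- check_depot_code(depot_code)
  n <- sum(mask$labels == depot_code)
  n * voxel_volume_mm3(mask) / 1e6
}

check_depot_code <- function(depot_code) {
  if (length(depot_code) != 1L || !depot_code %in% c(1L, 2L))
    stop_arg("depot_code must be 1 (SAT) or 2 (VAT)")
  as.integer(depot_code)
}

#' Mean PDFF over a depot
#'
#' Arithmetic mean of the PDFF map restricted to the voxels of one depot.
#' An empty depot has no defined mean: \code{NA} is returned with a warning
#' (class \code{adipoquant_empty_depot}), distinguishable from a true 0\%.
#'
#' @param pdff a \code{\link{scalar_volume}} on the same lattice as
#'   \code{mask}.
#' @inheritParams depot_volume
#' @return Mean PDFF in percent, or \code{NA_real_} for an empty depot.
#' @export
mean_pdff <- function(pdff, mask, depot_code) {
  depot_code <- check_depot_code(depot_code)
  check_same_lattice(pdff, mask)
  sel <- mask$labels == depot_code
  if (!any(sel)) {
    warning(warningCondition(
      sprintf("depot code %d is empty; mean PDFF undefined", depot_code),
      class = "adipoquant_empty_depot"))
    return(NA_real_)
  }
  mean(pdff$values[sel])
}

#' Apparent lipid volume
#'
#' PDFF-weighted depot volume, sum over depot voxels of
#' (PDFF/100) x voxel volume, in liters. Approximates the lipid contained in
#' the depot while ignoring MR-invisible components, hence "apparent". Equals
#' \code{mean_pdff/100 * depot_volume} up to floating point.
#'
#' @inheritParams mean_pdff
#' @return Apparent lipid volume in liters (0 for an empty depot).
#' @export
apparent_lipid_volume <- function(pdff, mask, depot_code) {
  depot_code <- check_depot_code(depot_code)
  check_same_lattice(pdff, mask)
  sel <- mask$labels == depot_code
  sum(pdff$values[sel] / 100) * voxel_volume_mm3(mask) / 1e6
}

#' Length-normalized volume
#'
#' Divides a volume by a craniocaudal length, giving L/cm. Used with the
#' length of the full segmented region for total depot volumes, and with a
#' third's own length for third subvolumes, to correct for differing
#' physiques.
#'
#' @param volume_L volume in liters (vectorized).
#' @param length_cm strictly positive length in cm.
#' @return Normalized volume in L/cm.
#' @export
normalized_volume <- function(volume_L, length_cm) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0))
    stop_arg("length_cm must be strictly positive")
  volume_L / length_cm
}

#' VAT/SAT volume ratio
#'
#' @param sat,vat depot volumes in liters, or \code{depot_summary} objects
#'   from \code{\link{summarize_subject}}.
#' @return Dimensionless ratio VAT volume / SAT volume.
#' @export
vat_sat_ratio <- function(sat, vat) {
  v <- function(x) if (inherits(x, "depot_summary")) x$volume_L else
    as.numeric(x)
  sat_v <- v(sat); vat_v <- v(vat)
  if (!is.finite(sat_v) || sat_v <= 0)
    stop_arg("SAT volume must be strictly positive for the VAT/SAT ratio")
  vat_v / sat_v
}
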