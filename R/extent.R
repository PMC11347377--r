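#' Craniocaudal extent of the segmented region
#'
#' The extent spans the most superior to the most inferior slice containing
#' any depot voxel (SAT or VAT; one shared extent per subject, mirroring a
#' segmentation that runs from the liver dome to the middle of the femoral
#' heads). Length is the number of spanned slices times the slice spacing.
#'
#' @param mask a \code{\link{label_mask}} with at least one depot voxel.
#' @return A \code{region_extent}: \code{first_slice}, \code{last_slice}
#'   (inclusive array indices along the craniocaudal axis), \code{n_slices},
#'   \code{length_cm}, plus the axis metadata.
#' @export
region_extent <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  occ <- apply(mask$labels > 0L, mask$cc_axis, any)
  if (!any(occ)) stop_arg("mask contains no depot voxels; extent undefined")
  first <- which(occ)[1L]
  last <- max(which(occ))  # gaps inside the span are still spanned
  n <- last - first + 1L
  structure(list(first_slice = first, last_slice = last, n_slices = n,
                 length_cm = n * mask$spacing[mask$cc_axis] / 10,
                 cc_axis = mask$cc_axis,
                 superior_first = mask$superior_first),
            class = "region_extent")
}

#' @export
print.region_extent <- function(x, ...) {
  cat(sprintf("<region_extent> slices %d-%d (%d slices, %.1f cm)\n",
              x$first_slice, x$last_slice, x$n_slices, x$length_cm))
  invisible(x)
}

# Slice-center third assignment for n uniform slices: slice s (0-based from
# the superior end) has center (s + 0.5) * dz; boundaries sit at 1/3 and 2/3
# of the physical extent n * dz. Comparing 3*(s + 0.5) against n and 2n keeps
# the arithmetic exact in doubles (0.5 is exact), so no boundary wobble.
assign_thirds_superior <- function(n_slices) {
  s <- seq_len(n_slices) - 1L
  1L + (3 * (s + 0.5) >= n_slices) + (3 * (s + 0.5) >= 2 * n_slices)
}

#' Subdivide the segmented region into equidistant thirds
#'
#' Slices of the extent are assigned to the upper, middle or lower third by
#' the position of their physical center against boundaries at 1/3 and 2/3 of
#' the extent. Every extent slice lands in exactly one third, so the thirds'
#' depot volumes sum exactly to the totals. "Upper" is the superior end
#' (liver dome), "lower" the inferior end (femoral heads).
#'
#' @param mask a \code{\link{label_mask}}.
#' @param extent optional \code{\link{region_extent}} derived from
#'   \code{mask}; recomputed when missing.
#' @return Named list \code{upper}, \code{middle}, \code{lower} of
#'   \code{label_mask}s (voxels outside the third zeroed), each carrying
#'   attributes \code{slices} (array slice indices) and \code{length_cm}.
#' @export
partition_thirds <- function(mask, extent = region_extent(mask)) {
  stopifnot(inherits(mask, "label_mask"), inherits(extent, "region_extent"))
  if (extent$cc_axis != mask$cc_axis ||
      extent$superior_first != mask$superior_first)
    stop_arg("extent was not derived from this mask (axis metadata differs)")
  n <- extent$n_slices
  if (n < 3L) stop_arg("extent spans fewer than 3 slices; thirds undefined")
  slices <- extent$first_slice:extent$last_slice
  ord <- if (mask$superior_first) slices else rev(slices)
  third_of <- assign_thirds_superior(n)  # along ord, superior to inferior
  dz_cm <- mask$spacing[mask$cc_axis] / 10
  out <- lapply(1:3, function(t3) {
    keep <- ord[third_of == t3]
    lab <- mask$labels
    idx <- rep(list(quote(expr = )), 3L)
    idx[[mask$cc_axis]] <- setdiff(seq_len(dim(lab)[mask$cc_axis]), keep)
    lab <- do.call(`[<-`, c(list(lab), idx, list(value = 0L)))
    m <- label_mask(lab, mask$spacing, mask$cc_axis, mask$superior_first)
    attr(m, "slices") <- sort(keep)
    attr(m, "length_cm") <- length(keep) * dz_cm
    m
  })
  names(out) <- c("upper", "middle", "lower")
  out
}
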