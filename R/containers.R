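#' PDFF scalar volume
#'
#' Container for a 3D proton density fat fraction (PDFF) map in percent units,
#' together with its voxel geometry. The craniocaudal (head-foot) axis must be
#' identified so that regional subdivision knows which way is superior.
#'
#' @param values 3D numeric array of PDFF in percent; all values finite and in
#'   \[0, 100\].
#' @param spacing numeric length-3, voxel edge lengths in mm (strictly
#'   positive), one per array axis.
#' @param cc_axis integer in 1..3, the array axis running craniocaudally.
#' @param superior_first logical; \code{TRUE} if index 1 along \code{cc_axis}
#'   is the most superior (cranial) slice.
#' @return An object of class \code{scalar_volume}.
#' @export
scalar_volume <- function(values, spacing = c(3, 3, 6), cc_axis = 3L,
                          superior_first = TRUE) {
  values <- check_grid(values, "values")
  if (any(values < 0 | values > 100))
    stop_arg("PDFF values must lie in [0, 100] percent")
  geom <- check_geometry(spacing, cc_axis, superior_first)
  structure(c(list(values = values), geom), class = "scalar_volume")
}

#' SAT/VAT label mask
#'
#' Integer segmentation mask on the same lattice as its paired PDFF volume.
#' Codes: 0 background, 1 SAT (subcutaneous), 2 VAT (visceral). SAT and VAT
#' are disjoint by construction since each voxel carries a single code.
#'
#' @param labels 3D array of integer codes in \{0, 1, 2\}.
#' @inheritParams scalar_volume
#' @return An object of class \code{label_mask}.
#' @export
label_mask <- function(labels, spacing = c(3, 3, 6), cc_axis = 3L,
                       superior_first = TRUE) {
  labels <- check_grid(labels, "labels")
  codes <- unique(as.vector(labels))
  bad <- setdiff(codes, c(0, 1, 2))
  if (length(bad))
    stop_arg("label mask contains invalid codes: ",
             paste(bad, collapse = ", "), " (allowed: 0, 1, 2)")
  storage.mode(labels) <- "integer"
  geom <- check_geometry(spacing, cc_axis, superior_first)
  structure(c(list(labels = labels), geom), class = "label_mask")
}

#' @rdname label_mask
#' @format NULL
#' @export
SAT <- 1L

#' @rdname label_mask
#' @format NULL
#' @export
VAT <- 2L

check_grid <- function(x, what) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_arg(what, " must be a 3D array")
  if (!all(is.finite(x))) stop_arg(what, " must be all finite")
  x
}

check_geometry <- function(spacing, cc_axis, superior_first) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_arg("spacing must be 3 strictly positive voxel edge lengths in mm")
  cc_axis <- as.integer(cc_axis)
  if (length(cc_axis) != 1L || is.na(cc_axis) || !cc_axis %in% 1:3)
    stop_arg("cc_axis must identify exactly one array axis (1, 2 or 3)")
  stopifnot(is.logical(superior_first), length(superior_first) == 1L,
            !is.na(superior_first))
  list(spacing = spacing, cc_axis = cc_axis, superior_first = superior_first)
}

grid_of <- function(x) {
  if (inherits(x, "scalar_volume")) x$values
  else if (inherits(x, "label_mask")) x$labels
  else stop_arg("expected a scalar_volume or label_mask")
}

#' Voxel volume in mm^3
#' @param x a \code{scalar_volume} or \code{label_mask}.
#' @return scalar, product of the voxel spacings (mm^3).
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

# lattice compatibility of a PDFF map and its mask
check_same_lattice <- function(a, b) {
  if (!identical(dim(grid_of(a)), dim(grid_of(b))) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      a$cc_axis != b$cc_axis || a$superior_first != b$superior_first)
    stop_arg("PDFF volume and label mask must share the same lattice ",
             "(shape, spacing, axis roles)")
  invisible(TRUE)
}

#' Flip a volume or mask along the craniocaudal axis
#'
#' Reverses the slice order along the craniocaudal axis and toggles the
#' superior-direction flag, so the object describes the same physical scene.
#'
#' @param x a \code{scalar_volume} or \code{label_mask}.
#' @return An object of the same class.
#' @export
flip_cc <- function(x) {
  g <- grid_of(x)
  idx <- rep(list(quote(expr = )), 3L)
  idx[[x$cc_axis]] <- rev(seq_len(dim(g)[x$cc_axis]))
  g2 <- do.call(`[`, c(list(g), idx, list(drop = FALSE)))
  if (inherits(x, "scalar_volume"))
    scalar_volume(g2, x$spacing, x$cc_axis, !x$superior_first)
  else
    label_mask(g2, x$spacing, x$cc_axis, !x$superior_first)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> PDFF map", paste(dim(x$values), collapse = "x"),
      "voxels @", paste(x$spacing, collapse = "x"), "mm\n")
  cat("  craniocaudal axis:", x$cc_axis,
      if (x$superior_first) "(slice 1 superior)" else "(slice 1 inferior)",
      "\n  PDFF range:", sprintf("%.1f-%.1f %%", min(x$values), max(x$values)),
      "\n")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  n <- tabulate(x$labels + 1L, nbins = 3L)
  cat("<label_mask>", paste(dim(x$labels), collapse = "x"), "voxels @",
      paste(x$spacing, collapse = "x"), "mm\n")
  cat(sprintf("  background %d | SAT %d | VAT %d voxels\n", n[1], n[2], n[3]))
  invisible(x)
}
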