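default_label_codes <- function() c(background = 0L, sat = 1L, vat = 2L)

# craniocaudal axis from a NIfTI orientation string such as "LPI": the
# letter gives the world direction of the increasing array index, so an "I"
# on an axis means slice 1 is the most superior
cc_from_orientation <- function(orient, default_axis = 3L) {
  letters3 <- strsplit(orient, "")[[1]]
  cc <- which(letters3 %in% c("S", "I"))
  if (length(cc) != 1L) {
    warning("could not identify the craniocaudal axis from orientation '",
            orient, "'; assuming axis ", default_axis,
            " with slice 1 superior", call. = FALSE)
    return(list(cc_axis = default_axis, superior_first = TRUE))
  }
  list(cc_axis = cc, superior_first = letters3[cc] == "I")
}

#' Read a PDFF map from NIfTI
#'
#' Reads a 3D NIfTI volume, takes voxel spacing from the header and the
#' craniocaudal axis from the image orientation (falling back to
#' \code{default_axis}, with a warning, when the orientation does not
#' resolve it). Values outside \[0, 100\] are rejected unless they are tiny
#' negative reconstruction artifacts within \code{clamp} percent, which are
#' clipped.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param default_axis fallback craniocaudal axis.
#' @param clamp tolerance (percentage points) for clipping slightly
#'   out-of-range values (default 0.5).
#' @return A \code{\link{scalar_volume}}.
#' @export
read_pdff_nifti <- function(path, default_axis = 3L, clamp = 0.5) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop_arg("'", path, "' is not a 3D volume")
  geom <- cc_from_orientation(RNifti::orientation(img), default_axis)
  vals <- array(as.numeric(img), dim(img))
  if (min(vals) < -clamp || max(vals) > 100 + clamp)
    stop_arg("'", path, "' has values outside [0, 100] percent (range ",
             sprintf("%.2f to %.2f", min(vals), max(vals)),
             "); not a percent-scaled PDFF map?")
  vals <- pmin(pmax(vals, 0), 100)
  scalar_volume(vals, RNifti::pixdim(img), geom$cc_axis, geom$superior_first)
}

#' Read a SAT/VAT label mask from NIfTI
#'
#' @inheritParams read_pdff_nifti
#' @param label_codes named integer vector mapping the file's codes to the
#'   roles \code{background}, \code{sat}, \code{vat}; codes found in the
#'   file but absent from the map are an error naming the file.
#' @return A \code{\link{label_mask}} with canonical codes 0/1/2.
#' @export
read_mask_nifti <- function(path, label_codes = default_label_codes(),
                            default_axis = 3L) {
  stopifnot(all(c("background", "sat", "vat") %in% names(label_codes)))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop_arg("'", path, "' is not a 3D volume")
  geom <- cc_from_orientation(RNifti::orientation(img), default_axis)
  raw <- array(round(as.numeric(img)), dim(img))
  bad <- setdiff(unique(as.vector(raw)), label_codes)
  if (length(bad))
    stop_arg("'", path, "' contains label codes not in the configured map: ",
             paste(bad, collapse = ", "))
  lab <- array(0L, dim(raw))
  lab[raw == label_codes[["sat"]]] <- SAT
  lab[raw == label_codes[["vat"]]] <- VAT
  label_mask(lab, RNifti::pixdim(img), geom$cc_axis, geom$superior_first)
}

# RAS-world affine matching the container's axis roles
affine_for <- function(spacing, cc_axis, superior_first) {
  aff <- diag(4)
  others <- setdiff(1:3, cc_axis)
  aff[1:3, 1:3] <- 0
  aff[1, others[1]] <- -spacing[others[1]]  # points left
  aff[2, others[2]] <- -spacing[others[2]]  # points posterior
  aff[3, cc_axis] <- if (superior_first) -spacing[cc_axis]
                     else spacing[cc_axis]
  aff
}

#' Write a volume or mask to NIfTI
#'
#' Writes the array with voxel spacing and an xform encoding the
#' craniocaudal axis role, so \code{\link{read_pdff_nifti}} /
#' \code{\link{read_mask_nifti}} round-trip the geometry.
#'
#' @param x a \code{\link{scalar_volume}} or \code{\link{label_mask}}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  g <- grid_of(x)
  img <- RNifti::asNifti(if (is.integer(g)) g + 0L else g)
  RNifti::pixdim(img) <- x$spacing
  aff <- affine_for(x$spacing, x$cc_axis, x$superior_first)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cohort or metrics table to CSV without precision loss
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' written table, re-read with \code{\link{read_metrics_csv}}, reproduces
#' the in-memory doubles exactly.
#'
#' @param table data frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  out <- table
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                          sprintf("%.17g", out[[nm]]))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a subject summary as a CSV row and JSON
#'
#' @param summary a \code{subject_summary} from
#'   \code{\link{summarize_subject}}.
#' @param csv_path,json_path output paths; either may be \code{NULL} to
#'   skip.
#' @param subject_id optional identifier column for the CSV row.
#' @return The one-row data frame, invisibly.
#' @export
write_subject_metrics <- function(summary, csv_path = NULL, json_path = NULL,
                                  subject_id = NULL) {
  row <- as.data.frame(summary)
  if (!is.null(subject_id)) row <- cbind(subject_id = subject_id, row)
  if (!is.null(csv_path)) write_metrics_csv(row, csv_path)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(row), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(row)
}

#' Validate a run configuration
#'
#' Checks a configuration list (typically parsed from YAML or JSON) for the
#' pipeline entry points: referenced paths must exist, stepwise thresholds
#' must lie in (0, 1) with \code{p_enter <= p_remove}, and the label-code
#' map must be complete.
#'
#' @param config named list; recognized fields: \code{paths} (named list of
#'   existing files/dirs), \code{label_codes}, \code{p_enter},
#'   \code{p_remove}, \code{correlation_method}, \code{seed},
#'   \code{default_axis}.
#' @return The config with defaults filled in; errors describe each
#'   violation.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  config$p_enter <- config$p_enter %||% 0.05
  config$p_remove <- config$p_remove %||% 0.10
  config$correlation_method <- config$correlation_method %||% "pearson"
  config$default_axis <- config$default_axis %||% 3L
  config$label_codes <- unlist(config$label_codes) %||%
    default_label_codes()
  problems <- character(0)
  for (th in c("p_enter", "p_remove"))
    if (!is.numeric(config[[th]]) || config[[th]] <= 0 || config[[th]] >= 1)
      problems <- c(problems, paste0(th, " must lie in (0, 1)"))
  if (is.numeric(config$p_enter) && is.numeric(config$p_remove) &&
      config$p_enter > config$p_remove)
    problems <- c(problems, "p_enter must not exceed p_remove")
  if (!config$correlation_method %in% c("pearson", "spearman"))
    problems <- c(problems, "correlation_method must be pearson or spearman")
  if (!all(c("background", "sat", "vat") %in% names(config$label_codes)))
    problems <- c(problems,
                  "label_codes must name background, sat and vat")
  for (p in unlist(config$paths))
    if (!file.exists(p))
      problems <- c(problems, paste0("path does not exist: ", p))
  if (length(problems))
    stop_arg("invalid run configuration:\n  ",
             paste(problems, collapse = "\n  "))
  config
}
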