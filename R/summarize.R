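#' Per-subject depot summaries
#'
#' Runs the full volumetric pipeline on one subject: depot volumes, mean
#' PDFF, apparent lipid volumes, the shared craniocaudal extent, equidistant
#' thirds, and length-normalized volumes (totals normalized by the region
#' length, thirds by their own length). Deterministic for fixed inputs.
#'
#' An empty depot gets volume 0 with mean PDFF and normalized values set to
#' \code{NA} (undefined rather than zero), so downstream statistics can
#' exclude them.
#'
#' @param pdff a \code{\link{scalar_volume}}.
#' @param mask a \code{\link{label_mask}} on the same lattice.
#' @return A \code{subject_summary}: list with \code{sat} and \code{vat}
#'   \code{depot_summary} objects, the \code{extent}, and
#'   \code{vat_sat_ratio} (\code{NA} when SAT is empty).
#' @export
summarize_subject <- function(pdff, mask) {
  check_same_lattice(pdff, mask)
  extent <- region_extent(mask)
  thirds <- partition_thirds(mask, extent)
  sat <- depot_summary_for(pdff, mask, SAT, extent, thirds)
  vat <- depot_summary_for(pdff, mask, VAT, extent, thirds)
  ratio <- if (sat$volume_L > 0) vat_sat_ratio(sat, vat) else NA_real_
  structure(list(sat = sat, vat = vat, extent = extent,
                 vat_sat_ratio = ratio),
            class = "subject_summary")
}

depot_summary_for <- function(pdff, mask, code, extent, thirds) {
  vol <- depot_volume(mask, code)
  mp <- if (vol > 0) mean_pdff(pdff, mask, code) else NA_real_
  lip <- apparent_lipid_volume(pdff, mask, code)
  third_names <- c("upper", "middle", "lower")
  third_list <- lapply(third_names, function(nm) {
    tm <- thirds[[nm]]
    tvol <- depot_volume(tm, code)
    tlen <- attr(tm, "length_cm")
    tlip <- apparent_lipid_volume(pdff, tm, code)
    list(third = nm, volume_L = tvol, length_cm = tlen,
         normalized_L_per_cm = if (tvol > 0 || vol > 0)
           normalized_volume(tvol, tlen) else NA_real_,
         apparent_lipid_L = tlip)
  })
  names(third_list) <- third_names
  structure(list(
    depot = c("sat", "vat")[code],
    volume_L = vol,
    mean_pdff_pct = mp,
    apparent_lipid_L = lip,
    normalized_L_per_cm = if (vol > 0)
      normalized_volume(vol, extent$length_cm) else NA_real_,
    normalized_lipid_L_per_cm = if (vol > 0)
      normalized_volume(lip, extent$length_cm) else NA_real_,
    thirds = third_list), class = "depot_summary")
}

#' @export
print.depot_summary <- function(x, ...) {
  cat(sprintf("<depot_summary> %s: %.2f L, mean PDFF %.1f %%, lipid %.2f L\n",
              toupper(x$depot), x$volume_L, x$mean_pdff_pct,
              x$apparent_lipid_L))
  for (t3 in x$thirds)
    cat(sprintf("  %-6s %.2f L over %.1f cm (%.3f L/cm)\n", t3$third,
                t3$volume_L, t3$length_cm, t3$normalized_L_per_cm))
  invisible(x)
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("<subject_summary> region %.1f cm, VAT/SAT ratio %.2f\n",
              x$extent$length_cm, x$vat_sat_ratio))
  print(x$sat); print(x$vat)
  invisible(x)
}

#' Flatten a subject summary to one data frame row
#'
#' Columns follow the package column dictionary (see
#' \code{\link{adipoquant-package}}): \code{sat_tv}, \code{sat_lv},
#' \code{sat_pdff_pct}, \code{norm_sat}, \code{norm_sat_upper}, ...,
#' \code{vat_sat_ratio}, \code{region_length_cm}.
#'
#' @param x a \code{subject_summary}.
#' @param row.names,optional,... passed over from the generic; unused.
#' @return A one-row \code{data.frame}.
#' @export
as.data.frame.subject_summary <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  row <- list(region_length_cm = x$extent$length_cm)
  for (d in c("sat", "vat")) {
    s <- x[[d]]
    row[[paste0(d, "_tv")]] <- s$volume_L
    row[[paste0(d, "_lv")]] <- s$apparent_lipid_L
    row[[paste0(d, "_pdff_pct")]] <- s$mean_pdff_pct
    row[[paste0("norm_", d)]] <- s$normalized_L_per_cm
    row[[paste0("norm_", d, "_lv")]] <- s$normalized_lipid_L_per_cm
    for (t3 in s$thirds) {
      row[[paste0(d, "_", t3$third)]] <- t3$volume_L
      row[[paste0("norm_", d, "_", t3$third)]] <- t3$normalized_L_per_cm
    }
  }
  row$vat_sat_ratio <- x$vat_sat_ratio
  as.data.frame(row, row.names = row.names)
}
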