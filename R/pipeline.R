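#' Run the full parcellation pipeline
#'
#' Chains section extraction (or a ready-made section mask), streamline
#' selection, homotopic bundle assembly, density mapping, the regularized
#' vote, gap filling, parcel-area measurement and quality control.
#'
#' @param tractogram A [cc_tractogram()] in world mm.
#' @param cortex Seven-label cortical [cc_volume()] or [cc_mesh()].
#' @param plane A [plane_spec()].
#' @param wm_mask Binary white-matter [cc_volume()] (ignored when
#'   `section_mask` is given).
#' @param section_mask Optional precomputed one-voxel-thick CC section mask.
#' @param oversample Section oversampling factor (default 2).
#' @param radius Endpoint-to-parcel search radius in mm (default 3).
#' @param clean Keep only the largest connected section component (default
#'   `TRUE`).
#' @param vote_cfg A [vote_config()].
#' @param qc_band Warning band for parcel area fractions.
#' @return A list of class `cc_parcellation`: `section`, `selection`,
#'   `bundles`, `density`, `labelmap`, `areas`, `qc`.
#' @export
run_parcellation <- function(tractogram, cortex, plane,
                             wm_mask = NULL, section_mask = NULL,
                             oversample = 2L, radius = 3,
                             clean = TRUE, vote_cfg = vote_config(),
                             qc_band = c(0.10, 0.25)) {
  section <- if (!is.null(section_mask)) {
    section_from_mask(section_mask, plane)
  } else if (!is.null(wm_mask)) {
    extract_section(wm_mask, plane, oversample)
  } else {
    stop("give either wm_mask or section_mask")
  }
  if (clean) section <- clean_section(section)
  selection <- select_cc_streamlines(tractogram, section)
  bundles <- build_bundles(tractogram, selection, cortex, plane, radius)
  density <- density_maps(bundles, section)
  labelmap <- regularized_vote(density, section, vote_cfg)
  labelmap <- fill_gaps(labelmap, section)
  areas <- parcel_areas(labelmap, section)
  qc <- qc_report(labelmap, section, band = qc_band)
  structure(list(section = section, selection = selection, bundles = bundles,
                 density = density, labelmap = labelmap, areas = areas,
                 qc = qc),
            class = "cc_parcellation")
}

#' @export
print.cc_parcellation <- function(x, ...) {
  cat(sprintf("<cc_parcellation> %d voxels, cc_total = %.1f mm^2, %d warnings\n",
              section_size(x$section), x$areas$cc_total,
              length(x$qc$warnings)))
  invisible(x)
}

#' Assemble a cohort-table row from parcellation results
#'
#' @param subject_id Subject identifier.
#' @param group Group name.
#' @param sex 0/1 (or F/M).
#' @param age_years Age.
#' @param areas Callosal areas from [parcel_areas()].
#' @param cortical Cortical areas from [cortical_areas()] (or `NA`s when no
#'   mesh is available).
#' @return One-row data frame in the cohort schema.
#' @export
morphometry_row <- function(subject_id, group, sex, age_years, areas,
                            cortical = NULL) {
  row <- data.frame(subject_id = subject_id, group = group, sex = sex,
                    age_years = age_years,
                    tcxs_cm2 = if (is.null(cortical)) NA_real_
                               else cortical$tcxs)
  for (nm in parcel_names())
    row[[cxps_column(nm)]] <- if (is.null(cortical)) NA_real_
                              else unname(cortical$cxps[nm])
  for (nm in parcel_names())
    row[[ccps_column(nm)]] <- unname(areas$ccps[nm])
  row$cc_total_mm2 <- areas$cc_total
  row
}
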