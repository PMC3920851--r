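# End-to-end chains: measure one scan (extract both surfaces, fit both
# spheres, compute the separation) and run a whole displacement study on
# synthetic phantoms.

#' Measure the implant in one CT volume
#'
#' Extracts the cup and head surfaces constrained by the seven landmarks,
#' robustly fits a sphere to each, and reports the cup-head separation.
#'
#' @param vol A [ct_volume()].
#' @param lm A `landmark_set`.
#' @param extraction An [extraction_config()].
#' @param fitting A [fit_config()].
#' @param scan_id Identifier used in result tables.
#' @return Object of class `implant_measurement`: `cup_fit`, `head_fit`
#'   (class `sphere_fit`), `separation` (mm) and `scan_id`.
#' @export
measure_implant <- function(vol, lm, extraction, fitting = fit_config(),
                            scan_id = "scan") {
  cup_pts <- extract_cup_surface(vol, lm, extraction)
  head_pts <- extract_head_surface(vol, lm, extraction)
  cup_fit <- fit_sphere(cup_pts, fitting)
  head_fit <- fit_sphere(head_pts, fitting)
  structure(list(scan_id = scan_id,
                 cup_fit = cup_fit,
                 head_fit = head_fit,
                 separation = cup_head_separation(cup_fit, head_fit)),
            class = "implant_measurement")
}

#' @export
print.implant_measurement <- function(x, ...) {
  cat(sprintf(paste0("<implant_measurement> scan %s\n",
                     "  cup diameter %.3f mm, head diameter %.3f mm\n",
                     "  cup-head separation %.4f mm\n"),
              x$scan_id, 2 * x$cup_fit$radius, 2 * x$head_fit$radius,
              x$separation))
  invisible(x)
}

# One row of the results table: scan identifier, initial radius and center,
# final radius and center for one fitted sphere, all in mm.
fit_result_row <- function(scan_id, fit, surface) {
  tibble(scan_id = scan_id, surface = surface,
         initial_radius = fit$initial_radius,
         initial_x = fit$initial_center[1],
         initial_y = fit$initial_center[2],
         initial_z = fit$initial_center[3],
         final_radius = fit$radius,
         final_x = fit$center[1],
         final_y = fit$center[2],
         final_z = fit$center[3])
}

#' Results table of an implant measurement
#'
#' @param m An `implant_measurement`.
#' @return Tibble with one row per fitted surface (cup, head) holding the
#'   scan identifier, initial radius and center, and final radius and
#'   center, all in mm.
#' @export
measurement_results <- function(m) {
  dplyr::bind_rows(fit_result_row(m$scan_id, m$cup_fit, "cup"),
                   fit_result_row(m$scan_id, m$head_fit, "head"))
}

#' Run a synthetic displacement study
#'
#' Generates one phantom per displacement (the first is the reference),
#' places the seven landmarks automatically from ground truth, measures each
#' scan, and tabulates measured against expected separation. Volumes are
#' generated and discarded one at a time, so memory stays flat.
#'
#' @param displacements Displacement triples (list, matrix, or a data frame
#'   with `dx`, `dy`, `dz` such as [table1_displacements()]).
#' @param spec Base [phantom_spec()].
#' @param extraction An [extraction_config()]; default threshold is midway
#'   between background and metal intensity.
#' @param fitting A [fit_config()].
#' @param scan_ids Optional scan identifiers (defaults to `scan_one` letters
#'   when `displacements` is the design tibble, else `scan01`...).
#' @param landmark_fn Function `(truth, spec) -> landmark_set`, by default
#'   [auto_landmarks()]; swap in a perturbing wrapper to emulate operator
#'   variability.
#' @param keep_fits Keep the per-scan `sphere_fit` objects (memory
#'   permitting).
#' @return Object of class `wear_study`: `wear` (a `wear_records` tibble),
#'   `diameters` (per scan and surface), `results` (the per-sphere results
#'   table) and optionally `fits`.
#' @export
run_phantom_study <- function(displacements = table1_displacements(),
                              spec = phantom_spec(),
                              extraction = NULL,
                              fitting = fit_config(),
                              scan_ids = NULL,
                              landmark_fn = auto_landmarks,
                              keep_fits = FALSE) {
  if (is.data.frame(displacements) && is.null(scan_ids) &&
      "scan_one" %in% names(displacements)) {
    scan_ids <- displacements$scan_one
  }
  dl <- as_displacement_list(displacements)
  if (is.null(scan_ids)) scan_ids <- sprintf("scan%02d", seq_along(dl))
  if (is.null(extraction)) {
    extraction <- extraction_config(
      threshold = (spec$metal_intensity + spec$background_intensity) / 2)
  }
  results <- list(); wear <- list(); fits <- list()
  for (i in seq_along(dl)) {
    ph <- generate_phantom(series_spec(spec, dl[[i]], i))
    lm <- landmark_fn(ph$truth, spec)
    m <- measure_implant(ph$volume, lm, extraction, fitting,
                         scan_id = scan_ids[i])
    rm(ph)
    results[[i]] <- measurement_results(m)
    wear[[i]] <- tibble(
      scan_id = scan_ids[i],
      measured = m$separation,
      dx = dl[[i]][1], dy = dl[[i]][2], dz = dl[[i]][3])
    if (keep_fits) fits[[i]] <- m
  }
  wear <- dplyr::bind_rows(wear)
  rec <- wear_records(wear$scan_id, wear$measured,
                      expected_separation(wear$dx, wear$dy, wear$dz))
  results <- dplyr::bind_rows(results)
  diameters <- dplyr::mutate(
    dplyr::select(results, "scan_id", "surface", "final_radius"),
    diameter = 2 * .data$final_radius)
  structure(list(wear = rec, diameters = diameters, results = results,
                 fits = if (keep_fits) fits else NULL,
                 spec = spec),
            class = "wear_study")
}

#' @export
print.wear_study <- function(x, ...) {
  cat(sprintf("<wear_study> %d scans\n", nrow(x$wear)))
  cat(sprintf("  max |measured - expected| separation: %.4f mm\n",
              max(abs(x$wear$difference))))
  for (s in unique(x$diameters$surface)) {
    d <- x$diameters$diameter[x$diameters$surface == s]
    cat(sprintf("  %s diameter: mean %.3f mm, SD %.4f mm\n", s,
                mean(d), sd(d)))
  }
  invisible(x)
}
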