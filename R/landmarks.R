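# The seven-landmark protocol: three cup-rim points defining the rim plane,
# one apical point in the dome hole, one offset point outward along the cup
# axis, and two spherical landmarks (head-stem junction, head-enclosing).
# Landmarks live in a tibble with columns name, x_mm, y_mm, z_mm, radius_mm
# (radius empty for point landmarks), the same columns as the CSV format.

landmark_names <- c("rim1", "rim2", "rim3", "apex", "cup_offset",
                    "stem_junction", "head_enclosing")
spherical_landmarks <- c("stem_junction", "head_enclosing")

#' Validate a landmark table
#'
#' Checks the seven-landmark protocol: all seven named landmarks present
#' exactly once, finite coordinates, radii present on the two spherical
#' landmarks, and noncolinear rim points. Rows are returned in protocol
#' order.
#'
#' @param lm A data frame with columns `name`, `x_mm`, `y_mm`, `z_mm`,
#'   `radius_mm`.
#' @return A validated `landmark_set` tibble.
#' @export
as_landmark_set <- function(lm) {
  lm <- as_tibble(lm)
  needed <- c("name", "x_mm", "y_mm", "z_mm", "radius_mm")
  if (!all(needed %in% names(lm))) {
    stop_hipwear(sprintf("landmark table must have columns %s",
                         paste(needed, collapse = ", ")),
                 "hipwear_validation_error")
  }
  missing <- setdiff(landmark_names, lm$name)
  extra <- setdiff(lm$name, landmark_names)
  if (length(missing) || length(extra) || nrow(lm) != 7L) {
    stop_hipwear(
      sprintf("expected exactly the 7 landmarks %s%s%s",
              paste(landmark_names, collapse = ", "),
              if (length(missing)) paste0("; missing: ",
                                          paste(missing, collapse = ", ")) else "",
              if (length(extra)) paste0("; unexpected: ",
                                        paste(extra, collapse = ", ")) else ""),
      "hipwear_validation_error")
  }
  lm <- lm[match(landmark_names, lm$name), ]
  coords <- as.matrix(lm[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(coords))) {
    stop_hipwear("landmark coordinates must be finite", "hipwear_validation_error")
  }
  rad <- lm$radius_mm[match(spherical_landmarks, lm$name)]
  if (any(!is.finite(rad) | rad <= 0)) {
    stop_hipwear("stem_junction and head_enclosing need a positive radius_mm",
                 "hipwear_validation_error")
  }
  # rim noncolinearity via fit_plane's own degeneracy check
  tryCatch(fit_plane(coords[1, ], coords[2, ], coords[3, ]),
           hipwear_degenerate_geometry = function(e) {
             stop_hipwear("rim landmarks rim1, rim2, rim3 are colinear",
                          "hipwear_validation_error")
           })
  class(lm) <- c("landmark_set", class(lm))
  lm
}

lm_point <- function(lm, name) {
  i <- match(name, lm$name)
  c(lm$x_mm[i], lm$y_mm[i], lm$z_mm[i])
}

lm_sphere <- function(lm, name) {
  i <- match(name, lm$name)
  sphere_model(c(lm$x_mm[i], lm$y_mm[i], lm$z_mm[i]), lm$radius_mm[i])
}

#' Read landmarks from CSV
#'
#' Expects columns `name`, `x_mm`, `y_mm`, `z_mm`, `radius_mm` (radius empty
#' for point landmarks) and exactly the seven protocol landmarks.
#'
#' @param path CSV path.
#' @return A validated `landmark_set` tibble.
#' @export
read_landmarks <- function(path) {
  lm <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          name = readr::col_character(),
                          .default = readr::col_double()))
  as_landmark_set(lm)
}

#' Write landmarks to CSV
#'
#' @param lm A `landmark_set` (or valid landmark data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  lm <- as_landmark_set(lm)
  readr::write_csv(lm, path)
  invisible(path)
}

#' Randomly perturb landmark positions
#'
#' Robustness harness: jitters every landmark coordinate uniformly within
#' `amount` mm (radii are left untouched). Deterministic given `seed`.
#'
#' @param lm A `landmark_set`.
#' @param amount Maximum absolute perturbation per coordinate, mm.
#' @param seed Integer seed.
#' @return A perturbed, revalidated `landmark_set`.
#' @export
perturb_landmarks <- function(lm, amount = 1, seed = 1L) {
  lm <- as_landmark_set(lm)
  withr::with_seed(seed, {
    for (col in c("x_mm", "y_mm", "z_mm")) {
      lm[[col]] <- lm[[col]] + runif(nrow(lm), -amount, amount)
    }
  })
  as_landmark_set(lm)
}
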