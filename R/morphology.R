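#' Cell biovolume from shape and dimensions
#'
#' Two shape models cover the organisms considered here: rod-shaped
#' nitrite-oxidizing bacteria are modeled as capsules (a cylinder capped by
#' two half-spheres) and ammonia-oxidizing archaea as prolate spheroids.
#'
#' Capsule: `V = pi (w/2)^2 (l - w) + (4/3) pi (w/2)^3`;
#' prolate spheroid: `V = (pi/6) l w^2`. With `l = w` both reduce to a sphere.
#'
#' @param length_um Cell length, µm (the long axis, including caps).
#' @param width_um Cell width, µm. Must satisfy `length_um >= width_um > 0`.
#' @param shape `"capsule"` or `"prolate_spheroid"`.
#' @return Biovolume, µm³.
#' @examples
#' biovolume(1, 1, "capsule")            # sphere: pi/6
#' biovolume(0.6, 0.4, "prolate_spheroid")  # 0.0503
#' @export
biovolume <- function(length_um, width_um,
                      shape = c("capsule", "prolate_spheroid")) {
  shape <- match.arg(shape)
  if (any(width_um <= 0)) stop("width must be positive")
  if (any(length_um < width_um)) stop("length must be >= width")
  switch(shape,
    capsule = pi * (width_um / 2)^2 * (length_um - width_um) +
      (4 / 3) * pi * (width_um / 2)^3,
    prolate_spheroid = (pi / 6) * length_um * width_um^2)
}

#' Biovolume from a projected ROI area
#'
#' nanoSIMS regions of interest are 2-D projections; given the projected area
#' and an assumed aspect ratio `l/w`, the cell dimensions are recovered by
#' inverting the shape's mid-plane projection and the 3-D volume follows from
#' [biovolume()].
#'
#' Projections: capsule -> rectangle `w (l - w)` plus a circle of diameter
#' `w`, i.e. `A = w(l-w) + pi w^2/4`; prolate spheroid -> ellipse
#' `A = (pi/4) l w`.
#'
#' @param roi_area_um2 Projected area, µm².
#' @param shape `"capsule"` or `"prolate_spheroid"`.
#' @param aspect_ratio Assumed length/width, >= 1.
#' @return Biovolume, µm³.
#' @examples
#' area_to_volume(pi / 4 * 0.6 * 0.4, "prolate_spheroid", 1.5)  # 0.0503
#' @export
area_to_volume <- function(roi_area_um2,
                           shape = c("capsule", "prolate_spheroid"),
                           aspect_ratio = 1.5) {
  shape <- match.arg(shape)
  if (any(roi_area_um2 <= 0)) stop("ROI area must be positive")
  if (any(aspect_ratio < 1)) stop("aspect ratio must be >= 1")
  if (shape == "prolate_spheroid") {
    # A = (pi/4) a w^2 with l = a w  =>  w = sqrt(4A / (pi a))
    w <- sqrt(4 * roi_area_um2 / (pi * aspect_ratio))
  } else {
    # A = w^2 (a - 1) + pi w^2 / 4  =>  w = sqrt(A / (a - 1 + pi/4))
    w <- sqrt(roi_area_um2 / (aspect_ratio - 1 + pi / 4))
  }
  biovolume(aspect_ratio * w, w, shape)
}

#' Allometric parameters for cellular carbon content
#'
#' Power-law biovolume-to-carbon allometry `C = a V^b` (C in fg, V in µm³).
#' The defaults (a = 196 fg, b = 0.486) are solved exactly from the two
#' (volume, carbon) anchor pairs used for the study populations:
#' (0.06 µm³, 50 fg) and (0.25 µm³, 100 fg).
#'
#' @param a Coefficient, fg-C at V = 1 µm³.
#' @param b Scaling exponent, in (0, 1].
#' @return An `allometry_params` object.
#' @export
allometry_params <- function(a = NULL, b = NULL) {
  if (is.null(b)) b <- log(100 / 50) / log(0.25 / 0.06)
  if (is.null(a)) a <- 50 / 0.06^b
  stopifnot(a > 0, b > 0, b <= 1)
  structure(list(a = a, b = b), class = "allometry_params")
}

#' Cellular carbon content from biovolume
#'
#' `C = a V^b` with allometric defaults calibrated so that V = 0.06 µm³ maps
#' to 50 fg-C and V = 0.25 µm³ to 100 fg-C.
#'
#' @param volume_um3 Biovolume, µm³.
#' @param params An [allometry_params()] object.
#' @return Carbon content, fg-C per cell.
#' @examples
#' carbon_content(0.25)  # 100 fg-C
#' @export
carbon_content <- function(volume_um3, params = allometry_params()) {
  if (any(volume_um3 <= 0)) stop("volume must be positive")
  params$a * volume_um3^params$b
}

#' Cellular nitrogen content from carbon content
#'
#' Redfield stoichiometry (C:N = 6.625:1) converts carbon to nitrogen quota:
#' `fgN = fgC / cn_ratio`, following the field convention of applying the
#' ratio directly to the femtogram amounts; fmol-N follows as fg-N / 14.
#'
#' @param carbon_fg Carbon content, fg-C per cell.
#' @param cn_ratio C:N ratio (default 6.625). An alternative measured value
#'   for cultured Nitrospina (5.9) may be supplied.
#' @return List with `nitrogen_fg` and `nitrogen_fmol` (per cell).
#' @examples
#' nitrogen_content(100)  # 15.09 fg-N, 1.078 fmol-N
#' @export
nitrogen_content <- function(carbon_fg, cn_ratio = sip_constants$redfield_cn) {
  if (cn_ratio <= 0) stop("cn_ratio must be positive")
  if (any(carbon_fg < 0)) stop("carbon must be non-negative")
  fgN <- carbon_fg / cn_ratio
  list(nitrogen_fg = fgN, nitrogen_fmol = fgN / sip_constants$fg_per_fmol_N)
}

#' Full cell quota from biovolume
#'
#' Chains [carbon_content()] and [nitrogen_content()].
#'
#' @param volume_um3 Biovolume, µm³.
#' @param params Allometry parameters.
#' @param cn_ratio C:N ratio.
#' @return A `cell_quota` data.frame with columns `volume_um3`, `carbon_fg`,
#'   `nitrogen_fg`, `nitrogen_fmol`.
#' @export
cell_quota <- function(volume_um3, params = allometry_params(),
                       cn_ratio = sip_constants$redfield_cn) {
  cfg <- carbon_content(volume_um3, params)
  n <- nitrogen_content(cfg, cn_ratio)
  structure(data.frame(volume_um3 = volume_um3, carbon_fg = cfg,
                       nitrogen_fg = n$nitrogen_fg,
                       nitrogen_fmol = n$nitrogen_fmol),
            class = c("cell_quota", "data.frame"))
}

#' Write a quota table to CSV
#'
#' @param quotas A data.frame with a `taxon` column plus quota columns.
#' @param path Output path.
#' @return The data.frame, invisibly.
#' @export
write_quota_table <- function(quotas, path) {
  utils::write.csv(quotas, path, row.names = FALSE)
  invisible(quotas)
}
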