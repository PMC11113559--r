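#' Classify a sample into a water mass
#'
#' Operational classification from salinity, latitude and bottom depth.
#' North of Cape Hatteras: S < 34.5 is MAB shelf water, 34.5 <= S < 36 Slope
#' Sea, 36 <= S < 36.5 Slope Sea-Gulf Stream frontal water, S >= 36.5 Gulf
#' Stream. South of Cape Hatteras the shelf (bottom depth <= 200 m) is SAB
#' shelf water regardless of salinity; deeper stations are Gulf Stream when
#' S >= 36.5, otherwise frontal water. Boundary salinities fall in the upper
#' interval (half-open [lower, upper) convention).
#'
#' @param latitude degrees north.
#' @param salinity practical salinity.
#' @param bottom_depth station bottom depth, m; required south of
#'   `hatteras_lat`.
#' @param hatteras_lat latitude separating the Mid- from the South Atlantic
#'   Bight (default 35.25 degrees N).
#' @return character vector of labels in
#'   `c("MAB", "SlopeSea", "SSGSFront", "SAB", "GulfStream")`.
#' @export
#' @examples
#' classify_water_mass(36.5, 34.0)            # "MAB"
#' classify_water_mass(34.0, 36.2, 80)        # "SAB"
#' classify_water_mass(34.0, 36.8, 3000)      # "GulfStream"
classify_water_mass <- function(latitude, salinity, bottom_depth = NA_real_,
                                hatteras_lat = 35.25) {
  n <- max(length(latitude), length(salinity), length(bottom_depth))
  latitude <- rep_len(latitude, n)
  salinity <- rep_len(salinity, n)
  bottom_depth <- rep_len(bottom_depth, n)
  if (any(is.na(salinity))) stop("salinity is required for classification")
  if (any(is.na(latitude))) stop("latitude is required for classification")
  if (any(salinity <= 0 | salinity >= 45)) stop("salinity outside (0, 45)")
  north <- latitude >= hatteras_lat
  if (any(!north & is.na(bottom_depth))) {
    stop("bottom_depth is required for stations south of hatteras_lat")
  }
  label <- character(n)
  label[north & salinity < 34.5] <- "MAB"
  label[north & salinity >= 34.5 & salinity < 36] <- "SlopeSea"
  label[north & salinity >= 36 & salinity < 36.5] <- "SSGSFront"
  label[north & salinity >= 36.5] <- "GulfStream"
  south <- !north
  label[south & bottom_depth <= 200] <- "SAB"
  label[south & bottom_depth > 200 & salinity >= 36.5] <- "GulfStream"
  label[south & bottom_depth > 200 & salinity < 36.5] <- "SSGSFront"
  label
}

#' Chlorophyll a from CTD fluorescence
#'
#' Linear calibration Chl = 0.55 FL - 0.19 (ug L^-1) against HPLC total
#' chlorophyll a. Negative results are returned as-is; use the attribute
#' `negative` or downstream flags to track them.
#'
#' @param FL fluorescence, relative units.
#' @return chlorophyll a, ug L^-1, with logical attribute `negative`.
#' @export
chl_from_fluorescence <- function(FL) {
  if (any(!is.finite(FL))) stop("FL must be finite")
  chl <- 0.55 * FL - 0.19
  attr(chl, "negative") <- chl < 0
  chl
}

#' Excess phosphate relative to the Redfield expectation
#'
#' P* = [PO4] - [NO3]/16 (umol L^-1). Below-detection concentrations should
#' be substituted with 0 by the caller (the pipeline does so, flagging them).
#'
#' @param PO4,NO3 concentrations, umol L^-1 (>= 0).
#' @return P*, umol L^-1.
#' @export
p_star <- function(PO4, NO3) {
  stopifnot(all(PO4 >= 0), all(NO3 >= 0))
  PO4 - NO3 / 16
}

#' Depth of the chlorophyll maximum in a profile
#'
#' Ties are broken toward the shallower depth.
#'
#' @param depth depths, m (need not be sorted).
#' @param chl chlorophyll at each depth; `NA` allowed but not all-missing.
#' @return depth of the maximum, m.
#' @export
find_chl_max <- function(depth, chl) {
  stopifnot(length(depth) == length(chl))
  ok <- !is.na(chl)
  if (sum(ok) < 1L) stop("no non-missing chlorophyll values in profile")
  depth <- depth[ok]; chl <- chl[ok]
  o <- order(depth)
  depth <- depth[o]; chl <- chl[o]
  depth[which.max(chl)]  # which.max returns the first (shallowest) maximum
}

#' Classify and derive hydrographic quantities for a cruise table
#'
#' Adds the water-mass label, fluorescence-derived chlorophyll, P*
#' (below-detection nutrients entering as zero, flagged), and the
#' chlorophyll-maximum depth of each station's profile.
#'
#' @param hydro data frame with columns `station_id`, `latitude`,
#'   `bottom_depth_m`, `depth_m`, `salinity`, `fluorescence`,
#'   `no3_umolN_L`, `no3_bdl`, `po4_umol_L`, `po4_bdl` (other columns pass
#'   through).
#' @param hatteras_lat see [classify_water_mass()].
#' @return the input with columns `water_mass`, `chl_ugL`, `chl_negative`,
#'   `p_star_umol_L`, `p_star_bdl_input`, `chl_max_depth_m` appended.
#' @export
classify_hydro <- function(hydro, hatteras_lat = 35.25) {
  req <- c("station_id", "latitude", "bottom_depth_m", "depth_m", "salinity",
           "fluorescence", "no3_umolN_L", "no3_bdl", "po4_umol_L", "po4_bdl")
  missing_cols <- setdiff(req, names(hydro))
  if (length(missing_cols)) {
    stop("hydro table is missing column(s): ", toString(missing_cols))
  }
  hydro$water_mass <- classify_water_mass(hydro$latitude, hydro$salinity,
                                          hydro$bottom_depth_m, hatteras_lat)
  chl <- chl_from_fluorescence(hydro$fluorescence)
  hydro$chl_ugL <- as.numeric(chl)
  hydro$chl_negative <- attr(chl, "negative")
  no3 <- ifelse(hydro$no3_bdl, 0, hydro$no3_umolN_L)
  po4 <- ifelse(hydro$po4_bdl, 0, hydro$po4_umol_L)
  hydro$p_star_umol_L <- p_star(po4, no3)
  hydro$p_star_bdl_input <- hydro$no3_bdl | hydro$po4_bdl
  cmx <- vapply(split(hydro, hydro$station_id),
                function(p) find_chl_max(p$depth_m, p$chl_ugL), numeric(1))
  hydro$chl_max_depth_m <- cmx[as.character(hydro$station_id)]
  hydro
}
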