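#' Method detection limits for dissolved nutrients
#'
#' Wet-chemistry method detection limits, umol N L^-1 (phosphate umol P
#' L^-1): nitrate+nitrite 0.14, nitrite 0.07, phosphate 0.03, urea 0.08,
#' ammonium 0.010, cyanate 0.0004, dissolved free amino acids 0.004.
#' @export
METHOD_DLS <- c(no3 = 0.14, no2 = 0.07, po4 = 0.03, urea = 0.08,
                nh4 = 0.010, cyanate = 0.0004, dfaa = 0.004)

NUTRIENT_FIELDS <- names(METHOD_DLS)
DEPTH_IDS <- c("surface", "above_chl_max", "chl_max")

#' Default per-regime parameter tables for the synthetic cruise
#'
#' Four hydrographic regimes with contrasting temperature, salinity,
#' nutrient fields, particulate nitrogen, chlorophyll, true uptake rates
#' per substrate, and community composition. Salinities sit well inside the
#' water-mass classification bands so that a noise-free cruise classifies
#' exactly to its truth labels; regional total uptake decreases
#' MAB > SlopeSea > SAB > GulfStream. The values are illustrative regime
#' contrasts, not fitted to any data set. Urea sits below its method
#' detection limit everywhere, so urea source pools are spike-dominated.
#'
#' @return named list of regime parameter lists.
#' @export
default_regime_params <- function() {
  rates <- function(total, frac) {
    stopifnot(abs(sum(frac) - 1) < 1e-9)
    total * frac[SUBSTRATES]
  }
  frac9 <- function(...) {
    f <- c(...)
    stopifnot(identical(names(f), PIGMENT_GROUPS), abs(sum(f) - 1) < 1e-9)
    f
  }
  list(
    MAB = list(
      label = "MAB", latitude = 37.0, longitude = -75.2, bottom_depth_m = 60,
      temperature = 22, salinity = 33.5, chl_max_depth_m = 21,
      nutrients = c(no3 = 0.60, no2 = 0.08, po4 = 0.25, urea = 0.03,
                    nh4 = 0.15, cyanate = 0.008, dfaa = 0.25),
      pn_umolN_L = 1.5, tchla_ugL = 1.2,
      uptake = rates(0.34, c(NO3 = 0.20, NO2 = 0.14, NH4 = 0.18,
                             urea = 0.28, cyanate = 0.004, DFAA = 0.196)),
      fractions = frac9(Diat = 0.45, Dino = 0.06, Hapt8 = 0.10, Hapt6 = 0.04,
                        Chlo = 0.06, Cryp = 0.04, Proc = 0.02, Syne = 0.13,
                        Pras = 0.10),
      upwelling = FALSE),
    SlopeSea = list(
      label = "SlopeSea", latitude = 36.4, longitude = -74.5,
      bottom_depth_m = 2000, temperature = 24, salinity = 35.2,
      chl_max_depth_m = 33,
      nutrients = c(no3 = 0.40, no2 = 0.05, po4 = 0.08, urea = 0.03,
                    nh4 = 0.06, cyanate = 0.004, dfaa = 0.17),
      pn_umolN_L = 1.0, tchla_ugL = 0.8,
      uptake = rates(0.23, c(NO3 = 0.22, NO2 = 0.13, NH4 = 0.16,
                             urea = 0.28, cyanate = 0.01, DFAA = 0.20)),
      fractions = frac9(Diat = 0.35, Dino = 0.05, Hapt8 = 0.14, Hapt6 = 0.05,
                        Chlo = 0.05, Cryp = 0.04, Proc = 0.07, Syne = 0.15,
                        Pras = 0.10),
      upwelling = FALSE),
    SAB = list(
      label = "SAB", latitude = 34.0, longitude = -76.8, bottom_depth_m = 80,
      temperature = 28, salinity = 36.2, chl_max_depth_m = 30,
      nutrients = c(no3 = 0.15, no2 = 0.03, po4 = 0.02, urea = 0.03,
                    nh4 = 0.03, cyanate = 0.002, dfaa = 0.12),
      pn_umolN_L = 0.8, tchla_ugL = 0.5,
      uptake = rates(0.13, c(NO3 = 0.25, NO2 = 0.10, NH4 = 0.23,
                             urea = 0.25, cyanate = 0.02, DFAA = 0.15)),
      fractions = frac9(Diat = 0.25, Dino = 0.05, Hapt8 = 0.12, Hapt6 = 0.05,
                        Chlo = 0.05, Cryp = 0.03, Proc = 0.15, Syne = 0.22,
                        Pras = 0.08),
      upwelling = FALSE),
    GulfStream = list(
      label = "GulfStream", latitude = 34.3, longitude = -75.6,
      bottom_depth_m = 3000, temperature = 28.5, salinity = 36.8,
      chl_max_depth_m = 102,
      nutrients = c(no3 = 0.05, no2 = 0.01, po4 = 0.01, urea = 0.02,
                    nh4 = 0.005, cyanate = 0.001, dfaa = 0.06),
      pn_umolN_L = 0.3, tchla_ugL = 0.08,
      uptake = rates(0.062, c(NO3 = 0.14, NO2 = 0.12, NH4 = 0.22,
                              urea = 0.28, cyanate = 0.08, DFAA = 0.16)),
      fractions = frac9(Diat = 0.03, Dino = 0.02, Hapt8 = 0.20, Hapt6 = 0.05,
                        Chlo = 0.03, Cryp = 0.02, Proc = 0.35, Syne = 0.25,
                        Pras = 0.05),
      upwelling = FALSE)
  )
}

#' Configuration for the synthetic cruise generator
#'
#' @param n_stations_per_regime stations per hydrographic regime.
#' @param depths_per_station sampling depths per station (3: surface, above
#'   the chlorophyll maximum, at the chlorophyll maximum).
#' @param regime_params per-regime parameter list, see
#'   [default_regime_params()].
#' @param noise_cv scalar fractional analytical coefficient of variation
#'   applied to concentrations, pigments, particulate N and atom% excess;
#'   salinity receives an absolute Gaussian SD of `2 * noise_cv` psu and
#'   temperature a CV of `noise_cv / 5`, reflecting CTD precision.
#' @param duration_h incubation length, hours.
#' @param spike_atom_pct tracer atom% 15N.
#' @param seed integer; fully determines the generated cruise.
#' @return validated list of class `cruise_config`.
#' @export
cruise_config <- function(n_stations_per_regime = 4L, depths_per_station = 3L,
                          regime_params = default_regime_params(),
                          noise_cv = 0.05, duration_h = 3, spike_atom_pct = 98.5,
                          seed = 1L) {
  stopifnot(n_stations_per_regime >= 1L, depths_per_station %in% c(2L, 3L),
            noise_cv >= 0, duration_h > 0,
            spike_atom_pct > 0, spike_atom_pct <= 100)
  bands <- list(MAB = c(0, 34.5), SlopeSea = c(34.5, 36),
                SSGSFront = c(36, 36.5), SAB = c(0, 45), GulfStream = c(36.5, 45))
  for (rn in names(regime_params)) {
    rp <- regime_params[[rn]]
    for (fld in c("nutrients", "pn_umolN_L", "tchla_ugL", "uptake")) {
      v <- rp[[fld]]
      if (any(v < 0)) {
        stop("regime ", rn, ": negative value in field '", fld, "'")
      }
    }
    if (abs(sum(rp$fractions) - 1) > 1e-9) {
      stop("regime ", rn, ": field 'fractions' must sum to 1")
    }
    b <- bands[[rp$label]]
    if (!is.null(b) && (rp$salinity < b[1] || rp$salinity >= b[2])) {
      stop("regime ", rn, ": field 'salinity' (", rp$salinity,
           ") outside its water-mass band [", b[1], ", ", b[2], ")")
    }
  }
  structure(list(n_stations_per_regime = as.integer(n_stations_per_regime),
                 depths_per_station = as.integer(depths_per_station),
                 regime_params = regime_params, noise_cv = noise_cv,
                 duration_h = duration_h, spike_atom_pct = spike_atom_pct,
                 seed = as.integer(seed)),
            class = "cruise_config")
}

# Forward model for one incubation: noise-free endpoint of the two-pool
# mixing model, then replicate noise. Draws from the current RNG stream
# when seed is NULL.
simulate_incubation_impl <- function(rho_true, PN0, a0, a_src, duration,
                                     n_replicates, noise_cv, pool_conc) {
  af0 <- (PN0 * a0 + rho_true * duration * a_src) / (PN0 + rho_true * duration)
  pnf0 <- PN0 + rho_true * duration
  pn_i <- lognormal_noise(rep(PN0, n_replicates), noise_cv)
  pn_f <- lognormal_noise(rep(pnf0, n_replicates), noise_cv)
  # IRMS-style noise: Gaussian on the atom% excess, SD scaled to the signal
  af <- af0 + if (noise_cv > 0) {
    stats::rnorm(n_replicates, 0, noise_cv * (af0 - a0))
  } else rep(0, n_replicates)
  consumed <- if (is.na(pool_conc)) NA_real_ else {
    min(1, rho_true * duration / pool_conc)
  }
  data.frame(replicate = seq_len(n_replicates),
             pn_initial_umolN_L = pn_i, pn_final_umolN_L = pn_f,
             atom_pn_initial_pct = a0, atom_pn_final_pct = af,
             duration_h = duration, consumed_fraction = consumed)
}

#' Forward-simulate one tracer incubation
#'
#' Noise-free endpoint: af = (PN0 a0 + rho t a_src) / (PN0 + rho t),
#' PN_final = PN0 + rho t. Replicate noise is multiplicative lognormal on
#' particulate N and additive Gaussian on the final atom% with SD =
#' noise_cv x (af - a0). The consumed fraction of the dissolved pool is
#' recorded when `pool_conc` is supplied, so quality-control filters can be
#' exercised downstream.
#'
#' @param rho_true true absolute uptake rate, umol N L^-1 h^-1 (>= 0).
#' @param PN0 initial particulate N, umol N L^-1.
#' @param a0 initial PN atom% 15N.
#' @param a_src source-pool atom% 15N (must exceed `a0`).
#' @param duration hours (> 0).
#' @param n_replicates replicate bottles.
#' @param noise_cv analytical CV.
#' @param seed integer, or `NULL` to draw from the current RNG stream.
#' @param pool_conc dissolved pool (ambient + spike), umol N L^-1, for the
#'   consumed-fraction bookkeeping; `NA` to omit.
#' @return data frame with one row per replicate (columns `replicate`,
#'   `pn_initial_umolN_L`, `pn_final_umolN_L`, `atom_pn_initial_pct`,
#'   `atom_pn_final_pct`, `duration_h`, `consumed_fraction`).
#' @export
simulate_incubation <- function(rho_true, PN0, a0, a_src, duration,
                                n_replicates = 3L, noise_cv = 0, seed = NULL,
                                pool_conc = NA_real_) {
  stopifnot(rho_true >= 0, PN0 > 0, duration > 0, n_replicates >= 1L,
            noise_cv >= 0, a0 > 0, a0 < 100)
  if (a_src <= a0) stop("a_src must exceed a0 (no isotopic contrast)")
  if (a_src > 100) stop("a_src cannot exceed 100 atom%")
  if (is.null(seed)) {
    simulate_incubation_impl(rho_true, PN0, a0, a_src, duration,
                             n_replicates, noise_cv, pool_conc)
  } else {
    local_seed(seed, simulate_incubation_impl(rho_true, PN0, a0, a_src,
                                              duration, n_replicates,
                                              noise_cv, pool_conc))
  }
}

#' Forward-simulate an HPLC pigment profile
#'
#' p = tchla x fractions' A plus multiplicative lognormal noise, with A the
#' expanded ratio matrix in which only Prochlorococcus contributes
#' divinyl-chlorophyll a.
#'
#' @param true_fractions named group fractions (sum to 1).
#' @param tchla total chlorophyll a, ug L^-1 (>= 0).
#' @param ratio_matrix see [default_ratio_matrix()].
#' @param noise_cv analytical CV.
#' @param seed integer or `NULL` (current RNG stream).
#' @return named numeric vector over [PIGMENT_CHANNELS].
#' @export
generate_pigments <- function(true_fractions, tchla,
                              ratio_matrix = default_ratio_matrix(),
                              noise_cv = 0, seed = NULL) {
  if (tchla < 0) stop("tchla must be non-negative")
  if (abs(sum(true_fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (!all(PIGMENT_GROUPS %in% names(true_fractions))) {
    stop("true_fractions must be named over: ", toString(PIGMENT_GROUPS))
  }
  A <- expand_ratio_matrix(ratio_matrix)
  p <- as.numeric(tchla * true_fractions[PIGMENT_GROUPS] %*% A)
  names(p) <- colnames(A)
  noisy <- function() {
    out <- lognormal_noise(p, noise_cv)
    names(out) <- names(p)
    out
  }
  if (is.null(seed)) noisy() else local_seed(seed, noisy())
}

#' Generate a complete synthetic cruise with known ground truth
#'
#' Emits the station, hydrography, incubation, pigment and truth tables
#' consumed by the pipeline. Deterministic for a fixed `config$seed`.
#' Tracer spikes are sized to keep substrate consumption below the 50%
#' exclusion threshold (matching the mostly-moderate consumption observed
#' at sea) while landing source enrichments of roughly 5-50 atom%; spike
#' pools for substrates whose ambient concentration is unmeasurable (urea)
#' are spike-dominated and carry the over-enrichment advisory downstream.
#'
#' @param config a [cruise_config()].
#' @return list of data frames: `stations`, `hydro`, `incubations`,
#'   `pigments`, `truth`.
#' @export
generate_cruise <- function(config) {
  stopifnot(inherits(config, "cruise_config"))
  local_seed(config$seed, generate_cruise_impl(config))
}

generate_cruise_impl <- function(config) {
  cv <- config$noise_cv
  depth_factors_nut <- c(surface = 0.5, above_chl_max = 1, chl_max = 2)
  depth_factors_chl <- c(surface = 0.7, above_chl_max = 0.85, chl_max = 1)
  nat <- isotope_constants()$natural_abundance_atom_pct
  stations <- hydro <- incs <- pigs <- truth <- list()
  for (rn in names(config$regime_params)) {
    rp <- config$regime_params[[rn]]
    for (si in seq_len(config$n_stations_per_regime)) {
      sid <- sprintf("%s_%02d", rn, si)
      lat <- rp$latitude + 0.05 * (si - 1)
      stations[[sid]] <- data.frame(
        station_id = sid, regime = rn, latitude = lat,
        longitude = rp$longitude + 0.05 * (si - 1),
        bottom_depth_m = rp$bottom_depth_m,
        upwelling = isTRUE(rp$upwelling), stringsAsFactors = FALSE)
      depths <- c(surface = 2,
                  above_chl_max = round(0.6 * rp$chl_max_depth_m),
                  chl_max = rp$chl_max_depth_m)[seq_len(config$depths_per_station)]
      for (did in names(depths)) {
        tmp <- lognormal_noise(rp$temperature, cv / 5)
        sal <- rp$salinity + if (cv > 0) stats::rnorm(1, 0, 2 * cv) else 0
        chl_true <- rp$tchla_ugL * depth_factors_chl[[did]]
        fl <- (chl_true + 0.19) / 0.55
        fl <- lognormal_noise(fl, cv)
        nut_true <- rp$nutrients * depth_factors_nut[[did]]
        nut_true["urea"] <- rp$nutrients[["urea"]]  # no depth structure
        nut_obs <- lognormal_noise(nut_true, cv)
        bdl <- nut_obs < METHOD_DLS[NUTRIENT_FIELDS]
        sigma <- 26.5 - 0.15 * (tmp - 20) + 0.75 * (sal - 35)
        row <- data.frame(station_id = sid, depth_id = did,
                          latitude = lat, bottom_depth_m = rp$bottom_depth_m,
                          depth_m = unname(depths[[did]]), temperature = tmp,
                          salinity = sal, sigma_kg_m3 = sigma,
                          fluorescence = fl,
                          pn_umolN_L = lognormal_noise(rp$pn_umolN_L, cv),
                          stringsAsFactors = FALSE)
        for (nf in NUTRIENT_FIELDS) {
          row[[paste0(nf, if (nf == "po4") "_umol_L" else "_umolN_L")]] <- nut_obs[[nf]]
          row[[paste0(nf, "_bdl")]] <- unname(bdl[[nf]])
        }
        hydro[[paste(sid, did)]] <- row
        # pigments
        pvec <- generate_pigments(rp$fractions, chl_true, noise_cv = cv)
        pigs[[paste(sid, did)]] <- cbind(
          data.frame(station_id = sid, depth_id = did, stringsAsFactors = FALSE),
          as.data.frame(as.list(pvec)))
        # incubations, one experiment per substrate
        sub_amb <- c(NO3 = nut_true[["no3"]], NO2 = nut_true[["no2"]],
                     NH4 = nut_true[["nh4"]], urea = nut_true[["urea"]],
                     cyanate = nut_true[["cyanate"]], dfaa = nut_true[["dfaa"]])
        names(sub_amb) <- SUBSTRATES[match(names(sub_amb),
                                           c("NO3", "NO2", "NH4", "urea", "cyanate", "dfaa"))]
        # uptake is depth-uniform: observed rates did not differ
        # significantly across the three sampling depths
        for (sub in SUBSTRATES) {
          rho <- rp$uptake[[sub]]
          amb_true <- sub_amb[[sub]]
          spike <- max(0.45 * amb_true, 2.5 * rho * config$duration_h, 1e-4)
          amb_obs_col <- switch(sub, NO3 = "no3_umolN_L", NO2 = "no2_umolN_L",
                                NH4 = "nh4_umolN_L", urea = "urea_umolN_L",
                                cyanate = "cyanate_umolN_L", DFAA = "dfaa_umolN_L")
          amb_obs <- row[[amb_obs_col]]
          amb_bdl <- row[[sub("_umolN_L", "_bdl", amb_obs_col)]]
          src <- source_pool_enrichment(amb_obs, nat, spike,
                                        config$spike_atom_pct,
                                        ambient_below_dl = amb_bdl)
          reps <- simulate_incubation(rho, rp$pn_umolN_L, nat, src$atom_pct,
                                      config$duration_h, n_replicates = 3L,
                                      noise_cv = cv,
                                      pool_conc = amb_true + spike)
          incs[[paste(sid, did, sub)]] <- cbind(
            data.frame(station_id = sid, depth_id = did, substrate = sub,
                       ambient_conc_umolN_L = amb_obs, ambient_bdl = amb_bdl,
                       spike_conc_umolN_L = spike,
                       spike_atom_pct = config$spike_atom_pct,
                       daynight = "day", stringsAsFactors = FALSE),
            reps)
          truth[[paste(sid, did, sub)]] <- cbind(
            data.frame(station_id = sid, depth_id = did, substrate = sub,
                       rho_true_umolN_L_h = rho, water_mass_true = rp$label,
                       tchla_true_ugL = chl_true, stringsAsFactors = FALSE),
            as.data.frame(as.list(stats::setNames(
              rp$fractions, paste0("frac_", names(rp$fractions))))))
        }
      }
    }
  }
  bind <- function(x) { r <- do.call(rbind, unname(x)); rownames(r) <- NULL; r }
  list(stations = bind(stations), hydro = bind(hydro),
       incubations = bind(incs), pigments = bind(pigs), truth = bind(truth))
}
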