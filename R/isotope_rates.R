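#' Isotope constants for delta / atom% conversions
#'
#' Reference isotope ratio of atmospheric dinitrogen used to convert between
#' delta-15N (per mil) and atom% 15N. The natural-abundance atom% is derived
#' from the ratio and must agree with any user-supplied value to 1e-4 atom%.
#'
#' @param R_std 15N/14N ratio of the atmospheric N2 standard (unitless).
#' @param natural_abundance_atom_pct atom% 15N at natural abundance; computed
#'   from `R_std` when `NULL`.
#' @return A list of class `isotope_constants` with elements `R_std` and
#'   `natural_abundance_atom_pct`.
#' @export
#' @examples
#' isotope_constants()$natural_abundance_atom_pct # ~0.3663
isotope_constants <- function(R_std = 0.0036765,
                              natural_abundance_atom_pct = NULL) {
  stopifnot(is.numeric(R_std), length(R_std) == 1L, R_std > 0, R_std < 1)
  derived <- 100 * R_std / (1 + R_std)
  if (is.null(natural_abundance_atom_pct)) {
    natural_abundance_atom_pct <- derived
  } else if (abs(natural_abundance_atom_pct - derived) > 1e-4) {
    stop("natural_abundance_atom_pct inconsistent with R_std (|diff| > 1e-4 atom%)")
  }
  structure(list(R_std = R_std,
                 natural_abundance_atom_pct = natural_abundance_atom_pct),
            class = "isotope_constants")
}

#' Convert delta-15N to atom percent 15N
#'
#' atom% = 100 R / (1 + R) with R = R_std (1 + delta/1000). Strictly
#' increasing in delta.
#'
#' @param delta_permil delta-15N in per mil; must exceed -1000.
#' @param constants an [isotope_constants()] object.
#' @return atom% 15N (vectorized over `delta_permil`).
#' @export
#' @examples
#' delta_to_atom_percent(0)   # 0.36630
#' delta_to_atom_percent(6)   # 0.36849
delta_to_atom_percent <- function(delta_permil, constants = isotope_constants()) {
  if (any(!is.finite(delta_permil)) || any(delta_permil <= -1000)) {
    stop("delta_permil must be finite and > -1000 (ratio would be non-positive)")
  }
  R <- constants$R_std * (1 + delta_permil / 1000)
  100 * R / (1 + R)
}

#' Known substrate identifiers
#' @export
SUBSTRATES <- c("NO3", "NO2", "NH4", "urea", "cyanate", "DFAA")

#' Assign the source-pool delta-15N for a substrate
#'
#' Nitrate source pools carry a delta-15N of 6 per mil when the ambient
#' nitrate concentration is below 0.5 umol L^-1 and 2.5 per mil when it
#' exceeds 0.5 umol L^-1 (the boundary value is treated as the high-nitrate
#' case). All other substrates are assigned natural abundance, 0 per mil.
#'
#' @param substrate one of `r toString(SUBSTRATES)`.
#' @param ambient_NO3 ambient nitrate concentration, umol L^-1; required
#'   (and non-negative) when `substrate == "NO3"`.
#' @return delta-15N in per mil.
#' @export
assign_source_delta <- function(substrate, ambient_NO3 = NA_real_) {
  substrate <- match.arg(substrate, SUBSTRATES)
  if (substrate != "NO3") return(0)
  if (is.na(ambient_NO3) || ambient_NO3 < 0) {
    stop("ambient_NO3 must be a non-negative concentration for NO3 substrate")
  }
  if (ambient_NO3 < 0.5) 6 else 2.5
}

#' Isotopic enrichment of the source pool after tracer addition
#'
#' Concentration-weighted mixture of ambient and spike atom%. Ambient pools
#' flagged below detection contribute zero concentration (the spike dominates),
#' and the result carries an `AMBIENT_BELOW_DL` flag. Enrichments above 50
#' atom% get an `OVER_ENRICHED` advisory: such rates are potential rather
#' than in-situ rates.
#'
#' @param ambient_conc ambient substrate concentration, umol N L^-1.
#' @param ambient_atom_pct atom% 15N of the ambient pool.
#' @param spike_conc tracer addition, umol N L^-1 (> 0).
#' @param spike_atom_pct atom% 15N of the tracer (typically 98-99).
#' @param ambient_below_dl logical; ambient concentration below its method
#'   detection limit.
#' @return list with `atom_pct` (source-pool atom%) and `flags`
#'   (character vector, possibly empty).
#' @export
source_pool_enrichment <- function(ambient_conc, ambient_atom_pct,
                                   spike_conc, spike_atom_pct,
                                   ambient_below_dl = FALSE) {
  stopifnot(ambient_conc >= 0, spike_conc > 0,
            ambient_atom_pct > 0, ambient_atom_pct <= 100,
            spike_atom_pct > 0, spike_atom_pct <= 100)
  flags <- character(0)
  if (isTRUE(ambient_below_dl)) {
    ambient_conc <- 0
    flags <- c(flags, "AMBIENT_BELOW_DL")
  }
  total <- ambient_conc + spike_conc
  if (total <= 0) stop("ambient + spike concentration must be positive")
  a_src <- (ambient_conc * ambient_atom_pct + spike_conc * spike_atom_pct) / total
  if (a_src > 50) flags <- c(flags, "OVER_ENRICHED")
  list(atom_pct = a_src, flags = flags)
}

#' Absolute nitrogen uptake rate (two-pool mixing model)
#'
#' rho = (af - a0) / (a_src - a0) * PN_avg / t, where PN_avg is the mean of
#' the initial and final particulate-nitrogen concentrations. Negative
#' excess enrichment yields a negative rate, which is reported (and later
#' flagged), never clamped.
#'
#' @param a0,af initial / final atom% 15N of the particulate pool.
#' @param a_src atom% 15N of the source pool after tracer addition
#'   (must exceed `a0`).
#' @param PN_initial,PN_final particulate N, umol N L^-1 (> 0).
#' @param duration incubation length, hours (> 0).
#' @return absolute uptake rate, umol N L^-1 h^-1.
#' @export
#' @examples
#' absolute_uptake_rate(0.3663, 0.5663, 9.2421, 1, 1, 2) # 0.011267
absolute_uptake_rate <- function(a0, af, a_src, PN_initial, PN_final, duration) {
  check_mixing_inputs(a0, a_src, duration)
  stopifnot(all(PN_initial > 0), all(PN_final > 0))
  (af - a0) / (a_src - a0) * (PN_initial + PN_final) / 2 / duration
}

#' Specific nitrogen uptake rate
#'
#' v = (af - a0) / (a_src - a0) / t, independent of particulate N. The
#' identity rho = v * PN_avg holds exactly.
#'
#' @inheritParams absolute_uptake_rate
#' @return specific uptake rate, h^-1.
#' @export
specific_uptake_rate <- function(a0, af, a_src, duration) {
  check_mixing_inputs(a0, a_src, duration)
  (af - a0) / (a_src - a0) / duration
}

check_mixing_inputs <- function(a0, a_src, duration) {
  if (any(a_src <= a0)) {
    stop("source-pool atom% must exceed initial PN atom% (no isotopic contrast)")
  }
  if (any(duration <= 0)) stop("duration must be positive (hours)")
  invisible(TRUE)
}

#' Per-experiment uptake detection limit
#'
#' Rates depend on incubation time and particulate N, so the detection limit
#' is evaluated per experiment: DL = atom_dl / (a_src - a0) * PN_avg / t,
#' with atom_dl the mass-spectrometer atom% detection limit (3 x SD of
#' standards; default 0.0018 atom% for 15N).
#'
#' @inheritParams absolute_uptake_rate
#' @param PN_avg mean particulate N over the incubation, umol N L^-1.
#' @param atom_dl mass-spec atom% detection limit.
#' @return detection limit, umol N L^-1 h^-1.
#' @export
experiment_detection_limit <- function(a_src, a0, PN_avg, duration,
                                       atom_dl = 0.0018) {
  check_mixing_inputs(a0, a_src, duration)
  stopifnot(all(PN_avg > 0), atom_dl > 0)
  atom_dl / (a_src - a0) * PN_avg / duration
}

#' Consumption quality-control filter
#'
#' Experiments in which at least half of the added substrate was consumed are
#' excluded from analysis (`EXCLUDED_CONSUMPTION`). A missing consumed
#' fraction yields an advisory flag only.
#'
#' @param consumed_fraction fraction of the added substrate consumed, in
#'   [0, 1], or `NA` when not measured.
#' @param threshold exclusion threshold (default 0.5).
#' @return character vector of flags (possibly empty).
#' @export
qc_consumption_filter <- function(consumed_fraction, threshold = 0.5) {
  if (is.na(consumed_fraction)) return("CONSUMPTION_UNKNOWN")
  if (consumed_fraction < 0 || consumed_fraction > 1) {
    stop("consumed_fraction must lie in [0, 1]")
  }
  if (consumed_fraction >= threshold) "EXCLUDED_CONSUMPTION" else character(0)
}

#' Aggregate replicate rates into one experiment result
#'
#' Mean and sample standard deviation over replicate rates (SD = 0 with a
#' `SINGLE_REPLICATE` flag for n = 1); flags are unioned. If
#' `EXCLUDED_CONSUMPTION` is present the aggregate carries no rates.
#'
#' @param rates numeric vector of per-replicate absolute rates.
#' @param specific_rates matching per-replicate specific rates (optional).
#' @param flags character vector of flags accumulated for the experiment.
#' @return list with `rate`, `rate_sd`, `specific_rate`, `specific_sd`,
#'   `n`, `flags`.
#' @export
aggregate_replicates <- function(rates, specific_rates = NULL,
                                 flags = character(0)) {
  if (length(rates) == 0L) stop("at least one replicate rate is required")
  if (length(rates) == 1L) flags <- c(flags, "SINGLE_REPLICATE")
  flags <- sort(unique(flags))
  if ("EXCLUDED_CONSUMPTION" %in% flags) {
    return(list(rate = NA_real_, rate_sd = NA_real_,
                specific_rate = NA_real_, specific_sd = NA_real_,
                n = length(rates), flags = flags))
  }
  sdev <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(rate = mean(rates), rate_sd = sdev(rates),
       specific_rate = if (is.null(specific_rates)) NA_real_ else mean(specific_rates),
       specific_sd = if (is.null(specific_rates)) NA_real_ else sdev(specific_rates),
       n = length(rates), flags = flags)
}

#' Compute uptake rates for a table of incubation replicates
#'
#' Driver for the isotope-rate stage: groups replicate rows by station,
#' depth and substrate, assigns the source-pool enrichment, evaluates the
#' mixing model per replicate, aggregates triplicates, computes the
#' per-experiment detection limit, and applies the quality-control rules.
#'
#' @param incubations data frame with one row per replicate; required
#'   columns: `station_id`, `depth_id`, `substrate`, `ambient_conc_umolN_L`,
#'   `ambient_bdl`, `spike_conc_umolN_L`, `spike_atom_pct`, `replicate`,
#'   `pn_initial_umolN_L`, `pn_final_umolN_L`, `atom_pn_initial_pct`,
#'   `atom_pn_final_pct`, `duration_h`, `consumed_fraction` (NA allowed).
#' @param constants an [isotope_constants()] object.
#' @param atom_dl mass-spec atom% detection limit for 15N.
#' @return data frame with one row per experiment: rates, SDs, detection
#'   limit, source atom%, replicate count and semicolon-joined flags.
#' @export
compute_uptake_rates <- function(incubations, constants = isotope_constants(),
                                 atom_dl = 0.0018) {
  req <- c("station_id", "depth_id", "substrate", "ambient_conc_umolN_L",
           "ambient_bdl", "spike_conc_umolN_L", "spike_atom_pct", "replicate",
           "pn_initial_umolN_L", "pn_final_umolN_L", "atom_pn_initial_pct",
           "atom_pn_final_pct", "duration_h", "consumed_fraction")
  missing_cols <- setdiff(req, names(incubations))
  if (length(missing_cols)) {
    stop("incubations table is missing column(s): ", toString(missing_cols))
  }
  key <- interaction(incubations$station_id, incubations$depth_id,
                     incubations$substrate, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(incubations, key), function(exp) {
    first <- exp[1L, ]
    # ambient NO3 drives the source delta only for the nitrate substrate
    delta <- assign_source_delta(first$substrate,
                                 ambient_NO3 = first$ambient_conc_umolN_L)
    a_amb <- delta_to_atom_percent(delta, constants)
    src <- source_pool_enrichment(first$ambient_conc_umolN_L, a_amb,
                                  first$spike_conc_umolN_L,
                                  first$spike_atom_pct,
                                  ambient_below_dl = isTRUE(first$ambient_bdl))
    a0 <- exp$atom_pn_initial_pct
    af <- exp$atom_pn_final_pct
    rho <- absolute_uptake_rate(a0, af, src$atom_pct,
                                exp$pn_initial_umolN_L, exp$pn_final_umolN_L,
                                first$duration_h)
    v <- specific_uptake_rate(a0, af, src$atom_pct, first$duration_h)
    flags <- c(src$flags, qc_consumption_filter(first$consumed_fraction))
    if (any(af < a0)) flags <- c(flags, "NEGATIVE_RATE")
    agg <- aggregate_replicates(rho, v, flags)
    pn_avg <- mean((exp$pn_initial_umolN_L + exp$pn_final_umolN_L) / 2)
    dl <- experiment_detection_limit(src$atom_pct, mean(a0), pn_avg,
                                     first$duration_h, atom_dl)
    if (!is.na(agg$rate) && agg$rate < dl) agg$flags <- sort(unique(c(agg$flags, "BELOW_DETECTION")))
    data.frame(station_id = first$station_id, depth_id = first$depth_id,
               substrate = first$substrate,
               rate_umolN_L_h = agg$rate, rate_sd = agg$rate_sd,
               specific_rate_h = agg$specific_rate, specific_sd = agg$specific_sd,
               detection_limit_umolN_L_h = dl,
               source_atom_pct = src$atom_pct,
               n_replicates = agg$n,
               flags = paste(agg$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test whether an experiment result is excluded from analysis
#' @param flags semicolon-joined flag string (column `flags` of a rates table).
#' @return logical.
#' @export
is_excluded <- function(flags) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(f) "EXCLUDED_CONSUMPTION" %in% f, logical(1))
}
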