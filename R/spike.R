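#' Spike-in experiment design
#'
#' Pipetting parameters for spiking a digested protein standard (a
#' UPS2-like mixture) into a background digest. Defaults describe a
#' 10.6 µg standard vial resuspended in 25 µL, of which 1.5 µL is spiked
#' into 7.5 µL of background digest at 200 ng/µL, with 4 µL of the mixture
#' injected.
#'
#' @param standard_total_mass_ng Standard mass in the vial (ng).
#' @param standard_resuspension_uL Resuspension volume (µL).
#' @param standard_spike_uL Volume of resuspended standard spiked (µL).
#' @param background_conc_ng_per_uL Background digest concentration (ng/µL).
#' @param background_uL Background volume receiving the spike (µL).
#' @param injection_uL Injected volume of the final mixture (µL).
#' @return A list of class `spike_design`.
#' @export
#' @examples
#' spike_mixture(spike_design())
spike_design <- function(standard_total_mass_ng = 10600,
                         standard_resuspension_uL = 25,
                         standard_spike_uL = 1.5,
                         background_conc_ng_per_uL = 200,
                         background_uL = 7.5,
                         injection_uL = 4) {
  fields <- list(
    standard_total_mass_ng = standard_total_mass_ng,
    standard_resuspension_uL = standard_resuspension_uL,
    standard_spike_uL = standard_spike_uL,
    background_conc_ng_per_uL = background_conc_ng_per_uL,
    background_uL = background_uL,
    injection_uL = injection_uL
  )
  if (any(unlist(fields) <= 0)) {
    abort("all spike-design volumes, masses and concentrations must be positive")
  }
  if (injection_uL > standard_spike_uL + background_uL) {
    abort("cannot inject more than the mixture volume")
  }
  structure(fields, class = "spike_design")
}

#' Derived spike-mixture quantities
#'
#' Exact arithmetic of the spike design: standard concentration after
#' resuspension, mass ratio of background to standard in the mixture, and
#' the total and standard-only masses in the injected volume. Values are
#' exact; any rounding is left to the caller.
#'
#' @param design A [spike_design()] list.
#' @return One-row tibble with `standard_conc_ng_per_uL`,
#'   `ratio_background_to_standard`, `injected_total_ng`,
#'   `injected_standard_ng`.
#' @export
spike_mixture <- function(design = spike_design()) {
  stopifnot(inherits(design, "spike_design"))
  standard_conc <- design$standard_total_mass_ng / design$standard_resuspension_uL
  standard_ng <- design$standard_spike_uL * standard_conc
  background_ng <- design$background_uL * design$background_conc_ng_per_uL
  mixture_uL <- design$standard_spike_uL + design$background_uL
  injected_frac <- design$injection_uL / mixture_uL
  tibble::tibble(
    standard_conc_ng_per_uL = standard_conc,
    ratio_background_to_standard = background_ng / standard_ng,
    injected_total_ng = (standard_ng + background_ng) * injected_frac,
    injected_standard_ng = standard_ng * injected_frac
  )
}
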