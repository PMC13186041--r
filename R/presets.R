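#' Named study presets
#'
#' Complete, ready-to-run configurations for the canonical double-pulse
#' simulations:
#'
#' * `"valine_memory"` — wild-type memory experiment: gamma GR distribution
#'   with mean 1100 and sd 220 (shape 25, scale 44), two 5-min 3.5 mM pulses
#'   starting at 0 and 30 min, binding constant `k1 = 14e-3`.
#' * `"wt_broad"` — wild-type with a broad (exponential) GR distribution:
#'   shape 1, scale 1100; two 2-min 10 mM pulses, `k1 = 350e-5`.
#' * `"gera_over"` — GerA-overexpressing spores: shape 67, scale 50 (mean
#'   3350); two 2-min 10 mM pulses, `k1 = 350e-5`.
#' * `"gr_scan"` — deterministic receptor scan setup: the `valine_memory`
#'   kinetics and protocol with a uniform `Ri0` axis 600 to 1800 in steps of
#'   50 instead of gamma draws.
#'
#' All other rate constants are shared: `k_minus1 = 100e-3`, `k2 = 25e-7`,
#' `k3 = 60e-3`, `k4 = 195e2`, `k5 = 305e-2`, `n = 3`, `theta = 20`,
#' `Cc(0) = 6500`, germination threshold 50 open channels.
#'
#' @param name One of `preset_names()`.
#' @param n_spores Ensemble size for the stochastic presets.
#' @param seed Seed for the stochastic presets.
#' @return A list with elements `params` ([kinetic_params()]), `protocol`
#'   ([pulse_protocol()]), and either `gamma` ([gamma_spec()]) plus
#'   `n_spores`/`seed`, or `Ri_values` for the deterministic scan preset.
#' @examples
#' preset_config("valine_memory")$gamma
#' @export
preset_config <- function(name, n_spores = 500, seed = 1) {
  name <- match.arg(name, preset_names())
  slow_bind <- kinetic_params(k1 = 350e-5)
  switch(name,
    valine_memory = list(
      params = kinetic_params(),
      protocol = double_pulse_protocol(3.5, duration = 5),
      gamma = gamma_spec(25, 44), n_spores = n_spores, seed = seed),
    wt_broad = list(
      params = slow_bind,
      protocol = double_pulse_protocol(10, duration = 2),
      gamma = gamma_spec(1, 1100), n_spores = n_spores, seed = seed),
    gera_over = list(
      params = slow_bind,
      protocol = double_pulse_protocol(10, duration = 2),
      gamma = gamma_spec(67, 50), n_spores = n_spores, seed = seed),
    gr_scan = list(
      params = kinetic_params(),
      protocol = double_pulse_protocol(3.5, duration = 5),
      Ri_values = seq(600, 1800, by = 50)))
}

#' @rdname preset_config
#' @export
preset_names <- function() c("valine_memory", "wt_broad", "gera_over", "gr_scan")
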