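# Shared fixtures: the aggregate control-tissue constants and a small
# cell-scale ratchet, built in code.

control_kv_params <- function() {
  # aggregate Kelvin-Voigt body: rest 20 um, stretch amplitude 40 um, tau 5
  material_params(l0 = 20, stretch = 40, tau = 5)
}

cell_ratchet_params <- function() {
  material_params(l0 = 0.3, stretch = 0.1, tau = 5, period = 20, n0 = 20L)
}

# noiseless retraction curve from a model, sampled after release
model_retraction_curve <- function(params, model_kind = "KELVIN_VOIGT",
                                   t_release = 60, dt = 0.25, t_max = 30) {
  sched <- traction_schedule(t_release)
  t_curve <- seq(0, t_max, by = dt)
  data.frame(t_min = t_curve,
             length_um = model_length(model_kind, t_release + t_curve,
                                      sched, params))
}
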