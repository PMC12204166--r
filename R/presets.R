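#' Named genotype presets
#'
#' Bundles of model kind, material parameters and noise settings emulating
#' the study genotypes, at two scales:
#'
#' \strong{Tissue scale} (whole dorsal-epidermis segment, used for
#' elongation trajectories):
#' \itemize{
#'   \item \code{"control"} — ratchet model discretized into 400 units
#'     (unit rest 0.05 um, unit stretch 0.10 um) so that the aggregate
#'     carries the canonical constants: rest 20 um, elastic amplitude
#'     40 um, tau = 5 min, polymerization period 0.75 min giving an
#'     asymptotic plastic elongation rate (l0 + stretch)/p = 0.2 um/min,
#'     and an equilibrated closure-onset length of 60 um.
#'   \item \code{"tkv"} — pure Kelvin-Voigt (period = Inf, no plasticity),
#'     same tau and unit size, per-unit stretch 1.3x control (higher
#'     stress), fewer units (n0 = 333: without plasticity no units were
#'     added before closure), equilibrated onset near 60 um and no further
#'     elongation.
#'   \item \code{"maxwell_demo"} — mixed Maxwell/Kelvin-Voigt with flow
#'     rate l0/p = 0.2 um/min, the discrimination alternative.
#' }
#'
#' \strong{Cell scale} (single leading-edge cells, used for ablation and
#' recoil-ratio experiments): n0 = 20 units of rest length 0.3 um,
#' tau = 5 min. \code{"control"} is a ratchet with per-unit stretch l0/3
#' (constant recoil ratio 25\%); \code{"tkv"} a Kelvin-Voigt with per-unit
#' stretch equal to l0, so that fully stretched cells reach twice their
#' rest length (recoil ratio up to 50\%), with per-cell traction scale
#' drawn from \code{stretch_scale_range}; \code{"maxwell_demo"} adds a slow
#' series dashpot and draws per-cell release times from
#' \code{t_release_range}, so longer cells carry proportionally more
#' permanent flow (decreasing ratio).
#'
#' @param name one of \code{"control"}, \code{"tkv"},
#'   \code{"maxwell_demo"}.
#' @param scale \code{"tissue"} or \code{"cell"}.
#' @param noise_sd additive Gaussian measurement noise on each length
#'   sample (um); default 0.5.
#' @param cv lognormal coefficient of variation of per-embryo (or
#'   per-cell) stretch and tau; default 0.15.
#' @param ratio_sd additive Gaussian noise on recoil ratios in summary
#'   records; default 0.02.
#' @return An object of class \code{"genotype_preset"}.
#' @examples
#' make_preset("control")$params$tau           # 5 min
#' make_preset("tkv")$params$period            # Inf: no plasticity
#' @export
make_preset <- function(name = c("control", "tkv", "maxwell_demo"),
                        scale = c("tissue", "cell"),
                        noise_sd = 0.5, cv = 0.15, ratio_sd = 0.02) {
  if (!is.character(name) || !name[1] %in% c("control", "tkv", "maxwell_demo"))
    stop("unknown preset '", name[1],
         "'; available: control, tkv, maxwell_demo")
  name <- match.arg(name)
  scale <- match.arg(scale)
  stopifnot(noise_sd >= 0, cv >= 0, ratio_sd >= 0)
  stretch_scale_range <- NULL
  t_release_range <- NULL
  if (scale == "tissue") {
    params <- switch(name,
      control      = material_params(l0 = 0.05, stretch = 0.10, tau = 5,
                                     period = 0.75, n0 = 400L),
      tkv          = material_params(l0 = 0.05, stretch = 0.13, tau = 5,
                                     period = Inf, n0 = 333L),
      maxwell_demo = material_params(l0 = 0.05, stretch = 0.10, tau = 5,
                                     period = 0.25, n0 = 400L))
    model_kind <- switch(name, control = "RATCHET", tkv = "KELVIN_VOIGT",
                         maxwell_demo = "MAXWELL_KV")
  } else {
    params <- switch(name,
      control      = material_params(l0 = 0.3, stretch = 0.1, tau = 5,
                                     period = 20, n0 = 20L),
      tkv          = material_params(l0 = 0.3, stretch = 0.3, tau = 5,
                                     period = Inf, n0 = 20L),
      maxwell_demo = material_params(l0 = 0.3, stretch = 0.1, tau = 5,
                                     period = 5, n0 = 20L))
    model_kind <- switch(name, control = "RATCHET", tkv = "KELVIN_VOIGT",
                         maxwell_demo = "MAXWELL_KV")
    if (name == "tkv") stretch_scale_range <- c(0.2, 1)
    if (name == "maxwell_demo") t_release_range <- c(60, 300)
  }
  structure(
    list(name = name, scale = scale, model_kind = model_kind,
         params = params, noise_sd = noise_sd, cv = cv, ratio_sd = ratio_sd,
         stretch_scale_range = stretch_scale_range,
         t_release_range = t_release_range),
    class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf("Genotype preset '%s' (%s scale): %s model\n",
              x$name, x$scale, x$model_kind))
  print(x$params)
  cat(sprintf("  noise sd %g um, cv %g, ratio sd %g\n",
              x$noise_sd, x$cv, x$ratio_sd))
  invisible(x)
}

#' Experiment specification
#'
#' Sizes, sampling and seed for a synthetic experiment. The seed is
#' mandatory: no implicit entropy, so regenerating with identical
#' (preset, spec) reproduces identical values bit for bit.
#'
#' @param n number of embryos (trajectories) or cells (ablations), >= 1.
#' @param sampling_interval sampling interval (min), > 0.
#' @param duration observation duration (min): closure duration for
#'   trajectories, retraction window for ablations; must cover at least 3
#'   sampling intervals.
#' @param t_release time under traction before ablation release (min);
#'   used by [simulate_ablation()]; default 60 (far beyond tau = 5).
#' @param seed integer random seed.
#' @return An object of class \code{"experiment_spec"}.
#' @export
experiment_spec <- function(n = 20L, sampling_interval = 0.5,
                            duration = 150, t_release = 60, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed) || seed != round(seed))
    stop("an integer 'seed' is mandatory (no implicit entropy)")
  stopifnot(n >= 1, sampling_interval > 0, duration > 0, t_release > 0)
  if (duration < 3 * sampling_interval)
    stop("'duration' must cover at least 3 sampling intervals")
  structure(
    list(n = as.integer(n), sampling_interval = sampling_interval,
         duration = duration, t_release = t_release,
         seed = as.integer(seed)),
    class = "experiment_spec")
}

# lognormal draw with given mean and coefficient of variation (cv = 0 ->
# the mean exactly)
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

provenance_block <- function(preset, spec) {
  list(preset = preset$name, scale = preset$scale,
       model_kind = preset$model_kind,
       noise_sd = preset$noise_sd, cv = preset$cv,
       ratio_sd = preset$ratio_sd,
       n = spec$n, sampling_interval = spec$sampling_interval,
       duration = spec$duration, t_release = spec$t_release,
       seed = spec$seed,
       package_version = as.character(utils::packageVersion("epirheo")))
}

#' Simulate tissue elongation trajectories
#'
#' Per embryo, draws stretch and tau from the lognormal variability model,
#' evaluates the preset's constitutive model, and adds iid Gaussian
#' measurement noise. With \code{equilibrate = TRUE} (default) the tissue
#' starts at closure onset in the model's steady state — the elastic
#' transient happened earlier (during germ-band retraction) — so a ratchet
#' preset elongates linearly from its onset length (60 um for the control
#' tissue preset) at its asymptotic plastic rate, and a Kelvin-Voigt preset
#' stays flat. With \code{equilibrate = FALSE} the model starts unstretched
#' at t = 0 and the full elastic transient is visible.
#'
#' @param spec an [experiment_spec()].
#' @param preset a [make_preset()] preset (tissue scale expected).
#' @param equilibrate logical; start from the traction steady state
#'   (default TRUE).
#' @return A tidy tibble (\code{embryo_id}, \code{time_min},
#'   \code{length_um}, \code{phase}, \code{n_units}) with a
#'   \code{"provenance"} attribute and an \code{"embryo_params"} attribute
#'   holding the drawn per-embryo parameters.
#' @export
simulate_trajectories <- function(spec, preset, equilibrate = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"),
            inherits(preset, "genotype_preset"))
  set.seed(spec$seed)
  times <- seq(0, spec$duration, by = spec$sampling_interval)
  sched <- traction_schedule(Inf)
  stretch_i <- rlnorm_cv(spec$n, preset$params$stretch, preset$cv)
  tau_i <- rlnorm_cv(spec$n, preset$params$tau, preset$cv)
  rows <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    p_i <- material_params(l0 = preset$params$l0, stretch = stretch_i[i],
                           tau = tau_i[i], period = preset$params$period,
                           n0 = preset$params$n0)
    if (equilibrate) {
      # burn-in: shift the time origin deep into the steady state so the
      # elastic transient is fully developed and (for a ratchet) the
      # unit-addition pipeline is stationary; re-anchor at the onset length
      t_burn <- if (is.finite(p_i$period))
        ceiling(20 * p_i$tau / p_i$period) * p_i$period else 20 * p_i$tau
      len <- model_length(preset$model_kind, times + t_burn, sched, p_i) -
        model_length(preset$model_kind, t_burn, sched, p_i) +
        rest_length_agg(p_i) + stretch_agg(p_i)
      n_units <- if (preset$model_kind == "RATCHET")
        ratchet_length(times + t_burn, sched, p_i)$n_units else
        rep(p_i$n0, length(times))
    } else {
      traj <- model_trajectory(preset$model_kind, sched, p_i, times)
      len <- traj$length_um
      n_units <- traj$n_units
    }
    len <- len + stats::rnorm(length(len), 0, preset$noise_sd)
    rows[[i]] <- tibble::tibble(
      embryo_id = sprintf("embryo_%02d", i),
      time_min = times, length_um = len, phase = "under_traction",
      n_units = as.integer(n_units))
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- provenance_block(preset, spec)
  attr(out, "embryo_params") <- tibble::tibble(
    embryo_id = sprintf("embryo_%02d", seq_len(spec$n)),
    stretch = stretch_i, tau = tau_i)
  out
}

#' Simulate laser-ablation experiments
#'
#' Per cell, draws parameters from the variability model, simulates the
#' traction phase to a cell-specific pre-ablation length, releases the
#' traction, samples the retraction curve at the spec's resolution, and
#' summarizes each cell into a recoil record (length before, length after
#' full relaxation, recoil, ratio).
#'
#' How the pre-ablation length is drawn depends on the preset's model:
#' ratchet cells grow to a unit count drawn uniformly in \code{n_range}
#' (release just before the next addition, so every unit is settled);
#' Kelvin-Voigt cells get a per-cell traction scale from the preset's
#' \code{stretch_scale_range}; Maxwell/KV cells get a per-cell release time
#' from the preset's \code{t_release_range} (more time, more permanent
#' flow). Retraction curves carry the preset's additive length noise;
#' summary records carry the preset's ratio noise.
#'
#' @param spec an [experiment_spec()]; \code{duration} and
#'   \code{sampling_interval} set the retraction window, \code{t_release}
#'   the time under traction (Kelvin-Voigt cells).
#' @param preset a [make_preset()] preset (cell scale expected).
#' @param n_range integer length-2: unit-count range for ratchet cells;
#'   default \code{c(n0, 2*n0)}.
#' @param curves logical; also sample and return the full retraction
#'   curves (default TRUE).
#' @return A list with \code{records} (tibble: \code{cell_id},
#'   \code{genotype}, \code{model}, \code{length_before_um},
#'   \code{length_after_um}, \code{recoil_um}, \code{ratio},
#'   \code{n_units}, \code{t_release_min}) and \code{curves} (tibble:
#'   \code{cell_id}, \code{t_min}, \code{length_um}, or NULL), plus a
#'   \code{"provenance"} attribute.
#' @export
simulate_ablation <- function(spec, preset, n_range = NULL, curves = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"),
            inherits(preset, "genotype_preset"))
  if (spec$t_release < preset$params$tau)
    warning("t_release < tau: partial-stretch regime, the long-release ",
            "recoil-ratio approximations do not apply")
  set.seed(spec$seed)
  n0 <- preset$params$n0
  if (is.null(n_range)) n_range <- c(n0, 2L * n0)
  # cell-to-cell length differences come from each model's own mechanism
  # (unit count, traction scale, flow time); the lognormal cv, an
  # inter-embryo dispersion, is applied to the retraction dynamics (tau)
  # but not to the per-cell stretch, which would confound the recoil-ratio
  # signature with traction heterogeneity
  stretch_i <- rep(preset$params$stretch, spec$n)
  tau_i <- rlnorm_cv(spec$n, preset$params$tau, preset$cv)
  t_curve <- seq(0, spec$duration, by = spec$sampling_interval)
  recs <- vector("list", spec$n)
  crv <- if (curves) vector("list", spec$n) else NULL
  for (i in seq_len(spec$n)) {
    s_i <- stretch_i[i]
    t_rel <- spec$t_release
    if (preset$model_kind == "RATCHET") {
      n_target <- sample(seq.int(n_range[1], n_range[2]), 1L)
      # release just before the next addition: all added units settled
      t_rel <- (n_target - n0 + 0.95) * preset$params$period
    } else if (preset$model_kind == "KELVIN_VOIGT" &&
               !is.null(preset$stretch_scale_range)) {
      s_i <- s_i * stats::runif(1, preset$stretch_scale_range[1],
                                preset$stretch_scale_range[2])
    } else if (preset$model_kind == "MAXWELL_KV" &&
               !is.null(preset$t_release_range)) {
      t_rel <- stats::runif(1, preset$t_release_range[1],
                            preset$t_release_range[2])
    }
    p_i <- material_params(l0 = preset$params$l0, stretch = s_i,
                           tau = tau_i[i], period = preset$params$period,
                           n0 = n0)
    sched <- traction_schedule(t_rel)
    dec <- release_decomposition(preset$model_kind, sched, p_i)
    ratio <- dec$l_stretch / dec$length_at_release +
      stats::rnorm(1, 0, preset$ratio_sd)
    recs[[i]] <- tibble::tibble(
      cell_id = sprintf("cell_%03d", i), genotype = preset$name,
      model = preset$model_kind,
      length_before_um = dec$length_at_release,
      length_after_um = dec$length_at_release * (1 - ratio),
      recoil_um = dec$length_at_release * ratio,
      ratio = ratio, n_units = dec$n_units, t_release_min = t_rel)
    if (curves) {
      len <- model_length(preset$model_kind, t_rel + t_curve, sched, p_i) +
        stats::rnorm(length(t_curve), 0, preset$noise_sd)
      crv[[i]] <- tibble::tibble(
        cell_id = sprintf("cell_%03d", i), t_min = t_curve, length_um = len)
    }
  }
  out <- list(records = do.call(rbind, recs),
              curves = if (curves) do.call(rbind, crv) else NULL)
  attr(out, "provenance") <- provenance_block(preset, spec)
  out
}
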