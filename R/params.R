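#' Constitutive parameters of a viscoelastic/viscoplastic material
#'
#' Bundle of the parameters shared by the three constitutive models of the
#' dorsal epidermis (Kelvin-Voigt, mixed Maxwell/Kelvin-Voigt, ratchet
#' polymerization). Only ratios of the raw mechanical constants are
#' identifiable from length-versus-time data, so the canonical
#' parameterization is by those ratios:
#'
#' \describe{
#'   \item{\code{l0}}{rest length of one elastic unit (um).}
#'   \item{\code{n0}}{initial number of units in series (integer >= 1).}
#'   \item{\code{stretch}}{steady-state elastic stretch per unit,
#'     \eqn{\sigma/k} (um).}
#'   \item{\code{tau}}{viscoelastic characteristic time
#'     \eqn{\tau = \eta_{KV}/k} (min).}
#'   \item{\code{period}}{polymerization period \eqn{p = l_0 \eta_M/\sigma}
#'     (min). \code{Inf} encodes "no plasticity": the ratchet model then
#'     never adds a unit and the Maxwell dashpot never flows.}
#' }
#'
#' Raw mechanical constants (traction \code{sigma}, stiffness \code{k},
#' viscosities \code{eta_kv}, \code{eta_m}) can be supplied instead via
#' [material_params_raw()]; the ratios are then derived and the raw values
#' kept for reference. Two raw parameterizations with equal ratios produce
#' identical trajectories.
#'
#' @param l0 rest length of one elastic unit (um), > 0.
#' @param stretch steady-state elastic stretch per unit sigma/k (um), >= 0.
#' @param tau viscoelastic characteristic time eta_KV/k (min), > 0.
#' @param period polymerization period p = l0*eta_M/sigma (min), > 0;
#'   default \code{Inf} (purely viscoelastic).
#' @param n0 initial unit count, integer >= 1; default 1.
#' @param raw optional named list of raw constants (internal use).
#'
#' @return An object of class \code{"material_params"}.
#' @seealso [material_params_raw()], [traction_schedule()]
#' @examples
#' material_params(l0 = 20, stretch = 40, tau = 5)           # aggregate KV body
#' material_params(l0 = 0.3, stretch = 0.1, tau = 5,
#'                 period = 20, n0 = 20)                     # ratchet cell
#' @export
material_params <- function(l0, stretch, tau, period = Inf, n0 = 1L,
                            raw = NULL) {
  stopifnot(is.numeric(l0), is.numeric(stretch), is.numeric(tau),
            is.numeric(period), is.numeric(n0),
            length(l0) == 1L, length(stretch) == 1L, length(tau) == 1L,
            length(period) == 1L, length(n0) == 1L)
  if (is.na(l0) || is.nan(l0) || l0 <= 0)
    stop("'l0' must be a positive finite length (um)")
  if (!is.finite(stretch) || stretch < 0)
    stop("'stretch' (sigma/k) must be finite and >= 0")
  if (!is.finite(tau) || tau <= 0)
    stop("'tau' (eta_KV/k) must be a positive finite time (min)")
  if (is.na(period) || period <= 0)
    stop("'period' must be > 0 (use Inf for no plasticity)")
  if (!is.finite(n0) || n0 < 1 || n0 != round(n0))
    stop("'n0' must be an integer >= 1")
  structure(
    list(l0 = as.numeric(l0), stretch = as.numeric(stretch),
         tau = as.numeric(tau), period = as.numeric(period),
         n0 = as.integer(n0), raw = raw),
    class = "material_params")
}

#' Construct material parameters from raw mechanical constants
#'
#' Convenience constructor taking traction, stiffness and viscosities in
#' arbitrary consistent force units; the identifiable ratios are derived as
#' \code{stretch = sigma/k}, \code{tau = eta_kv/k},
#' \code{period = l0*eta_m/sigma}.
#'
#' @param sigma constant traction (arbitrary force units), >= 0.
#' @param k spring stiffness (force/um), > 0.
#' @param eta_kv parallel (Kelvin-Voigt) viscosity (force*min/um), > 0.
#' @param eta_m series dashpot viscosity; \code{Inf} (default) disables flow.
#' @inheritParams material_params
#' @return A \code{"material_params"} object carrying the raw constants.
#' @export
material_params_raw <- function(sigma, k, eta_kv, l0, eta_m = Inf, n0 = 1L) {
  stopifnot(is.numeric(sigma), is.numeric(k), is.numeric(eta_kv),
            is.numeric(eta_m))
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be finite and >= 0")
  if (!is.finite(k) || k <= 0) stop("'k' must be positive and finite")
  if (!is.finite(eta_kv) || eta_kv <= 0) stop("'eta_kv' must be positive")
  if (is.na(eta_m) || eta_m <= 0) stop("'eta_m' must be > 0 (Inf allowed)")
  period <- if (sigma == 0) Inf else l0 * eta_m / sigma
  material_params(l0 = l0, stretch = sigma / k, tau = eta_kv / k,
                  period = period, n0 = n0,
                  raw = list(sigma = sigma, k = k, eta_kv = eta_kv,
                             eta_m = eta_m))
}

#' @export
print.material_params <- function(x, ...) {
  cat("Material parameters (", x$n0, " unit", if (x$n0 > 1) "s", "):\n",
      sep = "")
  cat(sprintf("  l0 = %g um, stretch (sigma/k) = %g um, tau = %g min, period = %g min\n",
              x$l0, x$stretch, x$tau, x$period))
  cat(sprintf("  aggregate: rest %g um, stretch amplitude %g um\n",
              rest_length_agg(x), stretch_agg(x)))
  invisible(x)
}

# aggregate (whole-chain) rest length n0*l0 (um)
#' Aggregate rest length and stretch amplitude
#'
#' The chain of \code{n0} identical units has aggregate rest length
#' \code{n0*l0} and aggregate steady-state stretch \code{n0*stretch};
#' the closed-form solutions for the whole tissue use these.
#'
#' @param params a [material_params()] object.
#' @return A length (um).
#' @export
rest_length_agg <- function(params) params$n0 * params$l0

#' @rdname rest_length_agg
#' @export
stretch_agg <- function(params) params$n0 * params$stretch

#' Traction schedule: constant pull released at a given time
#'
#' The only loading considered is a constant traction applied from t = 0 and
#' dropped to zero instantaneously at \code{t_release} (laser ablation or
#' detachment). \code{t_release = Inf} means the traction is never released.
#'
#' @param t_release release time (min), >= 0; default \code{Inf}.
#' @return An object of class \code{"traction_schedule"}.
#' @export
traction_schedule <- function(t_release = Inf) {
  stopifnot(is.numeric(t_release), length(t_release) == 1L)
  if (is.na(t_release) || t_release < 0)
    stop("'t_release' must be >= 0 (Inf = never released)")
  structure(list(t_release = as.numeric(t_release)),
            class = "traction_schedule")
}

#' @export
print.traction_schedule <- function(x, ...) {
  cat("Traction schedule: constant traction, release at t =",
      x$t_release, "min\n")
  invisible(x)
}

# internal: validate the (t, schedule, params) triple shared by all models
check_model_args <- function(t, schedule, params) {
  if (!inherits(params, "material_params"))
    stop("'params' must be a material_params object")
  if (!inherits(schedule, "traction_schedule"))
    stop("'schedule' must be a traction_schedule object")
  if (!is.numeric(t) || any(is.na(t)) || any(!is.finite(t)))
    stop("'t' must be finite numeric time(s) in minutes")
  if (any(t < 0)) stop("'t' must be >= 0")
  invisible(TRUE)
}

#' Model kinds
#'
#' String constants naming the three constitutive models:
#' \code{"KELVIN_VOIGT"} (spring and dashpot in parallel; deformation fully
#' recovers), \code{"MAXWELL_KV"} (series dashpot added; viscous flow is
#' permanent), \code{"RATCHET"} (new viscoelastic units added at constant
#' rate under traction; rest length grows permanently).
#'
#' @return Character vector of the three model names.
#' @export
model_kinds <- function() c("KELVIN_VOIGT", "MAXWELL_KV", "RATCHET")

match_model_kind <- function(model_kind) {
  match.arg(toupper(model_kind), model_kinds())
}
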