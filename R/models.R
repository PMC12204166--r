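#' Kelvin-Voigt length under piecewise-constant traction
#'
#' Closed-form creep-and-recovery solution for a Kelvin-Voigt body (spring
#' and dashpot in parallel) treated as one aggregate unit of rest length
#' \code{n0*l0} with aggregate stretch amplitude \code{n0*stretch}.
#'
#' Under constant traction (t <= t_release):
#' \deqn{L(t) = n_0 l_0 + n_0 (\sigma/k)\,(1 - e^{-t/\tau})}
#' and from the moment traction is released:
#' \deqn{L(t) = n_0 l_0 + L_{stretch}\, e^{-(t - t_{rel})/\tau},\quad
#'       L_{stretch} = n_0 (\sigma/k)(1 - e^{-t_{rel}/\tau}).}
#' The solution is continuous at the release time and relaxes back to the
#' rest length: a Kelvin-Voigt material keeps no permanent deformation.
#'
#' @param t time(s) since traction onset (min), >= 0. Vectorized.
#' @param schedule a [traction_schedule()].
#' @param params a [material_params()].
#' @return Length(s) in um, same length as \code{t}.
#' @export
kv_length <- function(t, schedule, params) {
  check_model_args(t, schedule, params)
  rest <- rest_length_agg(params)
  A <- stretch_agg(params)
  tau <- params$tau
  tr <- schedule$t_release
  under <- t <= tr
  out <- numeric(length(t))
  out[under] <- rest + A * (1 - exp(-t[under] / tau))
  if (any(!under)) {
    ls <- A * (1 - exp(-tr / tau))
    out[!under] <- rest + ls * exp(-(t[!under] - tr) / tau)
  }
  out
}

# sigma/eta_M expressed as a length rate (um/min), from p = l0*eta_M/sigma
flow_rate <- function(params) params$l0 / params$period

#' Mixed Maxwell/Kelvin-Voigt length under piecewise-constant traction
#'
#' A dashpot of viscosity \eqn{\eta_M} in series with the Kelvin-Voigt body.
#' Under constant traction the same traction acts on both elements, so
#' \deqn{L(t) = n_0 l_0 + (\sigma/\eta_M)\, t +
#'       n_0(\sigma/k)(1 - e^{-t/\tau})}
#' and after release the viscous flow is retained permanently:
#' \deqn{L(t) = n_0 l_0 + l_{deform} + L_{stretch} e^{-(t-t_{rel})/\tau},
#'       \quad l_{deform} = (\sigma/\eta_M)\, t_{rel}.}
#' The flow rate \eqn{\sigma/\eta_M} is carried by the ratio
#' parameterization as \code{l0/period}.
#'
#' @inheritParams kv_length
#' @return Length(s) in um.
#' @export
maxwellkv_length <- function(t, schedule, params) {
  check_model_args(t, schedule, params)
  if (!is.finite(params$period))
    stop("infinite eta_M (period = Inf): the series dashpot never flows; ",
         "use kv_length() for a pure Kelvin-Voigt body")
  rest <- rest_length_agg(params)
  A <- stretch_agg(params)
  tau <- params$tau
  v <- flow_rate(params)
  tr <- schedule$t_release
  under <- t <= tr
  out <- numeric(length(t))
  out[under] <- rest + v * t[under] + A * (1 - exp(-t[under] / tau))
  if (any(!under)) {
    ls <- A * (1 - exp(-tr / tau))
    out[!under] <- rest + v * tr + ls * exp(-(t[!under] - tr) / tau)
  }
  out
}

# number of units added by time t under traction (floor semantics,
# addition at exact multiples of p inclusive; eps guards float division)
ratchet_n_added <- function(t, params) {
  if (!is.finite(params$period)) return(rep(0L, length(t)))
  as.integer(floor(t / params$period + 1e-9))
}

# recoverable stretch held by a ratchet chain at time t under traction:
# n0*s*(1 - e^(-t/tau)) + sum_{i=1}^{m} s*(1 - e^(-(t - i p)/tau)),
# the geometric sum evaluated in closed form (no overflow for large t/tau)
ratchet_stretch_under <- function(t, params) {
  s <- params$stretch; tau <- params$tau; p <- params$period
  m <- ratchet_n_added(t, params)
  base <- params$n0 * s * (1 - exp(-t / tau))
  added <- numeric(length(t))
  pos <- m > 0
  if (any(pos)) {
    r <- exp(-p / tau)
    tailsum <- exp(-(t[pos] - m[pos] * p) / tau) * (1 - r^m[pos]) / (1 - r)
    added[pos] <- s * (m[pos] - tailsum)
  }
  base + added
}

#' Ratchet-polymerization length under piecewise-constant traction
#'
#' The viscoplastic model: a chain of \code{n0} Kelvin-Voigt units to which
#' new units (rest length \code{l0}) are added at constant rate, one per
#' polymerization period \code{p}, for as long as traction is applied.
#' Under traction,
#' \deqn{L(t) = n_0 l_0 + n_0(\sigma/k)(1 - e^{-t/\tau}) +
#'   \sum_{i=1}^{\lfloor t/p \rfloor}
#'   \left[ l_0 + (\sigma/k)(1 - e^{-(t - i p)/\tau}) \right].}
#' After release the unit count freezes, the recoverable stretch decays with
#' the common time constant \eqn{\tau}, and the grown rest length
#' \eqn{(n_0 + \lfloor t_{rel}/p \rfloor)\, l_0} is retained: deformation is
#' permanent in proportion to the units added (ratchet plasticity).
#'
#' With \code{period = Inf} no unit is ever added and the model reduces
#' exactly to [kv_length()].
#'
#' @inheritParams kv_length
#' @return A list with numeric vectors \code{length_um} and integer
#'   \code{n_units} (unit count at each time).
#' @export
ratchet_length <- function(t, schedule, params) {
  check_model_args(t, schedule, params)
  tau <- params$tau
  tr <- schedule$t_release
  under <- t <= tr
  len <- numeric(length(t))
  n_units <- integer(length(t))
  m <- ratchet_n_added(pmin(t, tr), params)
  n_units <- params$n0 + m
  len[under] <- (params$n0 + m[under]) * params$l0 +
    ratchet_stretch_under(t[under], params)
  if (any(!under)) {
    m_rel <- ratchet_n_added(tr, params)
    rest_rel <- (params$n0 + m_rel) * params$l0
    ls <- ratchet_stretch_under(tr, params)
    len[!under] <- rest_rel + ls * exp(-(t[!under] - tr) / tau)
  }
  list(length_um = len, n_units = n_units)
}

#' Evaluate any of the three models
#'
#' Dispatch wrapper returning length only; see [kv_length()],
#' [maxwellkv_length()], [ratchet_length()].
#'
#' @param model_kind one of [model_kinds()].
#' @inheritParams kv_length
#' @return Length(s) in um.
#' @export
model_length <- function(model_kind, t, schedule, params) {
  switch(match_model_kind(model_kind),
         KELVIN_VOIGT = kv_length(t, schedule, params),
         MAXWELL_KV   = maxwellkv_length(t, schedule, params),
         RATCHET      = ratchet_length(t, schedule, params)$length_um)
}

#' Decompose the state at traction release
#'
#' Splits the length at the moment of release into the permanently retained
#' part and the recoverable stretch:
#' \itemize{
#'   \item Kelvin-Voigt: \code{l_deform = 0}; everything above the rest
#'     length recoils.
#'   \item Maxwell/KV: \code{l_deform = (sigma/eta_M) * t_release} (viscous
#'     flow).
#'   \item Ratchet: \code{l_deform = floor(t_release/p) * l0} (rest length
#'     grown by unit addition).
#' }
#' In every case \code{rest_length + l_stretch} equals the length at the
#' moment of release, and \code{rest_length} is the length after full
#' relaxation.
#'
#' @inheritParams model_length
#' @return A list of class \code{"release_decomposition"} with fields
#'   \code{rest_length}, \code{l_stretch}, \code{l_deform},
#'   \code{length_at_release}, \code{n_units} (um; count).
#' @export
release_decomposition <- function(model_kind, schedule, params) {
  model_kind <- match_model_kind(model_kind)
  check_model_args(0, schedule, params)
  tr <- schedule$t_release
  if (!is.finite(tr))
    stop("release_decomposition needs a finite t_release")
  rest0 <- rest_length_agg(params)
  A <- stretch_agg(params)
  if (model_kind == "KELVIN_VOIGT") {
    l_deform <- 0
    l_stretch <- A * (1 - exp(-tr / params$tau))
    n_units <- params$n0
  } else if (model_kind == "MAXWELL_KV") {
    if (!is.finite(params$period))
      stop("MAXWELL_KV needs a finite period (eta_M)")
    l_deform <- flow_rate(params) * tr
    l_stretch <- A * (1 - exp(-tr / params$tau))
    n_units <- params$n0
  } else {
    m <- ratchet_n_added(tr, params)
    l_deform <- m * params$l0
    l_stretch <- ratchet_stretch_under(tr, params)
    n_units <- params$n0 + m
  }
  structure(
    list(rest_length = rest0 + l_deform, l_stretch = l_stretch,
         l_deform = l_deform,
         length_at_release = rest0 + l_deform + l_stretch,
         n_units = as.integer(n_units), model_kind = model_kind),
    class = "release_decomposition")
}

#' @export
print.release_decomposition <- function(x, ...) {
  cat(sprintf(
    "%s release: length %0.4g um = rest %0.4g (deform %0.4g) + stretch %0.4g um\n",
    x$model_kind, x$length_at_release, x$rest_length, x$l_deform,
    x$l_stretch))
  invisible(x)
}

#' Theoretical recoil ratio as a function of pre-ablation length
#'
#' The recoil ratio (recoil length over length before ablation, in the
#' fully-relaxed, \eqn{t_{rel} \gg \tau} regime) depends on pre-ablation
#' length in a model-specific way, which is what discriminates the three
#' material classes:
#' \itemize{
#'   \item Kelvin-Voigt: ratio \eqn{= 1 - n_0 l_0 / l}, strictly increasing
#'     in \eqn{l} (longer cells are proportionally more stretched).
#'   \item Maxwell/KV: stretch saturates at \eqn{n_0 \sigma/k} while viscous
#'     flow grows, so ratio \eqn{= n_0(\sigma/k)/l}, strictly decreasing.
#'   \item Ratchet: every unit carries the same stretch fraction, so ratio
#'     \eqn{= (\sigma/k)/(l_0 + \sigma/k)}, independent of length.
#' }
#'
#' @param model_kind one of [model_kinds()].
#' @param length_before pre-ablation length(s) (um). Vectorized.
#' @param params a [material_params()].
#' @return Recoil ratio(s) in [0, 1).
#' @export
recoil_ratio_theory <- function(model_kind, length_before, params) {
  model_kind <- match_model_kind(model_kind)
  stopifnot(is.numeric(length_before), all(is.finite(length_before)))
  rest <- rest_length_agg(params)
  A <- stretch_agg(params)
  switch(model_kind,
    KELVIN_VOIGT = {
      if (any(length_before < rest))
        stop("length_before below the rest length ", rest, " um")
      1 - rest / length_before
    },
    MAXWELL_KV = {
      if (any(length_before < rest + A))
        stop("length_before below rest + saturated stretch (",
             rest + A, " um): not in the t >> tau flow regime")
      A / length_before
    },
    RATCHET = {
      if (any(length_before < rest))
        stop("length_before below the rest length ", rest, " um")
      rep(params$stretch / (params$l0 + params$stretch),
          length(length_before))
    })
}

#' Theoretical laser-ablation proxies
#'
#' A retraction after ablation follows Kelvin-Voigt dynamics, and three
#' scalar proxies summarize it: the initial recoil velocity (tension over
#' viscosity, \eqn{\sigma/\eta_{KV}} as a length rate), the characteristic
#' time (viscosity over stiffness, \eqn{\tau}), and the total recoil
#' (tension over stiffness, \eqn{\sigma/k}). They satisfy the identity
#' \code{initial_recoil * char_time = total_recoil} exactly.
#'
#' @param params a [material_params()].
#' @param t_release time under traction before release (min); \code{Inf}
#'   (default) means the stretch is fully developed.
#' @return A list with \code{initial_recoil} (um/min), \code{char_time}
#'   (min), \code{total_recoil} (um) and logical \code{defined} (FALSE when
#'   there is no stretch to recoil, in which case \code{char_time} is NA).
#' @export
ablation_proxies_theory <- function(params, t_release = Inf) {
  if (!inherits(params, "material_params"))
    stop("'params' must be a material_params object")
  if (t_release < 0) stop("'t_release' must be >= 0")
  s_rel <- stretch_agg(params) * (1 - exp(-t_release / params$tau))
  if (s_rel <= 0) {
    return(list(initial_recoil = 0, char_time = NA_real_, total_recoil = 0,
                defined = FALSE))
  }
  list(initial_recoil = s_rel / params$tau, char_time = params$tau,
       total_recoil = s_rel, defined = TRUE)
}
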