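#' Numerically integrate a constitutive model
#'
#' Brute-force fixed-step integration of the governing equations, used as an
#' independent check on the closed-form solutions. Between breakpoints
#' (traction release, ratchet unit additions, requested output times) each
#' model reduces to the linear relaxation ODE
#' \eqn{dL/dt = (L_{target} - L)/\tau} (plus a constant drift for the
#' Maxwell flow), advanced with classical fourth-order Runge-Kutta
#' substeps. Ratchet unit additions are applied as exact +l0 jumps at
#' multiples of the polymerization period (inclusive), matching the closed
#' form's floor semantics.
#'
#' The requested grid must resolve the dynamics: maximum spacing at most
#' tau/50 and, for a finite period, p/20. (Internally the integrator
#' substeps finer; the requirement is about not aliasing the output.)
#'
#' @param model_kind one of [model_kinds()].
#' @param schedule a [traction_schedule()].
#' @param params a [material_params()].
#' @param grid strictly increasing output times (min), first >= 0.
#' @param L_init optional initial length (um) of the elastic element at
#'   t = 0; default is the model-consistent unstretched start (aggregate
#'   rest length). Lets one integrate, e.g., relaxation from a pre-stretched
#'   state under zero traction.
#' @return A trajectory tibble (see [model_trajectory()]).
#' @export
integrate_numeric <- function(model_kind, schedule, params, grid,
                              L_init = NULL) {
  model_kind <- match_model_kind(model_kind)
  if (!inherits(params, "material_params"))
    stop("'params' must be a material_params object")
  if (!inherits(schedule, "traction_schedule"))
    stop("'schedule' must be a traction_schedule object")
  if (!is.numeric(grid) || length(grid) < 2L || any(!is.finite(grid)))
    stop("'grid' must be a finite numeric vector of length >= 2")
  if (grid[1] < 0 || any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing with first time >= 0")
  h_max <- max(diff(grid))
  h_req <- params$tau / 50
  if (is.finite(params$period)) h_req <- min(h_req, params$period / 20)
  if (h_max > h_req * (1 + 1e-9))
    stop(sprintf(
      "grid too coarse: max spacing %g min, need <= %g min (tau/50 and p/20)",
      h_max, h_req))
  if (model_kind == "MAXWELL_KV" && !is.finite(params$period))
    stop("MAXWELL_KV needs a finite period (eta_M)")

  rest0 <- rest_length_agg(params)
  A <- stretch_agg(params)
  tau <- params$tau
  tr <- schedule$t_release
  p <- params$period

  # breakpoints: output times + release + (ratchet) addition instants
  t_end <- grid[length(grid)]
  events <- grid
  if (is.finite(tr) && tr <= t_end) events <- c(events, tr)
  add_times <- numeric(0)
  if (model_kind == "RATCHET" && is.finite(p)) {
    t_stop_add <- min(t_end, tr)
    if (t_stop_add >= p) add_times <- seq(p, t_stop_add + 1e-9, by = p)
    events <- c(events, add_times)
  }
  events <- sort(unique(signif(c(0, events), 13)))

  h_int <- tau / 200
  rk4_relax <- function(L, target, h) {
    f <- function(x) (target - x) / tau
    k1 <- f(L); k2 <- f(L + h / 2 * k1); k3 <- f(L + h / 2 * k2)
    k4 <- f(L + h * k3)
    L + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  advance <- function(L, target, span) {
    nsub <- max(1L, ceiling(span / h_int))
    h <- span / nsub
    for (i in seq_len(nsub)) L <- rk4_relax(L, target, h)
    L
  }

  n <- params$n0
  L_el <- if (is.null(L_init)) rest0 else as.numeric(L_init)
  L_flow <- 0
  res_len <- numeric(length(events))
  res_n <- integer(length(events))

  for (k in seq_along(events)) {
    tcur <- events[k]
    if (k > 1L) {
      t_prev <- events[k - 1L]
      under <- t_prev < tr  # release time itself is a breakpoint
      target <- switch(model_kind,
        KELVIN_VOIGT = if (under) rest0 + A else rest0,
        MAXWELL_KV   = if (under) rest0 + A else rest0,
        RATCHET      = n * (params$l0 + if (under) params$stretch else 0))
      if (model_kind == "MAXWELL_KV" && under)
        L_flow <- L_flow + flow_rate(params) * (tcur - t_prev)
      L_el <- advance(L_el, target, tcur - t_prev)
    }
    if (model_kind == "RATCHET" && length(add_times) &&
        tcur <= tr + 1e-12 && any(abs(add_times - tcur) < 1e-9)) {
      n <- n + 1L
      L_el <- L_el + params$l0
    }
    res_len[k] <- L_el + L_flow
    res_n[k] <- n
  }

  keep <- vapply(grid, function(g) which.min(abs(events - g)), integer(1))
  new_trajectory(model_kind, grid, res_len[keep],
                 phase = ifelse(grid <= tr, "under_traction", "released"),
                 n_units = res_n[keep], schedule = schedule, params = params)
}
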