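#' Build a trajectory tibble
#'
#' Internal constructor shared by the closed-form evaluator and the numeric
#' integrator. A trajectory is a tidy tibble with columns \code{model},
#' \code{time_min}, \code{length_um}, \code{phase}
#' (\code{"under_traction"}/\code{"released"}) and \code{n_units}; the
#' generating parameters and schedule ride along as attributes.
#'
#' @keywords internal
new_trajectory <- function(model_kind, times, lengths, phase, n_units,
                           schedule, params, embryo_id = NA_character_) {
  out <- tibble::tibble(
    model = model_kind,
    time_min = as.numeric(times),
    length_um = as.numeric(lengths),
    phase = phase,
    n_units = as.integer(n_units))
  if (!is.na(embryo_id)) out <- tibble::add_column(out, embryo_id = embryo_id,
                                                   .before = 1)
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  out
}

#' Closed-form trajectory of a constitutive model
#'
#' Evaluates the chosen model's closed-form solution on a time grid and
#' returns a tidy trajectory table.
#'
#' @param model_kind one of [model_kinds()].
#' @param schedule a [traction_schedule()].
#' @param params a [material_params()].
#' @param times numeric vector of times (min), strictly increasing, >= 0.
#' @return A tibble with columns \code{model}, \code{time_min},
#'   \code{length_um}, \code{phase}, \code{n_units}.
#' @examples
#' p <- material_params(l0 = 20, stretch = 40, tau = 5)
#' model_trajectory("KELVIN_VOIGT", traction_schedule(), p, 0:60)
#' @export
model_trajectory <- function(model_kind, schedule, params, times) {
  model_kind <- match_model_kind(model_kind)
  check_model_args(times, schedule, params)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (model_kind == "RATCHET") {
    r <- ratchet_length(times, schedule, params)
    len <- r$length_um
    n_units <- r$n_units
  } else {
    len <- model_length(model_kind, times, schedule, params)
    n_units <- rep(params$n0, length(times))
  }
  new_trajectory(model_kind, times, len,
                 phase = ifelse(times <= schedule$t_release,
                                "under_traction", "released"),
                 n_units = n_units, schedule = schedule, params = params)
}

#' Read and write tidy trajectory tables
#'
#' Trajectories are exchanged as tidy CSV with columns
#' (\code{model}, \code{time_min}, \code{length_um}, \code{phase},
#' \code{n_units}), optionally preceded by \code{embryo_id}.
#'
#' @param trajectory a trajectory tibble.
#' @param path file path.
#' @return \code{read_trajectory_csv} returns a tibble;
#'   \code{write_trajectory_csv} returns \code{path} invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(trajectory, path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize parameters and a schedule to/from JSON
#'
#' @param params a [material_params()]; @param schedule a
#'   [traction_schedule()]; @param path file path.
#' @return \code{read_params_json} returns a list with elements
#'   \code{params} and \code{schedule}.
#' @export
write_params_json <- function(params, schedule, path) {
  x <- list(
    params = list(l0 = params$l0, stretch = params$stretch,
                  tau = params$tau, period = params$period, n0 = params$n0),
    schedule = list(t_release = schedule$t_release))
  # Inf is not valid JSON; encode as the string "Inf"
  x <- rapply(x, function(v) if (is.numeric(v) && is.infinite(v)) "Inf" else v,
              how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (identical(v, "Inf")) Inf else as.numeric(v)
  list(params = material_params(l0 = num(x$params$l0),
                                stretch = num(x$params$stretch),
                                tau = num(x$params$tau),
                                period = num(x$params$period),
                                n0 = as.integer(x$params$n0)),
       schedule = traction_schedule(num(x$schedule$t_release)))
}
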