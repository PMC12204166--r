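#' Compare elastic and plastic elongation under identical constant traction
#'
#' Simulates the Kelvin-Voigt and ratchet-polymerization models side by
#' side with the control tissue constants (rest 20 um, elastic amplitude
#' 40 um, tau = 5 min, plastic rate 0.2 um/min), both starting unstretched,
#' under never-released traction. The two curves share the primary elastic
#' step; the Kelvin-Voigt curve then plateaus at rest + amplitude while the
#' ratchet curve keeps elongating linearly.
#'
#' @param t_max simulation end time (min), default 300.
#' @param dt output grid step (min), default 0.5.
#' @param preset tissue-scale preset supplying the constants; default
#'   \code{make_preset("control", "tissue")}.
#' @param late_window window (min) for the late-slope regression; default
#'   \code{c(100, t_max)}.
#' @param out_dir optional directory; when given, writes
#'   \code{compare_models_trajectories.csv},
#'   \code{compare_models_summary.json} and the resolved
#'   \code{compare_models_config.json} there.
#' @return A list with \code{trajectories} (tibble, both models) and
#'   \code{summary} (tibble: model, late slope, KV asymptote).
#' @export
compare_models <- function(t_max = 300, dt = 0.5,
                           preset = make_preset("control", "tissue"),
                           late_window = c(100, t_max), out_dir = NULL) {
  stopifnot(inherits(preset, "genotype_preset"))
  times <- seq(0, t_max, by = dt)
  sched <- traction_schedule(Inf)
  p_ratchet <- preset$params
  if (!is.finite(p_ratchet$period))
    stop("compare_models needs a plastic (finite-period) preset")
  p_kv <- material_params(l0 = p_ratchet$l0, stretch = p_ratchet$stretch,
                          tau = p_ratchet$tau, period = Inf,
                          n0 = p_ratchet$n0)
  tr_kv <- model_trajectory("KELVIN_VOIGT", sched, p_kv, times)
  tr_ra <- model_trajectory("RATCHET", sched, p_ratchet, times)
  slope_of <- function(tr) {
    elongation_speed(tr, window = late_window)$speed_um_per_min
  }
  summary <- tibble::tibble(
    model = c("KELVIN_VOIGT", "RATCHET"),
    late_slope_um_per_min = c(slope_of(tr_kv), slope_of(tr_ra)),
    asymptote_um = c(rest_length_agg(p_kv) + stretch_agg(p_kv), NA_real_))
  trajectories <- rbind(tr_kv, tr_ra)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(trajectories,
                     file.path(out_dir, "compare_models_trajectories.csv"))
    jsonlite::write_json(summary,
                         file.path(out_dir, "compare_models_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(t_max = t_max, dt = dt, preset = preset$name,
           scale = preset$scale, late_window = late_window),
      file.path(out_dir, "compare_models_config.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(trajectories = trajectories, summary = summary)
}

#' Parameter-recovery benchmark: simulate, fit, tabulate bias and RMSE
#'
#' End-to-end check that the fitting stage recovers the generating
#' parameters under the preset's noise model. Per replicate seed, generates
#' (a) n retraction curves from the Kelvin-Voigt tissue body with the
#' control constants and fits each exponential recoil (recovering tau and
#' the stretch amplitude), and (b) n control-ratchet trajectories and fits
#' the per-embryo elongation speed (recovering the plastic rate). Reports
#' per-seed means plus overall bias and RMSE against the known truths.
#'
#' @param seed base integer seed; replicate k uses \code{seed + k}.
#' @param n curves/embryos per replicate (>= 3), default 20.
#' @param n_seeds number of replicate seeds, default 10.
#' @param noise_sd,cv noise and variability overriding the preset
#'   defaults.
#' @param out optional path for a machine-readable JSON report.
#' @return A list with \code{per_seed} (tibble) and \code{summary}
#'   (tibble: parameter, truth, mean estimate, bias, relative bias, RMSE).
#' @export
recover_benchmark <- function(seed, n = 20L, n_seeds = 10L, noise_sd = 0.5,
                              cv = 0.15, out = NULL) {
  if (n < 3) stop("need n >= 3 curves per replicate")
  ctrl <- make_preset("control", "tissue", noise_sd = noise_sd, cv = cv)
  kv <- ctrl
  kv$model_kind <- "KELVIN_VOIGT"
  kv$params <- material_params(l0 = ctrl$params$l0,
                               stretch = ctrl$params$stretch,
                               tau = ctrl$params$tau, period = Inf,
                               n0 = ctrl$params$n0)
  t_release <- 60
  truth <- c(tau = ctrl$params$tau,
             # the stretch developed by the time of release, the quantity
             # the exponential fit actually estimates
             stretch = stretch_agg(ctrl$params) *
               (1 - exp(-t_release / ctrl$params$tau)),
             slope = (ctrl$params$l0 + ctrl$params$stretch) /
               ctrl$params$period)
  per_seed <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    sp_abl <- experiment_spec(n = n, sampling_interval = 0.25,
                              duration = 30, t_release = t_release,
                              seed = seed + k)
    abl <- simulate_ablation(sp_abl, kv)
    fits <- lapply(split(abl$curves, abl$curves$cell_id),
                   fit_exponential_recoil)
    sp_tr <- experiment_spec(n = n, sampling_interval = 1, duration = 150,
                             seed = seed + 1000L + k)
    traj <- simulate_trajectories(sp_tr, ctrl, equilibrate = TRUE)
    sp <- elongation_speed(traj)
    per_seed[[k]] <- tibble::tibble(
      seed = seed + k,
      tau_hat = mean(vapply(fits, `[[`, numeric(1), "tau_fit")),
      stretch_hat = mean(vapply(fits, `[[`, numeric(1), "stretch_length")),
      slope_hat = mean(sp$speed_um_per_min),
      converged = mean(vapply(fits, `[[`, logical(1), "converged")))
  }
  per_seed <- do.call(rbind, per_seed)
  est <- cbind(tau = per_seed$tau_hat, stretch = per_seed$stretch_hat,
               slope = per_seed$slope_hat)
  mean_est <- colMeans(est)[names(truth)]
  rmse <- sqrt(colMeans((est - rep(truth, each = nrow(est)))^2))[
    names(truth)]
  summary <- tibble::tibble(
    parameter = names(truth),
    truth = unname(truth),
    mean_estimate = unname(mean_est),
    bias = unname(mean_est - truth),
    rel_bias = unname((mean_est - truth) / truth),
    rmse = unname(rmse))
  if (!is.null(out))
    jsonlite::write_json(list(summary = summary, per_seed = per_seed,
                              n = n, n_seeds = n_seeds, seed = seed),
                         out, auto_unbox = TRUE, digits = NA)
  list(per_seed = per_seed, summary = summary)
}

#' Discriminate material class from a recoil-record table
#'
#' Thin orchestration over [recoil_ratio_regression()]: accepts a tibble or
#' a CSV path in the recoil-record dialect, runs the discrimination
#' regression, and optionally writes a labeled JSON report.
#'
#' @param records a data frame or a CSV path (see
#'   [read_recoil_records()]).
#' @param alpha significance level, default 0.05.
#' @param col_map optional column-name mapping for CSV input.
#' @param out optional JSON report path.
#' @return The [recoil_ratio_regression()] result, invisibly when a report
#'   is written.
#' @export
discriminate_records <- function(records, alpha = 0.05, col_map = NULL,
                                 out = NULL) {
  if (is.character(records)) records <- read_recoil_records(records, col_map)
  res <- recoil_ratio_regression(records, alpha = alpha)
  if (!is.null(out)) {
    ci <- res$slope + c(-1, 1) * stats::qt(0.975, df = res$n - 2) *
      res$slope_se
    jsonlite::write_json(
      list(classification = res$classification, slope = res$slope,
           slope_se = res$slope_se, ci95 = ci, p_value = res$p_value,
           n = res$n, n_excluded = res$n_excluded,
           mean_ratio = res$mean_ratio, alpha = res$alpha),
      out, auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
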