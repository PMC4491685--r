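#' Fitting control settings
#'
#' @param multi_start Number of optimizer starts; each start perturbs the
#'   supplied parameter set by a +/-20 percent uniform factor (configurable
#'   via `perturb`). At least 1.
#' @param seed Integer seed for the start perturbations (default 1905).
#' @param reltol Relative change in the objective below which the optimizer
#'   stops (default 1e-10).
#' @param maxit Maximum optimizer iterations per start (default 500).
#' @param perturb Half-width of the uniform multiplicative start
#'   perturbation (default 0.2).
#' @param bounds Named list of length-2 numeric vectors overriding the
#'   default per-parameter box bounds.
#' @param objective `"mean_squared"` (default) or `"mean_absolute"` local
#'   relative residual.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(multi_start = 5, seed = 1905, reltol = 1e-10,
                       maxit = 500, perturb = 0.2, bounds = NULL,
                       objective = c("mean_squared", "mean_absolute")) {
  objective <- match.arg(objective)
  stop_unless(is_scalar_num(multi_start) && multi_start >= 1,
              "`multi_start` must be at least 1")
  stop_unless(is_scalar_num(seed), "`seed` must be an integer")
  stop_unless(is_scalar_num(reltol) && reltol > 0, "`reltol` must be positive")
  stop_unless(is_scalar_num(maxit) && maxit >= 1, "`maxit` must be at least 1")
  stop_unless(is_scalar_num(perturb) && perturb >= 0 && perturb < 1,
              "`perturb` must be in [0, 1)")
  if (!is.null(bounds)) {
    stop_unless(is.list(bounds) && !is.null(names(bounds)) &&
                  all(vapply(bounds, function(b) is.numeric(b) && length(b) == 2L &&
                               b[1] <= b[2], logical(1))),
                "`bounds` must be a named list of increasing length-2 numeric vectors")
  }
  structure(list(multi_start = as.integer(multi_start), seed = as.integer(seed),
                 reltol = reltol, maxit = as.integer(maxit), perturb = perturb,
                 bounds = bounds, objective = objective),
            class = "fit_config")
}

# --- parameter packing ------------------------------------------------------

par_names_general <- function() {
  c("alpha_E", "p_E", "hd_ref_iso",
    "a1", "b1", "a2", "b2", "c2", "d2", "a3", "a4", "b4", "c4",
    "alpha1", "alpha2", "alpha3", "alpha4",
    "sigma1", "sigma2", "sigma3", "sigma4", "q")
}

par_names_ocular <- function() {
  c("hd_iso", "C1", "C2", "C3", "C4",
    "sigma1", "sigma2", "sigma3", "sigma4", "q")
}

#' Flatten a beamline configuration to a named parameter vector
#'
#' The in-water variant has 22 parameters (calibration, apportionment
#' coefficients, attenuation, widths, falloff); the in-air variant has 10
#' (measured isocenter H/D, four scalar fractions, widths, falloff).
#'
#' @param config A [beamline_config()].
#' @return A named numeric vector.
#' @export
config_to_params <- function(config) {
  stop_unless(inherits(config, "beamline_config"), "`config` must be a beamline_config")
  tp <- config$transport
  if (config$geometry$environment == "in_air") {
    app <- config$apportionment
    stats::setNames(c(config$hd_iso, app$C1, app$C2, app$C3, app$C4,
                      tp$sigma, tp$q), par_names_ocular())
  } else {
    cal <- config$calibration
    app <- config$apportionment
    stats::setNames(c(cal$alpha_E, cal$p_E, cal$hd_ref_iso,
                      app$a1, app$b1, app$a2, app$b2, app$c2, app$d2, app$a3,
                      app$a4, app$b4, app$c4, tp$alpha, tp$sigma, tp$q),
                    par_names_general())
  }
}

#' Rebuild a beamline configuration from a named parameter vector
#'
#' Inverse of [config_to_params()]; `template` supplies everything the
#' vector does not carry (geometry, names, reference energy, renormalize
#' flag, energy range).
#'
#' @param par Named numeric vector as produced by [config_to_params()].
#' @param template A [beamline_config()] of the matching variant.
#' @return A [beamline_config()].
#' @export
params_to_config <- function(par, template) {
  stop_unless(inherits(template, "beamline_config"), "`template` must be a beamline_config")
  if (template$geometry$environment == "in_air") {
    stop_unless(identical(sort(names(par)), sort(par_names_ocular())),
                "`par` must carry the 10 in-air parameter names")
    app <- scalar_apportionment(par[["C1"]], par[["C2"]], par[["C3"]], par[["C4"]],
                                renormalize = template$apportionment$renormalize)
    tp <- transport_parameters(alpha = c(0, 0, 0, 0),
                               sigma = unname(par[paste0("sigma", 1:4)]),
                               q = par[["q"]])
    beamline_config(template$name, template$geometry, tp, app,
                    hd_iso = par[["hd_iso"]], energy = template$energy)
  } else {
    stop_unless(identical(sort(names(par)), sort(par_names_general())),
                "`par` must carry the 22 in-water parameter names")
    cal <- energy_calibration(par[["alpha_E"]], par[["p_E"]], par[["hd_ref_iso"]],
                              template$calibration$ref_energy)
    app <- regime_apportionment(par[["a1"]], par[["b1"]], par[["a2"]], par[["b2"]],
                                par[["c2"]], par[["d2"]], par[["a3"]], par[["a4"]],
                                par[["b4"]], par[["c4"]],
                                renormalize = template$apportionment$renormalize,
                                energy_range = template$apportionment$energy_range)
    tp <- transport_parameters(alpha = unname(par[paste0("alpha", 1:4)]),
                               sigma = unname(par[paste0("sigma", 1:4)]),
                               q = par[["q"]])
    beamline_config(template$name, template$geometry, tp, app, calibration = cal)
  }
}

default_bounds <- function(names, user = NULL) {
  tab <- list(
    alpha_E = c(1e-14, 1e-4), p_E = c(0.5, 8), hd_ref_iso = c(1e-8, 1),
    a1 = c(-0.01, 0.01), b1 = c(0, 2),
    a2 = c(0, 2), b2 = c(50, 300), c2 = c(0.5, 100), d2 = c(-0.1, 0.1),
    a3 = c(0, 1), a4 = c(-1e-5, 1e-5), b4 = c(-0.01, 0.01), c4 = c(-0.5, 0.5),
    alpha1 = c(0, 1), alpha2 = c(0, 1), alpha3 = c(0, 1), alpha4 = c(0, 1),
    sigma1 = c(0.5, 1e5), sigma2 = c(0.5, 1e5), sigma3 = c(0.5, 1e5),
    sigma4 = c(0.5, 1e5),
    q = c(0.1, 5), hd_iso = c(1e-8, 1),
    C1 = c(0, 1), C2 = c(0, 1), C3 = c(0, 1), C4 = c(0, 1)
  )
  out <- tab[names]
  if (!is.null(user)) {
    unknown <- setdiff(names(user), names)
    if (length(unknown)) {
      stop("bounds supplied for unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out[names(user)] <- user
  }
  lower <- vapply(out, `[`, numeric(1), 1)
  upper <- vapply(out, `[`, numeric(1), 2)
  list(lower = stats::setNames(lower, names),
       upper = stats::setNames(upper, names))
}

# --- objective and predictions ----------------------------------------------

check_dataset <- function(data, require_positive_hd = TRUE) {
  stop_unless(is.data.frame(data), "`data` must be a data frame")
  needed <- c("x_cm", "y_cm", "z_cm", "energy_MeV", "environment", "hd_Sv_per_Gy")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("invalid data: dataset is empty", call. = FALSE)
  if (require_positive_hd && any(data$hd_Sv_per_Gy <= 0)) {
    stop("invalid data: observed H/D must be strictly positive", call. = FALSE)
  }
  bad_env <- setdiff(unique(data$environment), c("in_water", "in_air"))
  if (length(bad_env)) {
    stop("invalid data: unknown environment token(s): ",
         paste(bad_env, collapse = ", "), call. = FALSE)
  }
  data
}

#' Model predictions for every record of a dose dataset
#'
#' @param config A [beamline_config()].
#' @param data A dose-dataset data frame (see [generate_dataset()] /
#'   [read_dataset()]) whose `environment` matches the configuration.
#' @param quiet Suppress energy-range and clipping warnings (used inside
#'   optimizer objectives).
#' @return Numeric vector of modeled H/D (Sv/Gy), one per record.
#' @export
predict_hd <- function(config, data, quiet = FALSE) {
  model_predict(config, data, quiet = quiet)$hd
}

# Prediction core shared by predict_hd() and the fitting objective; with
# `clip = TRUE` infeasible raw fractions are clipped and their mean squared
# violation returned alongside the predictions.
model_predict <- function(config, data, quiet = FALSE, clip = FALSE) {
  stop_unless(inherits(config, "beamline_config"), "`config` must be a beamline_config")
  data <- check_dataset(data, require_positive_hd = FALSE)
  if (!all(data$environment == config$geometry$environment)) {
    stop("environment mismatch: dataset records do not match the configuration's ",
         config$geometry$environment, " environment", call. = FALSE)
  }
  points <- data[, c("x_cm", "y_cm", "z_cm")]
  if (config$geometry$environment == "in_air") {
    Cmat <- regime_fraction_matrix(rep(1, nrow(data)), config$apportionment,
                                   quiet = quiet, clip = clip)
    res <- hd_eval_core(points, config$geometry, data$energy_MeV,
                        rep(config$hd_iso, nrow(data)), Cmat, config$transport)
  } else {
    E <- data$energy_MeV
    Cmat <- regime_fraction_matrix(E, config$apportionment, quiet = quiet,
                                   clip = clip)
    res <- hd_eval_core(points, config$geometry, E, hd_iso(E, config$calibration),
                        Cmat, config$transport)
  }
  list(hd = res$hd_Sv_per_Gy, violation = attr(Cmat, "violation") %||% 0)
}

#' Local relative residual objective
#'
#' The training objective: the mean over records of the squared (default) or
#' absolute local relative residual `(model - observed) / observed`. It is
#' zero exactly when the model reproduces every record, and is invariant
#' under a common rescaling of all observed and modeled values.
#'
#' @inheritParams predict_hd
#' @param type `"mean_squared"` or `"mean_absolute"`.
#' @return A non-negative scalar.
#' @export
#' @examples
#' cfg <- beamline_preset("ocular_75MeV")
#' ds <- generate_dataset(ocular_positions(), cfg)
#' hd_objective(cfg, ds) # 0: data generated from the model itself
hd_objective <- function(config, data, type = c("mean_squared", "mean_absolute"),
                         quiet = FALSE) {
  type <- match.arg(type)
  data <- check_dataset(data)
  rel <- (predict_hd(config, data, quiet = quiet) - data$hd_Sv_per_Gy) /
    data$hd_Sv_per_Gy
  if (type == "mean_squared") mean(rel^2) else mean(abs(rel))
}

#' Local relative error statistics of a model against a dataset
#'
#' Computes the average and maximum local relative error,
#' `|model - observed| / observed`, in percent, overall and per energy.
#'
#' @inheritParams predict_hd
#' @return A list with `mean_pct`, `max_pct`, and `per_energy` (a tibble with
#'   one row per distinct energy: `energy_MeV`, `n`, `mean_pct`, `max_pct`).
#' @export
error_statistics <- function(config, data) {
  data <- check_dataset(data)
  rel_error_stats(predict_hd(config, data), data$hd_Sv_per_Gy, data$energy_MeV)
}

rel_error_stats <- function(model, obs, energy) {
  rel_pct <- 100 * abs(model - obs) / obs
  per_energy <- tibble::tibble(energy_MeV = energy, rel_pct = rel_pct) |>
    dplyr::group_by(.data$energy_MeV) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_pct = mean(.data$rel_pct),
                     max_pct = max(.data$rel_pct),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$energy_MeV))
  list(mean_pct = mean(rel_pct), max_pct = max(rel_pct), per_energy = per_energy)
}

# --- fitting engine ---------------------------------------------------------

fit_engine <- function(data, start, free, control) {
  stop_unless(inherits(control, "fit_config"), "`control` must be a fit_config()")
  data <- check_dataset(data)
  if (!all(data$environment == start$geometry$environment)) {
    stop("environment mismatch: dataset records do not match the configuration's ",
         start$geometry$environment, " environment", call. = FALSE)
  }
  # the sum-to-unity constraint is always enforced during training
  template <- start
  template$apportionment$renormalize <- TRUE
  par_full <- config_to_params(template)
  stop_unless(is.character(free), "`free` must be a character vector of parameter names")
  unknown <- setdiff(free, names(par_full))
  if (length(unknown)) {
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(free) > 0L && (nrow(data) < 2L || nrow(data) <= length(free))) {
    stop("underdetermined fit: ", nrow(data), " record(s) cannot constrain ",
         length(free), " free parameter(s)", call. = FALSE)
  }
  b <- default_bounds(free, control$bounds)
  # Parameters with strictly positive bounds (scale factors, widths,
  # exponents) are optimized on the log scale: the power-law calibration is
  # linear in log space, which conditions the otherwise strongly correlated
  # (alpha_E, p_E) pair.
  logmask <- b$lower > 0
  to_opt <- function(th) { th[logmask] <- log(th[logmask]); th }
  from_opt <- function(th) { th[logmask] <- exp(th[logmask]); th }
  # Hoist the record columns once; the objective below runs thousands of
  # times and works on plain vectors.
  xv <- data$x_cm; yv <- data$y_cm; zv <- data$z_cm
  Ev <- data$energy_MeV; obs <- data$hd_Sv_per_Gy
  nrec <- nrow(data)
  in_air <- template$geometry$environment == "in_air"
  # Continuous soft-constrained objective: raw regime fractions that dip
  # below zero are clipped and penalized quadratically, so the optimizer is
  # steered back to the feasible region instead of hitting a cliff.
  obj <- function(theta_opt) {
    theta <- from_opt(theta_opt)
    par <- par_full
    par[free] <- theta
    tryCatch({
      config <- params_to_config(par, template)
      Cmat <- regime_fraction_matrix(if (in_air) rep(1, nrec) else Ev,
                                     config$apportionment, quiet = TRUE,
                                     clip = TRUE)
      hdiso <- if (in_air) rep(config$hd_iso, nrec) else hd_iso(Ev, config$calibration)
      total <- hd_eval_values(xv, yv, zv, config$geometry, hdiso, Cmat,
                              config$transport)$total
      rel <- (total - obs) / obs
      base <- if (control$objective == "mean_squared") mean(rel^2) else mean(abs(rel))
      base + 1e4 * (attr(Cmat, "violation") %||% 0)
    },
    error = function(e) 1e10) # unevaluable parameter combination
  }
  start_vals <- par_full[free]
  if (length(free) == 0L) { # no degrees of freedom: evaluate, don't optimize
    runs <- list(list(par = start_vals, value = obj(numeric(0)),
                      convergence = 0L, message = NULL,
                      start = start_vals, start_value = obj(numeric(0))))
    best <- runs[[1]]
    return(finish_fit(best, runs, par_full, free, template, data, b, control))
  }
  starts <- withr::with_seed(control$seed, {
    lapply(seq_len(control$multi_start), function(k) {
      fac <- stats::runif(length(free), 1 - control$perturb, 1 + control$perturb)
      th <- start_vals * fac
      zero <- start_vals == 0
      if (any(zero)) { # a multiplicative perturbation cannot move a zero
        span <- control$perturb * (b$upper[zero] - b$lower[zero]) / 10
        th[zero] <- stats::runif(sum(zero), -span, span)
      }
      pmin(pmax(th, b$lower), b$upper)
    })
  })
  one_optim <- function(th0) {
    th0_opt <- to_opt(th0)
    # characteristic scale: O(1) on the log scale; bound-width based for
    # sign-indefinite coefficients whose magnitudes can be ~1e-7
    parscale <- ifelse(logmask, pmax(abs(th0_opt), 1),
                       pmax(abs(th0_opt), (b$upper - b$lower) / 1e3))
    res <- stats::optim(
      th0_opt, obj, method = "L-BFGS-B",
      lower = to_opt(b$lower), upper = to_opt(b$upper),
      control = list(maxit = control$maxit,
                     factr = control$reltol / .Machine$double.eps,
                     parscale = parscale,
                     ndeps = rep(1e-6, length(th0_opt)))
    )
    res$par <- from_opt(res$par)
    res
  }
  runs <- lapply(starts, function(th0) {
    f0 <- obj(to_opt(th0))
    res <- one_optim(th0)
    if (res$value > f0) { # never accept a step that worsens the start point
      res$par <- th0
      res$value <- f0
      res$convergence <- 1L
    }
    res$start <- th0
    res$start_value <- f0
    res
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  # polish: restart from the incumbent with refreshed parameter scaling (a
  # fresh L-BFGS-B memory often makes further progress); bounded rounds
  for (round in 1:2) {
    polish <- one_optim(best$par)
    if (polish$value < best$value) {
      polish$start <- best$start
      polish$start_value <- best$start_value
      improved <- best$value - polish$value > 0.05 * best$value
      best <- polish
      if (!improved) break
    } else break
  }
  finish_fit(best, runs, par_full, free, template, data, b, control)
}

finish_fit <- function(best, runs, par_full, free, template, data, b, control) {
  par_fit <- par_full
  par_fit[free] <- best$par
  fitted_config <- params_to_config(par_fit, template)
  pred <- model_predict(fitted_config, data, quiet = TRUE, clip = TRUE)
  model_hd <- pred$hd
  residuals <- dplyr::mutate(tibble::as_tibble(data),
                             hd_model_Sv_per_Gy = model_hd,
                             rel_residual = (model_hd - .data$hd_Sv_per_Gy) /
                               .data$hd_Sv_per_Gy)
  stats <- rel_error_stats(model_hd, data$hd_Sv_per_Gy, data$energy_MeV)
  structure(
    list(config = fitted_config, par = par_fit, free = free,
         objective = best$value,
         converged = best$convergence == 0L && pred$violation == 0,
         feasible = pred$violation == 0,
         message = best$message,
         residuals = residuals,
         error_stats = stats,
         starts = tibble::tibble(
           start = seq_along(runs),
           start_objective = vapply(runs, `[[`, numeric(1), "start_value"),
           final_objective = vapply(runs, `[[`, numeric(1), "value"),
           converged = vapply(runs, function(r) r$convergence == 0L, logical(1))),
         bounds = b, control = control, n_obs = nrow(data)),
    class = "hd_fit"
  )
}

#' Fit the general-purpose (in-water, multi-energy) model
#'
#' Trains any subset of the 22 in-water model parameters on a multi-energy
#' dose dataset by bounded quasi-Newton minimization of the local relative
#' residual objective, from multiple perturbed starts. The sum-to-unity
#' constraint on the regime fractions is enforced at every evaluated energy
#' by renormalization inside the model, and the reference isocenter H/D is
#' always held fixed (it enters the calibration only as a product with the
#' scaling factor, so freeing both would be degenerate).
#'
#' Non-convergence within the iteration budget is reported through the
#' `converged` flag on the result, not as an error.
#'
#' @param data A dose-dataset data frame of in-water records spanning the
#'   energies being fitted.
#' @param start A [beamline_config()] (in-water) providing starting values
#'   and fixed parameters.
#' @param free Character vector naming the free parameters (see
#'   [config_to_params()] for names).
#' @param control A [fit_config()].
#' @return An object of class `hd_fit`; see [tidy.hd_fit()] and
#'   [glance.hd_fit()].
#' @export
#' @examples
#' cfg <- beamline_preset("general_purpose_100_250")
#' ds <- generate_dataset(mdacc_grid(), cfg, energies = c(100, 175, 250))
#' fit <- fit_general(ds, cfg, free = "q", control = fit_config(multi_start = 2))
#' glance(fit)
fit_general <- function(data, start, free, control = fit_config()) {
  stop_unless(inherits(start, "beamline_config") &&
                start$geometry$environment == "in_water",
              "`start` must be an in-water beamline_config")
  if ("hd_ref_iso" %in% free) {
    stop("`hd_ref_iso` is always held fixed (identifiable only as a product with alpha_E)",
         call. = FALSE)
  }
  fit_engine(data, start, free, control)
}

#' Fit the single-energy in-air (ocular) model
#'
#' Trains the scalar regime fractions, lateral widths and falloff exponent
#' on in-air records at a single energy. The attenuation coefficients are
#' pinned at zero (no phantom) and the measured isocenter H/D is held fixed.
#'
#' @param data A dose-dataset data frame of in-air records.
#' @param start A [beamline_config()] (in-air) providing starting values and
#'   the measured isocenter H/D.
#' @param free Character vector of free parameter names among `C1`..`C4`,
#'   `sigma1`..`sigma4`, `q`.
#' @param control A [fit_config()].
#' @return An object of class `hd_fit`.
#' @export
fit_ocular <- function(data, start,
                       free = c("C1", "C2", "C3", "C4",
                                "sigma1", "sigma2", "sigma3", "sigma4", "q"),
                       control = fit_config()) {
  stop_unless(inherits(start, "beamline_config") &&
                start$geometry$environment == "in_air",
              "`start` must be an in-air beamline_config")
  if ("hd_iso" %in% free) {
    stop("`hd_iso` is fixed at the measured isocenter value", call. = FALSE)
  }
  fit_engine(data, start, free, control)
}

# --- methods on hd_fit ------------------------------------------------------

#' @export
print.hd_fit <- function(x, ...) {
  cat("<hd_fit>", x$config$name, "\n")
  cat(sprintf("  %d records, %d free parameter(s): %s\n", x$n_obs,
              length(x$free), paste(x$free, collapse = ", ")))
  cat(sprintf("  objective (%s relative residual): %.4g; converged: %s\n",
              x$control$objective, x$objective, x$converged))
  cat(sprintf("  local relative error: mean %.3g%%, max %.3g%%\n",
              x$error_stats$mean_pct, x$error_stats$max_pct))
  est <- signif(x$par[x$free], 5)
  cat("  estimates:", paste(sprintf("%s = %g", names(est), est), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted H/D model
#'
#' @param x An `hd_fit` from [fit_general()] or [fit_ocular()].
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `free`, and (for free parameters) the box bounds used.
#' @export
tidy.hd_fit <- function(x, ...) {
  terms <- names(x$par)
  tibble::tibble(
    term = terms,
    estimate = unname(x$par),
    free = terms %in% x$free,
    lower = ifelse(terms %in% x$free, x$bounds$lower[match(terms, names(x$bounds$lower))], NA_real_),
    upper = ifelse(terms %in% x$free, x$bounds$upper[match(terms, names(x$bounds$upper))], NA_real_)
  )
}

#' Glance at a fitted H/D model
#'
#' @inheritParams tidy.hd_fit
#' @return A one-row tibble: objective value, convergence flag, record and
#'   free-parameter counts, number of starts, seed, and the mean/max local
#'   relative error (percent) on the training data.
#' @export
glance.hd_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, converged = x$converged,
    n_obs = x$n_obs, n_free = length(x$free),
    n_starts = nrow(x$starts), seed = x$control$seed,
    mean_err_pct = x$error_stats$mean_pct, max_err_pct = x$error_stats$max_pct
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
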