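# Two-step parameter identification: combinatorial enzyme-subset screening
# with per-observable weighting grids, then L1-regularized re-estimation
# against the reference parameter set.

#' Observation bundle
#'
#' Time-stamped measurement tables over one feast/famine cycle:
#' concentrations (mM), reaction rates (mM/s) and optionally enrichment (%).
#' @param concentrations data.frame (species, time_s, value, sd)
#' @param fluxes data.frame (reaction, time_s, value, sd), may be empty
#' @param enrichment data.frame (species, time_s, value, sd), may be empty
#' @param provenance `"experimental"` or `"synthetic"`
#' @param cycle_length cycle length (s) the time stamps live in
#' @return an `observation_bundle`
#' @export
observation_bundle <- function(concentrations, fluxes = NULL, enrichment = NULL,
                               provenance = c("synthetic", "experimental"),
                               cycle_length = 400) {
  provenance <- match.arg(provenance)
  empty <- function(key) setNames(
    data.frame(a = character(), time_s = numeric(), value = numeric(),
               sd = numeric(), stringsAsFactors = FALSE),
    c(key, "time_s", "value", "sd"))
  fix <- function(df, key) {
    if (is.null(df) || !nrow(df)) return(empty(key))
    stopifnot(all(c(key, "time_s", "value") %in% names(df)))
    if (is.null(df$sd)) df$sd <- abs(df$value) * 0.1 + 1e-6
    if (any(df$sd <= 0)) stop("non-positive sd in ", key, " table")
    if (any(df$time_s < 0 | df$time_s > cycle_length))
      stop("observation time outside [0, cycle_length]")
    df <- df[order(df[[key]], df$time_s), c(key, "time_s", "value", "sd")]
    rownames(df) <- NULL
    df
  }
  structure(list(concentrations = fix(concentrations, "species"),
                 fluxes = fix(fluxes, "reaction"),
                 enrichment = fix(enrichment, "species"),
                 provenance = provenance, cycle_length = cycle_length),
            class = "observation_bundle")
}

#' @export
print.observation_bundle <- function(x, ...) {
  cat(sprintf("<observation_bundle (%s): %d conc, %d flux, %d enrichment rows>\n",
              x$provenance, nrow(x$concentrations), nrow(x$fluxes),
              nrow(x$enrichment)))
  invisible(x)
}

#' Free kinetic constants associated with an enzyme subset
#'
#' Maps enzyme identifiers to the constants released during estimation. The
#' scope mirrors the estimated-parameter policy of the calibration study:
#' transport, phosphorylation, the trehalose cycle, and maintenance ATPase.
#' `"TREHALOSE"` expands to the trehalose-cycle reactions.
#' @param enzymes character vector of enzyme/reaction identifiers
#' @return character vector of parameter keys
#' @export
enzyme_free_params <- function(enzymes) {
  reg <- list(
    HXT = c("HXT.Vmax", "HXT.Km"),
    HXK = c("HXK.Vmax", "HXK.Km_GLC", "HXK.Ki_T6P"),
    PFK = c("PFK.Vmax", "PFK.Km_F6P"),
    PGI = c("PGI.Vmax"),
    PYK = c("PYK.Vmax", "PYK.K05"),
    GAPDH = c("GAPDH.Vmax"),
    TPS1 = c("TPS1.Vmax"),
    TPS2 = c("TPS2.Vmax"),
    NTH1 = c("NTH1.Vmax", "NTH1.Km_TRE"),
    ATH1 = c("ATH1.Vmax"),
    AGT1 = c("AGT1.Vmax"),
    ATPase = c("ATPase.k")
  )
  enzymes <- unique(unlist(lapply(enzymes, function(e)
    if (identical(e, "TREHALOSE")) c("TPS1", "TPS2", "NTH1") else e)))
  unknown <- setdiff(enzymes, names(reg))
  if (length(unknown)) stop("no free-parameter registry for: ",
                            paste(unknown, collapse = ", "))
  unique(unlist(reg[enzymes]))
}

#' Estimation configuration
#'
#' @param free character vector of free parameter keys (see
#'   [enzyme_free_params()]), fitted in log10 space
#' @param reference reference `parameter_set` (regularization anchor and
#'   default initial guess for the free constants)
#' @param base parameter set supplying all non-free constants (defaults to
#'   the calibrated set)
#' @param weights named per-observable weight multipliers (> 0); unnamed
#'   observables get weight 1
#' @param lambda L1 regularization factor (>= 0)
#' @param bounds_decades half-width of the log10 box around the start
#' @param init_state initial state for the fitting simulations
#' @param n_cycles_fit cycles simulated per objective evaluation (the last
#'   one is compared to the data)
#' @param multistart number of starts (first at the reference values)
#' @param seed seed for the multistart jitter
#' @param max_iter LM iteration budget per start
#' @param rtol,atol,max_steps integrator controls for fitting simulations
#' @param subset_id label carried into results
#' @return an `estimation_config`
#' @export
estimation_config <- function(free, reference = reference_parameters(),
                              base = calibrated_parameters(), weights = NULL,
                              lambda = 0, bounds_decades = 2,
                              init_state = shipped_steady_state(),
                              n_cycles_fit = 3, multistart = 1, seed = 1,
                              max_iter = 25, rtol = 1e-6, atol = 1e-8,
                              max_steps = 30000L, subset_id = NULL) {
  stopifnot(lambda >= 0, bounds_decades > 0, multistart >= 1)
  unknown <- setdiff(free, model_parameters())
  if (length(unknown)) stop("unknown free parameter(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be > 0")
  structure(list(free = free, reference = reference, base = base,
                 weights = weights, lambda = lambda,
                 bounds_decades = bounds_decades, init_state = init_state,
                 n_cycles_fit = n_cycles_fit, multistart = multistart,
                 seed = seed, max_iter = max_iter, rtol = rtol, atol = atol,
                 max_steps = max_steps,
                 subset_id = subset_id %||% paste(sort(unique(sub("\\..*", "", free))),
                                                  collapse = "+")),
            class = "estimation_config")
}

#' Simulator factory for estimation
#'
#' Returns a function mapping a full `parameter_set` to model predictions at
#' the bundle's observation coordinates (final fitted cycle).
#' @param config an `estimation_config`
#' @param data an `observation_bundle`
#' @param protocol a [feed_protocol()]
#' @return function(parameter_set) -> list(conc, flux) prediction vectors
#' @export
make_cycle_simulator <- function(config, data, protocol = feed_protocol()) {
  conc_tab <- data$concentrations
  flux_tab <- data$fluxes
  out_times <- sort(unique(c(conc_tab$time_s, flux_tab$time_s)))
  if (!length(out_times)) stop("observation bundle is empty")
  function(p) {
    traj <- run_cycles(config$init_state, p, protocol,
                       n_cycles = config$n_cycles_fit, out_dt = 5,
                       keep = "last", rtol = config$rtol, atol = config$atol,
                       max_steps = config$max_steps)
    st_at <- function(var, ts) approx(traj$time, traj$states[, var], xout = ts,
                                      rule = 2)$y
    fl_at <- function(var, ts) approx(traj$time, traj$fluxes[, var], xout = ts,
                                      rule = 2)$y
    conc <- if (nrow(conc_tab)) unlist(lapply(split(conc_tab, conc_tab$species),
      function(d) st_at(d$species[1], d$time_s))) else numeric(0)
    flux <- if (nrow(flux_tab)) unlist(lapply(split(flux_tab, flux_tab$reaction),
      function(d) fl_at(d$reaction[1], d$time_s))) else numeric(0)
    list(conc = conc, flux = flux)
  }
}

.obs_blocks <- function(data) {
  # per-series normalization: every observable contributes with equal weight
  blocks <- list()
  for (tab in c("concentrations", "fluxes")) {
    df <- data[[tab]]
    if (!nrow(df)) next
    key <- if (tab == "concentrations") "species" else "reaction"
    for (d in split(df, df[[key]])) {
      blocks[[d[[key]][1]]] <- list(obs = d$value,
                                    norm = max(abs(d$value), 1e-9),
                                    table = tab)
    }
  }
  blocks
}

#' Weighted residual vector with optional L1 penalty
#'
#' Data residuals are `weight * (sim - obs) / norm` per observable, with
#' `norm = max |obs|` of that observable (equal-weight normalization).
#' When `lambda > 0`, one penalty residual per free parameter,
#' `sqrt(lambda * |log10 theta - log10 theta_ref|)`, implements the L1 cost
#' `lambda * sum |log10(theta/theta_ref)|` inside a least-squares objective.
#' Simulation failures yield large finite residuals so the optimizer can
#' retreat.
#'
#' @param p_free named numeric vector of free parameter values (natural scale)
#' @param config an `estimation_config`
#' @param data an `observation_bundle`
#' @param simulator from [make_cycle_simulator()]
#' @return numeric residual vector with attribute `blocks` (data/penalty split)
#' @export
build_residuals <- function(p_free, config, data, simulator) {
  p <- parameter_set(p_free, role = "estimated", base = config$base)
  blocks <- .obs_blocks(data)
  sim <- tryCatch(simulator(p), error = function(e) NULL)
  n_data <- sum(vapply(blocks, function(b) length(b$obs), 0L))
  if (is.null(sim)) {
    res <- rep(1e3, n_data)
  } else {
    simvals <- c(sim$conc, sim$flux)
    res <- numeric(0)
    i <- 1L
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      w <- if (!is.null(config$weights) && nm %in% names(config$weights))
        config$weights[[nm]] else 1
      k <- length(b$obs)
      res <- c(res, w * (simvals[i:(i + k - 1L)] - b$obs) / b$norm)
      i <- i + k
    }
    res[!is.finite(res)] <- 1e3
  }
  n_pen <- 0L
  if (config$lambda > 0 && length(config$free)) {
    ref <- as.numeric(config$reference[config$free])
    pen <- sqrt(config$lambda * abs(log10(p_free[config$free] / ref)))
    res <- c(res, pen)
    n_pen <- length(pen)
  }
  attr(res, "n_data") <- length(res) - n_pen
  res
}

#' Fit one enzyme subset
#'
#' Bounded Levenberg-Marquardt in log10-parameter space, starting from the
#' reference values of the free constants (multistart jitters around them).
#' @param config an `estimation_config`
#' @param data an `observation_bundle`
#' @param protocol a [feed_protocol()]
#' @return a `fit_result`: estimated `parameter_set`, data error, parameter
#'   error, residuals, convergence flag, subset id, weights
#' @export
fit_subset <- function(config, data, protocol = feed_protocol()) {
  simulator <- make_cycle_simulator(config, data, protocol)
  if (!length(config$free)) {
    p <- parameter_set(role = "estimated", base = config$base)
    r <- build_residuals(setNames(numeric(0), character(0)), config, data,
                         simulator)
    return(structure(list(par = p, estimates = numeric(0),
                          cost = sum(r^2), data_error = sum(r^2),
                          param_error = 0, residuals = r, converged = TRUE,
                          subset_id = config$subset_id, weights = config$weights,
                          n_eval = 1L),
                     class = "fit_result"))
  }
  start_vals <- if (!is.null(config$start)) config$start[config$free]
                else as.numeric(config$reference[config$free])
  anchor <- log10(as.numeric(config$reference[config$free]))
  lower <- anchor - config$bounds_decades
  upper <- anchor + config$bounds_decades
  start <- pmin(pmax(log10(as.numeric(start_vals)), lower), upper)
  objective <- function(x) {
    pf <- setNames(10^x, config$free)
    build_residuals(pf, config, data, simulator)
  }
  set.seed(config$seed)
  starts <- list(start)
  if (config$multistart > 1)
    for (k in seq_len(config$multistart - 1))
      starts[[k + 1]] <- pmin(pmax(start + rnorm(length(start), 0, 0.3), lower),
                              upper)
  best <- NULL
  for (x0 in starts) {
    fit <- lm_least_squares(objective, x0, lower, upper,
                            max_iter = config$max_iter)
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  est <- setNames(10^best$par, config$free)
  p_hat <- parameter_set(est, role = "estimated", base = config$base)
  lam <- config$lambda
  param_error <- if (lam > 0)
    lam * sum(abs(log10(est / as.numeric(config$reference[config$free])))) else 0
  structure(list(par = p_hat, estimates = est, cost = best$cost,
                 data_error = best$cost - param_error,
                 param_error = param_error,
                 residuals = best$residuals, converged = best$converged,
                 subset_id = config$subset_id, weights = config$weights,
                 n_eval = best$n_eval),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: cost %.4g (data %.4g + penalty %.4g), %s>\n",
              x$subset_id, x$cost, x$data_error, x$param_error,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Combinatorial enzyme-subset screening
#'
#' Fits every combination of enzyme subset and weight vector; every subset
#' must contain the trehalose cycle. Results are ranked by cost, ties broken
#' by fewer enzymes, then lexicographic subset id. Individual fit failures
#' are recorded and the screen continues.
#'
#' @param subsets list of character vectors of enzyme ids (each must include
#'   `"TREHALOSE"` or all of TPS1/TPS2/NTH1)
#' @param weight_grids list of named weight vectors (default: single
#'   all-ones vector)
#' @param data an `observation_bundle`
#' @param config_base an `estimation_config` template (its `free` field is
#'   replaced per subset)
#' @param protocol a [feed_protocol()]
#' @return a `screen_result`: `table` (ranked data.frame) and `fits`
#' @export
combinatorial_screen <- function(subsets, weight_grids = list(NULL), data,
                                 config_base, protocol = feed_protocol()) {
  has_tre <- vapply(subsets, function(s)
    "TREHALOSE" %in% s || all(c("TPS1", "TPS2", "NTH1") %in% s), TRUE)
  if (!all(has_tre))
    stop("every screened subset must contain the trehalose cycle")
  rows <- list(); fits <- list()
  k <- 0L
  for (sub in subsets) {
    for (wi in seq_along(weight_grids)) {
      k <- k + 1L
      cfg <- config_base
      cfg$free <- enzyme_free_params(sub)
      cfg$weights <- weight_grids[[wi]]
      cfg$subset_id <- paste(sort(setdiff(sub, character(0))), collapse = "+")
      fit <- tryCatch(fit_subset(cfg, data, protocol), error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[k]] <- data.frame(subset = cfg$subset_id, weights = wi,
                                n_enzymes = length(sub), cost = NA_real_,
                                converged = FALSE,
                                error = conditionMessage(fit),
                                stringsAsFactors = FALSE)
      } else {
        fits[[k]] <- fit
        rows[[k]] <- data.frame(subset = cfg$subset_id, weights = wi,
                                n_enzymes = length(sub), cost = fit$cost,
                                converged = fit$converged, error = "",
                                stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(is.na(tab$cost), tab$cost, tab$n_enzymes, tab$subset)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "screen_result")
}

#' Regularization sweep over lambda
#'
#' Re-fits the chosen subset for each lambda (warm-starting each fit from
#' the previous solution), returning the data-error and parameter-error
#' curves and the selected lambda: the largest lambda whose data error stays
#' within 5% of the sweep minimum (knee rule).
#'
#' @param subset character vector of enzyme ids
#' @param lambdas lambda grid (log-spaced, should include 0)
#' @param data an `observation_bundle`
#' @param config_base an `estimation_config` template
#' @param protocol a [feed_protocol()]
#' @param slack relative data-error slack for the knee rule
#' @return a `sweep_result`: `curve` data.frame, `chosen_lambda`, `fits`
#' @export
regularization_sweep <- function(subset, lambdas, data, config_base,
                                 protocol = feed_protocol(), slack = 0.05) {
  free <- enzyme_free_params(subset)
  fits <- list()
  rows <- list()
  warm <- NULL
  for (i in seq_along(lambdas)) {
    cfg <- config_base
    cfg$free <- free
    cfg$lambda <- lambdas[i]
    if (!is.null(warm)) cfg$start <- warm   # regularization anchor stays fixed
    fit <- fit_subset(cfg, data, protocol)
    if (length(fit$estimates)) warm <- fit$estimates
    fits[[i]] <- fit
    rows[[i]] <- data.frame(lambda = lambdas[i], cost = fit$cost,
                            data_error = fit$data_error,
                            param_error = fit$param_error,
                            converged = fit$converged)
  }
  curve <- do.call(rbind, rows)
  dmin <- min(curve$data_error)
  ok <- curve$lambda[curve$data_error <= (1 + slack) * dmin]
  chosen <- max(ok)
  structure(list(curve = curve, chosen_lambda = chosen, fits = fits,
                 subset = subset), class = "sweep_result")
}
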