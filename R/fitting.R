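# Two-step SSR estimation: control fit for (lambda, K), joint treated fit
# for (Emax, IC50), Nelder-Mead in transformed space, bootstrap CIs.

#' Fitting configuration
#'
#' Settings shared by \code{\link{fit_control}}, \code{\link{fit_treated}}
#' and \code{\link{bootstrap_ci}}.
#'
#' @param reltol Nelder-Mead relative convergence tolerance on the SSR.
#' @param maxit maximum Nelder-Mead iterations per round.
#' @param restarts maximum number of optimizer restarts from the incumbent
#'   optimum (restarting rebuilds the simplex and guards against premature
#'   collapse).
#' @param Emax_upper upper bound on Emax; the fit works on
#'   logit(Emax / Emax_upper) so the bound is enforced by construction.
#' @param estimate_N0 if TRUE the control fit estimates the initial count
#'   N0 as a free parameter instead of fixing it at the plating density.
#' @param max_day drop observations after this day before fitting (counts
#'   past the growth peak can reflect well overcrowding; default keeps all).
#' @param boot_scheme bootstrap resampling scheme: \code{"case"} (default)
#'   resamples wells (records) with replacement from the whole arm — the
#'   standard pairs bootstrap; \code{"stratified"} resamples replicate
#'   wells within each (condition, dose, day) cell, preserving the design
#'   exactly but shrinking within-cell variance by (n-1)/n, which is
#'   anti-conservative with the usual 3 wells per cell; \code{"residual"}
#'   resamples residuals around the fitted trajectory. Schemes needing
#'   replicates fall back to \code{"residual"} when no cell has more than
#'   one replicate.
#' @param n_boot default number of bootstrap replicates.
#' @return A list of class \code{fit_config}.
#' @export
fit_config <- function(reltol = 1e-8, maxit = 5000, restarts = 3,
                       Emax_upper = 2, estimate_N0 = FALSE, max_day = Inf,
                       boot_scheme = c("case", "stratified", "residual"),
                       n_boot = 1000) {
  boot_scheme <- match.arg(boot_scheme)
  structure(list(reltol = reltol, maxit = maxit, restarts = restarts,
                 Emax_upper = Emax_upper, estimate_N0 = estimate_N0,
                 max_day = max_day, boot_scheme = boot_scheme,
                 n_boot = n_boot),
            class = "fit_config")
}

#' Sum of squared residuals between a dataset and model predictions
#'
#' Every replicate enters individually; predictions are matched to records
#' by (dose, day).
#'
#' @param dataset a \code{\link{growth_dataset}}.
#' @param predicted a data.frame with columns \code{dose_ug_ml},
#'   \code{day}, \code{count} covering every (dose, day) pair present in
#'   the dataset.
#' @return The nonnegative sum over records of (observed - predicted)^2.
#' @export
ssr <- function(dataset, predicted) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (!all(c("dose_ug_ml", "day", "count") %in% names(predicted)))
    stop_domain("'predicted' needs columns dose_ug_ml, day, count")
  key_obs <- paste(dataset$dose_ug_ml, dataset$day)
  key_pred <- paste(predicted$dose_ug_ml, predicted$day)
  idx <- match(key_obs, key_pred)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop_domain("no prediction for observed point (dose = %g, day = %g)",
                dataset$dose_ug_ml[bad], dataset$day[bad])
  }
  sum((dataset$count - predicted$count[idx])^2)
}

# Model counts for the (dose, day) pairs of a record table. Vectorised and
# allocation-light: this sits in the innermost loop of every fit.
predict_counts <- function(dose, day, lambda, K, N0, Emax = 0, IC50 = 1) {
  eps <- Emax * dose / (dose + IC50)
  r <- lambda * (1 - eps)
  if (N0 == K) return(rep_len(K, length(day)))
  N0 * K / (N0 + (K - N0) * exp(-r * day))
}

new_fit_result <- function(step, estimates, ssr, converged, n_iterations,
                           flags = character(), params = NULL,
                           effect = NULL, fixed = NULL, config,
                           n_obs) {
  structure(list(step = step, estimates = estimates, ssr = ssr,
                 converged = converged, n_iterations = n_iterations,
                 flags = flags, params = params, effect = effect,
                 fixed = fixed, config = config, n_obs = n_obs,
                 bootstrap_samples = NULL, ci_lower = NULL,
                 ci_upper = NULL, seed = NULL),
            class = "chemofit_fit")
}

#' @export
print.chemofit_fit <- function(x, ...) {
  cat(sprintf("chemofit fit (%s step): SSR = %.6g, converged = %s\n",
              x$step, x$ssr, x$converged))
  est <- data.frame(estimate = x$estimates)
  if (!is.null(x$ci_lower)) {
    est$ci_lower <- x$ci_lower[rownames(est)]
    est$ci_upper <- x$ci_upper[rownames(est)]
  }
  print(est)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Repeated Nelder-Mead with restarts from the incumbent optimum.
nm_minimize <- function(par, fn, config) {
  best <- list(par = par, value = fn(par), convergence = 1L, counts = 0L)
  iters <- 0L
  for (round in seq_len(max(1L, config$restarts))) {
    opt <- stats::optim(best$par, fn, method = "Nelder-Mead",
                        control = list(reltol = config$reltol,
                                       maxit = config$maxit))
    iters <- iters + opt$counts[["function"]]
    improved <- best$value - opt$value
    if (opt$value <= best$value)
      best <- list(par = opt$par, value = opt$value,
                   convergence = opt$convergence, counts = iters)
    if (improved <= config$reltol * (abs(best$value) + 1e-12)) break
  }
  best$counts <- iters
  best
}

# Starting value for lambda from log-linear regression of the early part of
# the control curve (logistic growth is ~exponential well below K).
start_lambda <- function(day, count) {
  agg <- tapply(pmax(count, 0.5), day, mean)
  d <- as.numeric(names(agg))
  use <- seq_len(max(2L, ceiling(length(d) / 2)))
  sl <- tryCatch(coef(lm(log(agg[use]) ~ d[use]))[[2]], error = function(e) NA)
  if (!is.finite(sl) || sl <= 0) 0.1 else sl
}

#' Fit the control (drug-free) growth curve
#'
#' Estimates lambda and K (optionally N0) by minimising the SSR between
#' dose-0 counts and the closed-form logistic trajectory, using
#' Nelder-Mead on (log lambda, log K) so positivity holds by construction.
#'
#' @param dataset a \code{\link{growth_dataset}}; only dose-0 records are
#'   used, and at least 3 distinct days are required.
#' @param config a \code{\link{fit_config}}.
#' @param N0 initial count; defaults to the dataset's plating density.
#'   Required unless \code{config$estimate_N0} is TRUE.
#' @param start optional named vector \code{c(lambda=, K=)} (and \code{N0}
#'   when estimated) overriding the automatic starting point.
#' @return A \code{chemofit_fit} with \code{$params} the fitted
#'   \code{\link{growth_parameters}}.
#' @export
fit_control <- function(dataset, config = fit_config(), N0 = NULL,
                        start = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  ctrl <- control_subset(dataset)
  if (is.finite(config$max_day))
    ctrl <- subset_dataset(ctrl, ctrl$day <= config$max_day)
  if (nrow(ctrl) == 0L)
    stop_domain("dataset contains no dose-0 (control) records")
  if (length(unique(ctrl$day)) < 3L)
    stop_domain("control fit needs >= 3 distinct days")
  N0 <- N0 %||% attr(dataset, "plating_density")
  if (is.null(N0) && !config$estimate_N0)
    stop_domain("N0 unknown: supply N0, set a plating density, or use estimate_N0 = TRUE")

  counts <- ctrl$count
  if (all(counts == 0))
    stop_domain("degenerate control data: all counts are zero")
  if (length(unique(counts)) == 1L) {
    cst <- counts[1]
    if (!is.null(N0) && abs(cst - N0) <= 0.05 * N0) {
      # saturated well: K is the constant, lambda carries no information
      est <- c(lambda = start_lambda(ctrl$day, counts), K = cst)
      fit <- new_fit_result("control", est, ssr = 0, converged = TRUE,
                            n_iterations = 0L,
                            flags = "saturated-well; lambda unidentifiable",
                            params = growth_parameters(est[["lambda"]], cst, N0),
                            config = config, n_obs = nrow(ctrl))
      return(fit)
    }
    stop_domain("degenerate control data: all counts constant at %g", cst)
  }

  est_n0 <- isTRUE(config$estimate_N0)
  l0 <- if (!is.null(start)) start[["lambda"]] else start_lambda(ctrl$day, counts)
  K0 <- if (!is.null(start)) start[["K"]] else 1.5 * max(counts)
  n00 <- if (est_n0) {
    if (!is.null(start) && "N0" %in% names(start)) start[["N0"]]
    else N0 %||% max(min(counts), 1)
  } else N0
  theta <- if (est_n0) log(c(l0, K0, n00)) else log(c(l0, K0))

  day <- ctrl$day
  obs <- counts
  fn <- if (est_n0) {
    function(th) {
      p <- exp(th)
      sum((obs - predict_counts(0, day, p[1], p[2], p[3]))^2)
    }
  } else {
    function(th) {
      p <- exp(th)
      sum((obs - predict_counts(0, day, p[1], p[2], N0))^2)
    }
  }
  opt <- nm_minimize(theta, fn, config)
  p <- exp(opt$par)
  est <- if (est_n0) c(lambda = p[1], K = p[2], N0 = p[3])
         else c(lambda = p[1], K = p[2])
  n0_hat <- if (est_n0) p[3] else N0
  converged <- opt$convergence == 0L
  flags <- character()
  if (!converged) flags <- "optimizer did not converge"
  new_fit_result("control", est, ssr = opt$value, converged = converged,
                 n_iterations = opt$counts, flags = flags,
                 params = growth_parameters(p[1], p[2], n0_hat),
                 config = config, n_obs = nrow(ctrl))
}

#' Jointly fit the treated growth curves for (Emax, IC50)
#'
#' All dose > 0 curves are fitted simultaneously with a single
#' (Emax, IC50) pair — the pooled SSR over every treated record is
#' minimised, never per-dose fits — while the control parameters
#' (lambda, K, N0) stay fixed. Nelder-Mead works on
#' (logit(Emax/Emax_upper), log IC50), so 0 <= Emax <= Emax_upper and
#' IC50 > 0 hold by construction.
#'
#' @param dataset a \code{\link{growth_dataset}}; only dose > 0 records
#'   are used.
#' @param control fitted control parameters: a
#'   \code{\link{growth_parameters}} or the \code{chemofit_fit} returned by
#'   \code{\link{fit_control}}.
#' @param config a \code{\link{fit_config}}.
#' @param condition optional condition label restricting the treated arm.
#' @param start optional named vector \code{c(Emax=, IC50=)} overriding the
#'   default start (Emax = 0.5, IC50 = geometric mean of tested doses).
#' @return A \code{chemofit_fit} with \code{$effect} the fitted
#'   \code{\link{drug_effect}} and \code{$fixed} the control parameters.
#' @export
fit_treated <- function(dataset, control, config = fit_config(),
                        condition = NULL, start = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (inherits(control, "chemofit_fit")) control <- control$params
  stopifnot(inherits(control, "growth_parameters"))
  trt <- treated_subset(dataset, condition)
  if (is.finite(config$max_day))
    trt <- subset_dataset(trt, trt$day <= config$max_day)
  if (nrow(trt) == 0L)
    stop_domain("dataset contains no treated (dose > 0) records")
  flags <- character()
  doses_present <- sort(unique(trt$dose_ug_ml))
  if (length(doses_present) < 2L)
    flags <- c(flags,
               "single dose: Emax and IC50 are confounded (identifiability warning)")

  upper <- config$Emax_upper
  e0 <- if (!is.null(start)) start[["Emax"]] else 0.5
  ic0 <- if (!is.null(start)) start[["IC50"]] else geometric_mean(doses_present)
  e0 <- min(max(e0, 1e-4 * upper), (1 - 1e-4) * upper)
  theta <- c(stats::qlogis(e0 / upper), log(ic0))

  dose <- trt$dose_ug_ml
  day <- trt$day
  obs <- trt$count
  lam <- control$lambda; K <- control$K; N0 <- control$N0
  fn <- function(th) {
    Emax <- upper * stats::plogis(th[1])
    IC50 <- exp(th[2])
    sum((obs - predict_counts(dose, day, lam, K, N0, Emax, IC50))^2)
  }
  opt <- nm_minimize(theta, fn, config)
  Emax_hat <- upper * stats::plogis(opt$par[1])
  IC50_hat <- exp(opt$par[2])
  if (Emax_hat >= 0.999 * upper)
    flags <- c(flags, "Emax at upper bound")
  if (IC50_hat > max(doses_present) * 1e3 ||
      IC50_hat < min(doses_present) * 1e-3)
    flags <- c(flags, "IC50 outside tested dose range (boundary hit)")
  converged <- opt$convergence == 0L
  if (!converged) flags <- c(flags, "optimizer did not converge")
  new_fit_result("treated", c(Emax = Emax_hat, IC50 = IC50_hat),
                 ssr = opt$value, converged = converged,
                 n_iterations = opt$counts, flags = flags,
                 effect = drug_effect(min(Emax_hat, upper), IC50_hat, upper),
                 fixed = control, config = config, n_obs = nrow(trt))
}

#' Two-step growth-model fit
#'
#' Convenience wrapper running \code{\link{fit_control}} then
#' \code{\link{fit_treated}} on one dataset.
#'
#' @inheritParams fit_treated
#' @inheritParams fit_control
#' @return A list of class \code{chemofit_two_step} with elements
#'   \code{control} and \code{treated}.
#' @export
fit_two_step <- function(dataset, config = fit_config(), N0 = NULL,
                         condition = NULL) {
  ctrl_fit <- fit_control(dataset, config, N0 = N0)
  trt_fit <- fit_treated(dataset, ctrl_fit$params, config,
                         condition = condition)
  structure(list(control = ctrl_fit, treated = trt_fit),
            class = "chemofit_two_step")
}

#' @export
print.chemofit_two_step <- function(x, ...) {
  print(x$control); print(x$treated); invisible(x)
}

# --- bootstrap ---------------------------------------------------------

# Pairs bootstrap: resample wells with replacement from the whole table.
resample_pairs <- function(df) {
  df[sort(sample.int(nrow(df), replace = TRUE)), , drop = FALSE]
}

# Stratified resampling: draw replicate rows with replacement within each
# (condition, dose, day) cell.
resample_cases <- function(df) {
  cells <- split(seq_len(nrow(df)),
                 paste(df$condition, df$dose_ug_ml, df$day))
  idx <- unlist(lapply(cells, function(i) i[sample.int(length(i),
                                                       replace = TRUE)]),
                use.names = FALSE)
  df[sort(idx), , drop = FALSE]
}

# Residual resampling around the fitted trajectory.
resample_residuals <- function(df, pred) {
  resid <- df$count - pred
  df$count <- pmax(pred + sample(resid, length(resid), replace = TRUE), 0)
  df
}

# Pick the effective scheme (replicate-based schemes fall back to residual
# resampling when the design has no true replicates) and draw one
# bootstrap dataset.
effective_scheme <- function(scheme, df) {
  has_reps <- any(tabulate(factor(paste(df$condition, df$dose_ug_ml,
                                        df$day))) > 1L)
  if (!has_reps) "residual" else scheme
}

draw_bootstrap <- function(scheme, df, pred) {
  switch(scheme,
         case = resample_pairs(df),
         stratified = resample_cases(df),
         residual = resample_residuals(df, pred))
}

refit_once <- function(df_boot, fitted, dataset) {
  boot_ds <- growth_dataset(df_boot,
                            plating_density = attr(dataset, "plating_density"))
  if (fitted$step == "control") {
    fit_control(boot_ds, fitted$config, N0 = fitted$params$N0,
                start = fitted$estimates[c("lambda", "K")])
  } else {
    fit_treated(boot_ds, fitted$fixed, fitted$config,
                start = fitted$estimates[c("Emax", "IC50")])
  }
}

#' Bootstrap percentile confidence intervals for a fit
#'
#' Refits the model on resampled datasets and attaches percentile 2.5/97.5
#' bounds per parameter. Resampling is case resampling of replicate wells
#' within each (condition, dose, day) cell, falling back to residual
#' resampling when the design has no true replicates (configurable via
#' \code{\link{fit_config}}). Deterministic given \code{seed}.
#'
#' For a \code{chemofit_two_step} fit the whole procedure — control fit
#' then treated fit — is repeated on each resampled dataset, so the
#' intervals on Emax and IC50 propagate the uncertainty of the control
#' parameters instead of conditioning on their point estimates
#' (conditioning makes the treated-step intervals anti-conservative).
#'
#' @param dataset the \code{\link{growth_dataset}} the fit was computed
#'   from (the full dataset; the relevant arm is selected per step).
#' @param fitted a converged \code{chemofit_fit} from
#'   \code{\link{fit_control}} or \code{\link{fit_treated}}, or a
#'   \code{chemofit_two_step} from \code{\link{fit_two_step}}.
#' @param n_boot number of bootstrap replicates (>= 2; 1000 by default via
#'   the config).
#' @param seed RNG seed; identical seeds give bit-identical samples.
#' @return The input fit with \code{bootstrap_samples} (n_boot x n_param
#'   matrix), \code{ci_lower}, \code{ci_upper} and \code{seed} filled in.
#'   More than 20% non-convergent replicate fits adds an
#'   \code{"unreliable"} flag; an interval not containing the point
#'   estimate adds a warning flag.
#' @export
bootstrap_ci <- function(dataset, fitted, n_boot = NULL, seed = 1) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (inherits(fitted, "chemofit_two_step"))
    return(bootstrap_two_step(dataset, fitted, n_boot, seed))
  stopifnot(inherits(fitted, "chemofit_fit"))
  n_boot <- n_boot %||% fitted$config$n_boot
  if (n_boot < 2) stop_domain("n_boot must be >= 2")
  if (!isTRUE(fitted$converged))
    stop_domain("bootstrap requires a converged point fit")

  df <- if (fitted$step == "control") control_subset(dataset)
        else treated_subset(dataset)
  if (is.finite(fitted$config$max_day))
    df <- subset_dataset(df, df$day <= fitted$config$max_day)
  df <- as.data.frame(df)

  scheme <- effective_scheme(fitted$config$boot_scheme, df)
  pred <- if (fitted$step == "control") {
    p <- fitted$params
    predict_counts(0, df$day, p$lambda, p$K, p$N0)
  } else {
    p <- fitted$fixed
    predict_counts(df$dose_ug_ml, df$day, p$lambda, p$K, p$N0,
                   fitted$estimates[["Emax"]], fitted$estimates[["IC50"]])
  }

  pnames <- names(fitted$estimates)
  samples <- matrix(NA_real_, n_boot, length(pnames),
                    dimnames = list(NULL, pnames))
  n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      df_b <- draw_bootstrap(scheme, df, pred)
      fit_b <- tryCatch(refit_once(df_b, fitted, dataset),
                        error = function(e) NULL)
      if (is.null(fit_b) || !fit_b$converged) n_fail <- n_fail + 1L
      if (!is.null(fit_b)) samples[b, ] <- fit_b$estimates[pnames]
    }
  })

  ok <- stats::complete.cases(samples)
  fitted$bootstrap_samples <- samples
  fitted$ci_lower <- apply(samples[ok, , drop = FALSE], 2, quantile,
                           probs = 0.025, names = FALSE)
  fitted$ci_upper <- apply(samples[ok, , drop = FALSE], 2, quantile,
                           probs = 0.975, names = FALSE)
  names(fitted$ci_lower) <- names(fitted$ci_upper) <- pnames
  fitted$seed <- seed
  if (n_fail > 0.2 * n_boot)
    fitted$flags <- c(fitted$flags, "unreliable: >20% bootstrap fits failed")
  outside <- fitted$estimates < fitted$ci_lower |
             fitted$estimates > fitted$ci_upper
  if (any(outside))
    fitted$flags <- c(fitted$flags,
                      paste("point estimate outside percentile CI:",
                            paste(pnames[outside], collapse = ", ")))
  fitted
}

# Bootstrap of the full two-step procedure: resample every
# (condition, dose, day) cell of the dataset, refit control then treated,
# and attach CIs for all four parameters to both sub-fits.
bootstrap_two_step <- function(dataset, fitted, n_boot = NULL, seed = 1) {
  n_boot <- n_boot %||% fitted$control$config$n_boot
  if (n_boot < 2) stop_domain("n_boot must be >= 2")
  if (!fitted$control$converged || !fitted$treated$converged)
    stop_domain("bootstrap requires converged point fits")
  config <- fitted$control$config
  df <- as.data.frame(dataset)
  if (is.finite(config$max_day)) df <- df[df$day <= config$max_day, ]

  scheme <- effective_scheme(config$boot_scheme, df)
  p <- fitted$control$params
  eff <- fitted$treated$estimates
  pred <- predict_counts(df$dose_ug_ml, df$day, p$lambda, p$K, p$N0,
                         eff[["Emax"]], eff[["IC50"]])

  pnames <- c(names(fitted$control$estimates),
              names(fitted$treated$estimates))
  samples <- matrix(NA_real_, n_boot, length(pnames),
                    dimnames = list(NULL, pnames))
  n_fail <- 0L
  pd <- attr(dataset, "plating_density")
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      df_b <- draw_bootstrap(scheme, df, pred)
      fit_b <- tryCatch({
        ds_b <- growth_dataset(df_b, plating_density = pd)
        cf <- fit_control(ds_b, config, N0 = p$N0,
                          start = fitted$control$estimates)
        tf <- fit_treated(ds_b, cf$params, config,
                          start = fitted$treated$estimates)
        list(cf = cf, tf = tf)
      }, error = function(e) NULL)
      if (is.null(fit_b) || !fit_b$cf$converged || !fit_b$tf$converged)
        n_fail <- n_fail + 1L
      if (!is.null(fit_b))
        samples[b, ] <- c(fit_b$cf$estimates, fit_b$tf$estimates)[pnames]
    }
  })

  ok <- stats::complete.cases(samples)
  lo <- apply(samples[ok, , drop = FALSE], 2, quantile, probs = 0.025,
              names = FALSE)
  hi <- apply(samples[ok, , drop = FALSE], 2, quantile, probs = 0.975,
              names = FALSE)
  names(lo) <- names(hi) <- pnames
  unreliable <- n_fail > 0.2 * n_boot
  for (part in c("control", "treated")) {
    pn <- names(fitted[[part]]$estimates)
    fitted[[part]]$bootstrap_samples <- samples[, pn, drop = FALSE]
    fitted[[part]]$ci_lower <- lo[pn]
    fitted[[part]]$ci_upper <- hi[pn]
    fitted[[part]]$seed <- seed
    if (unreliable)
      fitted[[part]]$flags <- c(fitted[[part]]$flags,
                                "unreliable: >20% bootstrap fits failed")
    outside <- fitted[[part]]$estimates < lo[pn] |
               fitted[[part]]$estimates > hi[pn]
    if (any(outside))
      fitted[[part]]$flags <- c(fitted[[part]]$flags,
                                paste("point estimate outside percentile CI:",
                                      paste(pn[outside], collapse = ", ")))
  }
  fitted$bootstrap_samples <- samples
  fitted
}
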