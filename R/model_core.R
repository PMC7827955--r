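# Forward model: logistic growth, Emax efficacy, and dosed growth curves.

#' Drug-free growth parameters
#'
#' Container for the logistic growth model dN/dt = lambda * N * (1 - N/K).
#'
#' @param lambda cell growth rate, per day (> 0).
#' @param K carrying capacity of the well, cells/well (> 0).
#' @param N0 initial (plated) cell count, cells/well (> 0). Typically the
#'   known plating density; wells are seeded far below capacity so usually
#'   N0 <= K, though that is not enforced.
#' @return An object of class \code{growth_parameters}.
#' @examples
#' growth_parameters(lambda = 0.5, K = 1e5, N0 = 1000)
#' @export
growth_parameters <- function(lambda, K, N0) {
  check_scalar_num(lambda, "lambda", 0, strict = TRUE)
  check_scalar_num(K, "K", 0, strict = TRUE)
  check_scalar_num(N0, "N0", 0, strict = TRUE)
  structure(list(lambda = lambda, K = K, N0 = N0),
            class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat(sprintf("Growth parameters: lambda = %.4g /day, K = %.4g cells, N0 = %.4g cells\n",
              x$lambda, x$K, x$N0))
  invisible(x)
}

#' Emax drug-effect parameters
#'
#' Container for the Emax pharmacodynamic model
#' eps(D) = Emax * D / (D + IC50), the fractional reduction of the growth
#' rate at drug concentration D.
#'
#' @param Emax maximum growth-rate reduction (dimensionless). Values above
#'   1 put treated cells in a net-death regime (negative effective rate),
#'   which complete growth suppression at high doses can require.
#' @param IC50 concentration achieving half the maximum effect, ug/mL (> 0).
#' @param Emax_upper upper bound on Emax used by the fitting routines
#'   (default 2; set to 1 to forbid the net-death regime).
#' @return An object of class \code{drug_effect}.
#' @examples
#' drug_effect(Emax = 0.9, IC50 = 0.002)
#' @export
drug_effect <- function(Emax, IC50, Emax_upper = 2) {
  check_scalar_num(Emax, "Emax", 0)
  check_scalar_num(IC50, "IC50", 0, strict = TRUE)
  check_scalar_num(Emax_upper, "Emax_upper", 0, strict = TRUE)
  if (Emax > Emax_upper)
    stop_domain("Emax (%g) exceeds Emax_upper (%g)", Emax, Emax_upper)
  structure(list(Emax = Emax, IC50 = IC50, Emax_upper = Emax_upper),
            class = "drug_effect")
}

#' @export
print.drug_effect <- function(x, ...) {
  cat(sprintf("Drug effect: Emax = %.4g, IC50 = %.4g ug/mL (bound %.3g)\n",
              x$Emax, x$IC50, x$Emax_upper))
  invisible(x)
}

#' Dose schedule
#'
#' An ordered set of drug concentrations applied in one experiment arm.
#'
#' @param doses concentrations in ug/mL, >= 0; 0 encodes the untreated
#'   control. Sorted ascending; duplicates are an error.
#' @param label formulation identifier, e.g. \code{"DOX"} or
#'   \code{"DOX-N-GQD"}.
#' @return An object of class \code{dose_schedule}.
#' @export
dose_schedule <- function(doses, label = "drug") {
  check_num_vec(doses, "doses", lower = 0)
  doses <- sort(doses)
  if (anyDuplicated(doses))
    stop_domain("duplicate doses are not allowed")
  structure(list(doses = doses, label = as.character(label)[1]),
            class = "dose_schedule")
}

#' Drug efficacy at a given concentration
#'
#' Evaluates the Emax model eps(D) = Emax * D / (D + IC50).
#'
#' @param D drug concentration(s) in ug/mL, >= 0 (vectorised).
#' @param effect a \code{\link{drug_effect}}.
#' @return Efficacy value(s) in [0, Emax]; 0 at D = 0, Emax/2 at D = IC50,
#'   approaching Emax as D grows.
#' @examples
#' eff <- drug_effect(Emax = 0.9, IC50 = 1)
#' efficacy(9, eff)   # 0.81
#' @export
efficacy <- function(D, effect) {
  stopifnot(inherits(effect, "drug_effect"))
  if (!is.numeric(D) || anyNA(D))
    stop_domain("'D' must be numeric without NAs")
  if (any(D < 0))
    stop_domain("negative concentration D = %g is not allowed", min(D))
  effect$Emax * D / (D + effect$IC50)
}

#' Effective growth rate under treatment
#'
#' The drug scales the growth rate: r = lambda * (1 - eps). For eps > 1 the
#' rate is negative (net cell death), which is permitted.
#'
#' @param params a \code{\link{growth_parameters}}.
#' @param eps efficacy value(s) as returned by \code{\link{efficacy}}.
#' @return Effective rate(s) per day.
#' @export
effective_rate <- function(params, eps) {
  stopifnot(inherits(params, "growth_parameters"))
  if (!is.numeric(eps) || anyNA(eps))
    stop_domain("'eps' must be numeric without NAs")
  params$lambda * (1 - eps)
}

#' Closed-form logistic growth trajectory
#'
#' Solution of dN/dt = r * N * (1 - N/K) with N(0) = N0:
#' N(t) = N0 * K / (N0 + (K - N0) * exp(-r t)).
#' Computed in the decaying-exponential form so large r*t never overflows;
#' for r < 0 the count decays toward 0, for r > 0 it saturates at K.
#'
#' @param t time(s) in days, >= 0 (vectorised; `t` and `rate` recycle).
#' @param params a \code{\link{growth_parameters}} supplying K and N0.
#' @param rate effective growth rate per day; defaults to the drug-free
#'   \code{params$lambda}.
#' @return Cell count(s) at time t.
#' @examples
#' p <- growth_parameters(0.5, 1e5, 500)
#' logistic_solution(c(0, 7, 14), p)
#' @export
logistic_solution <- function(t, params, rate = params$lambda) {
  stopifnot(inherits(params, "growth_parameters"))
  if (!is.numeric(t) || anyNA(t))
    stop_domain("'t' must be numeric without NAs")
  if (any(t < 0))
    stop_domain("negative time t = %g is not allowed", min(t))
  K <- params$K
  N0 <- params$N0
  if (N0 == K) {
    # fixed point of the logistic for every rate
    out <- rep_len(K, max(length(t), length(rate)))
    return(out)
  }
  # exp(-r t) may legitimately overflow to Inf when r < 0 and t is large;
  # the ratio then underflows to the correct limit 0.
  N0 * K / (N0 + (K - N0) * exp(-rate * t))
}

#' Simulate noise-free dosed growth curves
#'
#' Composes the Emax efficacy, rate scaling, and logistic solution into one
#' trajectory per dose of a schedule. Dose 0 reproduces the untreated
#' control; for Emax > 0 trajectories are pointwise non-increasing in dose.
#'
#' @param params a \code{\link{growth_parameters}}.
#' @param effect a \code{\link{drug_effect}}.
#' @param schedule a \code{\link{dose_schedule}}.
#' @param times observation days, nonnegative and ascending.
#' @param cell_line label stored in the dataset metadata.
#' @return A \code{\link{growth_dataset}} with one replicate per
#'   (dose, day) cell and exact model counts.
#' @export
simulate_growth_curves <- function(params, effect, schedule, times,
                                   cell_line = "cells") {
  stopifnot(inherits(params, "growth_parameters"),
            inherits(effect, "drug_effect"),
            inherits(schedule, "dose_schedule"))
  if (length(times) == 0L)
    stop_domain("'times' must not be empty")
  check_num_vec(times, "times", lower = 0)
  if (is.unsorted(times, strictly = TRUE))
    stop_domain("'times' must be strictly ascending")
  if (length(schedule$doses) == 0L)
    stop_domain("'schedule' must contain at least one dose")

  rates <- effective_rate(params, efficacy(schedule$doses, effect))
  grid <- expand.grid(day = times, dose_ug_ml = schedule$doses,
                      KEEP.OUT.ATTRS = FALSE)
  grid$count <- logistic_solution(grid$day, params,
                                  rate = rep(rates, each = length(times)))
  growth_dataset(data.frame(
    cell_line = cell_line,
    condition = schedule$label,
    dose_ug_ml = grid$dose_ug_ml,
    day = grid$day,
    replicate = 1L,
    count = grid$count
  ), plating_density = params$N0)
}
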