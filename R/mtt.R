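# Forward simulation of MTT viability assays and apparent-IC50 extraction.
#
# The simulation equates viability with the treated/control cell-count
# ratio at the measurement day, i.e. formazan absorbance is taken as
# proportional to viable cell number.

#' Default MTT dose grid
#'
#' Nine-point twofold dilution series from 0.00625 to 1.6 ug/mL
#' (0.00625 * 2^8 = 1.6), the standard plate layout the package's MTT
#' presets emulate.
#'
#' @return Numeric vector of 9 concentrations in ug/mL.
#' @export
mtt_dose_grid <- function() 0.00625 * 2^(0:8)

#' Simulate an MTT viability assay at one measurement day
#'
#' Viability at dose D is the ratio of the treated to the untreated
#' logistic trajectory at the measurement day:
#' v(D) = N(day; lambda (1 - eps(D))) / N(day; lambda).
#' Deterministic, monotone non-increasing in dose, and exactly 1 at D = 0.
#'
#' @param params a \code{\link{growth_parameters}}.
#' @param effect a \code{\link{drug_effect}}.
#' @param doses concentrations in ug/mL (default \code{\link{mtt_dose_grid}}).
#' @param day measurement day (> 0; day = 0 returns all-1 viabilities with
#'   a warning).
#' @return An object of class \code{mtt_series}: a data.frame with columns
#'   \code{day}, \code{dose_ug_ml}, \code{viability}.
#' @export
simulate_mtt <- function(params, effect, doses = mtt_dose_grid(), day) {
  stopifnot(inherits(params, "growth_parameters"),
            inherits(effect, "drug_effect"))
  check_num_vec(doses, "doses", lower = 0)
  check_scalar_num(day, "day", 0)
  if (day == 0)
    warning("day = 0: all viabilities are 1 (degenerate assay)")
  doses <- sort(doses)
  if (max(doses) < effect$IC50 && effect$Emax > 0)
    warning("dose range ends below the model IC50; the viability curve may not bracket its half-maximum")
  rates <- effective_rate(params, efficacy(doses, effect))
  treated <- logistic_solution(rep(day, length(doses)), params, rate = rates)
  ctrl <- logistic_solution(day, params)
  structure(data.frame(day = day, dose_ug_ml = doses,
                       viability = treated / ctrl),
            class = c("mtt_series", "data.frame"))
}

#' Apparent IC50 of a viability series
#'
#' The concentration at which viability crosses 0.5. The default method is
#' linear interpolation on log10 dose between the two bracketing doses; an
#' optional four-parameter logistic fit is available. If the series is
#' non-monotone beyond tolerance, a decreasing isotonic regression is
#' applied first and recorded in the method tag. When no dose reaches 50%
#' viability the IC50 is "not reached" (NA value, \code{reached = FALSE}).
#'
#' @param series an \code{mtt_series} (or data.frame with
#'   \code{dose_ug_ml} and \code{viability}); >= 3 positive doses required.
#' @param method \code{"interpolation"} (default) or \code{"ll4"}
#'   (four-parameter logistic least-squares fit).
#' @param tol monotonicity tolerance before pre-smoothing kicks in.
#' @return A list of class \code{apparent_ic50} with elements \code{ic50}
#'   (ug/mL or NA), \code{reached}, \code{method}, \code{day}.
#' @export
apparent_ic50 <- function(series, method = c("interpolation", "ll4"),
                          tol = 1e-8) {
  method <- match.arg(method)
  if (!all(c("dose_ug_ml", "viability") %in% names(series)))
    stop_domain("'series' needs columns dose_ug_ml and viability")
  df <- series[series$dose_ug_ml > 0, , drop = FALSE]
  if (nrow(df) < 3L)
    stop_domain("apparent IC50 extraction needs >= 3 positive doses")
  o <- order(df$dose_ug_ml)
  dose <- df$dose_ug_ml[o]
  v <- df$viability[o]
  day <- if ("day" %in% names(df)) df$day[o][1] else NA_real_
  # average replicates sharing a dose
  if (anyDuplicated(dose)) {
    v <- as.numeric(tapply(v, dose, mean))
    dose <- sort(unique(dose))
  }
  tag <- method
  if (any(diff(v) > tol)) {
    # monotone (decreasing) regression pre-smoothing
    v <- -stats::isoreg(log(dose), -v)$yf
    tag <- paste0(method, "+monotone")
  }

  if (method == "ll4") {
    ic <- fit_ll4_ic50(dose, v)
    if (is.na(ic))
      return(structure(list(ic50 = NA_real_, reached = FALSE,
                            method = tag, day = day),
                       class = "apparent_ic50"))
    return(structure(list(ic50 = ic, reached = TRUE, method = tag,
                          day = day),
                     class = "apparent_ic50"))
  }

  if (min(v) > 0.5)
    return(structure(list(ic50 = NA_real_, reached = FALSE, method = tag,
                          day = day),
                     class = "apparent_ic50"))
  i <- which(v <= 0.5)[1]
  if (i == 1L) {
    # already below 50% at the lowest tested dose: crossing lies below range
    return(structure(list(ic50 = dose[1], reached = TRUE,
                          method = paste0(tag, "+left-censored"), day = day),
                     class = "apparent_ic50"))
  }
  if (v[i] == 0.5) {
    ic <- dose[i]
  } else {
    ld1 <- log10(dose[i - 1]); ld2 <- log10(dose[i])
    ic <- 10^(ld1 + (0.5 - v[i - 1]) * (ld2 - ld1) / (v[i] - v[i - 1]))
  }
  structure(list(ic50 = ic, reached = TRUE, method = tag, day = day),
            class = "apparent_ic50")
}

# Least-squares 4-parameter logistic on log dose; returns the dose at
# which the fitted curve crosses 0.5 (NA if it never does).
fit_ll4_ic50 <- function(dose, v) {
  ld <- log(dose)
  obj <- function(th) {
    top <- stats::plogis(th[1]); bot <- top * stats::plogis(th[2])
    hill <- exp(th[3]); lec50 <- th[4]
    pred <- bot + (top - bot) / (1 + exp(hill * (ld - lec50)))
    sum((v - pred)^2)
  }
  st <- c(stats::qlogis(min(max(v), 1 - 1e-6)),
          stats::qlogis(0.25), 0, mean(ld))
  opt <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  top <- stats::plogis(opt$par[1]); bot <- top * stats::plogis(opt$par[2])
  hill <- exp(opt$par[3]); lec50 <- opt$par[4]
  if (top <= 0.5 || bot >= 0.5) return(NA_real_)
  # invert bot + (top - bot)/(1 + exp(hill (x - lec50))) = 0.5
  x <- lec50 + log((top - 0.5) / (0.5 - bot)) / hill
  exp(x)
}

#' @export
print.apparent_ic50 <- function(x, ...) {
  if (x$reached)
    cat(sprintf("apparent IC50 = %.4g ug/mL (day %g, %s)\n",
                x$ic50, x$day, x$method))
  else
    cat(sprintf("apparent IC50 not reached (day %g, %s)\n", x$day, x$method))
  invisible(x)
}

#' Apparent IC50 as a function of measurement day
#'
#' Simulates one MTT assay per requested day and extracts the apparent
#' IC50 from each — the endpoint readout drifts with measurement time even
#' though the underlying model parameters are fixed. "Not reached" entries
#' propagate as NA rows rather than aborting.
#'
#' @inheritParams simulate_mtt
#' @param days measurement days, strictly increasing (default the standard
#'   readout schedule 2, 4, 6, 8).
#' @param method IC50 extraction method, see \code{\link{apparent_ic50}}.
#' @return An object of class \code{apparent_ic50_curve}: a data.frame
#'   with columns \code{day}, \code{ic50_ug_ml}, \code{method},
#'   \code{reached}.
#' @export
ic50_vs_time <- function(params, effect, doses = mtt_dose_grid(),
                         days = c(2, 4, 6, 8),
                         method = c("interpolation", "ll4")) {
  method <- match.arg(method)
  check_num_vec(days, "days", lower = 0)
  if (is.unsorted(days, strictly = TRUE))
    stop_domain("'days' must be strictly increasing")
  rows <- lapply(days, function(d) {
    res <- apparent_ic50(simulate_mtt(params, effect, doses, d), method)
    data.frame(day = d, ic50_ug_ml = if (res$reached) res$ic50 else NA_real_,
               method = res$method, reached = res$reached)
  })
  structure(do.call(rbind, rows),
            class = c("apparent_ic50_curve", "data.frame"))
}

#' Compare two drug formulations sharing one growth model
#'
#' Tabulates per-day apparent IC50s for two fitted drug effects (e.g. free
#' drug vs nanoparticle-delivered drug) on the same cell line, their
#' ratio, and the model-level parameter ratios. Ratios are fold-changes of
#' B relative to A: \code{ic50_fold = IC50_A / IC50_B} (how many times
#' lower B's IC50 is) and \code{emax_fold = Emax_B / Emax_A}.
#'
#' @param effect_a,effect_b the two \code{\link{drug_effect}}s.
#' @param params the shared \code{\link{growth_parameters}}.
#' @inheritParams ic50_vs_time
#' @param labels character(2) naming the formulations.
#' @return A list of class \code{formulation_comparison} with elements
#'   \code{by_day} (data.frame: day, apparent IC50 A and B, their A/B
#'   ratio), \code{model_ic50_fold}, \code{model_emax_fold},
#'   \code{labels}.
#' @export
compare_formulations <- function(effect_a, effect_b, params,
                                 doses = mtt_dose_grid(),
                                 days = c(2, 4, 6, 8),
                                 labels = c("A", "B")) {
  stopifnot(inherits(effect_a, "drug_effect"),
            inherits(effect_b, "drug_effect"),
            inherits(params, "growth_parameters"))
  ca <- ic50_vs_time(params, effect_a, doses, days)
  cb <- ic50_vs_time(params, effect_b, doses, days)
  by_day <- data.frame(day = ca$day,
                       ic50_a = ca$ic50_ug_ml,
                       ic50_b = cb$ic50_ug_ml,
                       ratio_a_over_b = ca$ic50_ug_ml / cb$ic50_ug_ml)
  structure(list(by_day = by_day,
                 model_ic50_fold = effect_a$IC50 / effect_b$IC50,
                 model_emax_fold = effect_b$Emax / effect_a$Emax,
                 labels = labels),
            class = "formulation_comparison")
}

#' @export
print.formulation_comparison <- function(x, ...) {
  cat(sprintf("Formulation comparison: %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  model IC50 fold-decrease (A/B): %.4g\n", x$model_ic50_fold))
  cat(sprintf("  model Emax fold-increase (B/A): %.4g\n", x$model_emax_fold))
  print(x$by_day)
  invisible(x)
}
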