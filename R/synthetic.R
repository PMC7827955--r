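# Synthetic growth-curve and MTT datasets with the replicate structure of
# the real assays, so every pipeline stage is testable without lab data.

#' Noise model for synthetic datasets
#'
#' @param kind \code{"multiplicative-lognormal"} (count * exp(N(0, sigma)),
#'   proportional hemocytometer-style error; the default),
#'   \code{"additive-gaussian"} (count + N(0, sigma) in count units), or
#'   \code{"poisson-count"} (Poisson with mean equal to the model count;
#'   sigma is ignored).
#' @param sigma dispersion parameter, >= 0. sigma = 0 switches the noise
#'   (and integer rounding) off entirely.
#' @param seed RNG seed carried with the model; generators are
#'   deterministic given it.
#' @return A list of class \code{noise_model}.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal",
                                 "additive-gaussian", "poisson-count"),
                        sigma = 0.1, seed = NULL) {
  kind <- match.arg(kind)
  check_scalar_num(sigma, "sigma", 0)
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_model")
}

# Perturb model counts per the noise model. Counts are rounded to integers
# and floored at 0 whenever noise is actually applied; noise-free output
# stays exactly on the model trajectory.
apply_count_noise <- function(counts, noise) {
  n <- length(counts)
  if (noise$kind == "poisson-count")
    return(rpois(n, counts))
  if (noise$sigma == 0) return(counts)
  noisy <- switch(noise$kind,
    "multiplicative-lognormal" = counts * exp(rnorm(n, 0, noise$sigma)),
    "additive-gaussian" = counts + rnorm(n, 0, noise$sigma))
  pmax(round(noisy), 0)
}

#' Experimental design template
#'
#' Describes one assay layout: plating density, observation days, dose
#' grid and replicate count.
#'
#' @param plating_density seeded cells/well.
#' @param days observation days.
#' @param doses concentrations in ug/mL (0 allowed for control wells).
#' @param replicates wells counted per (dose, day) cell.
#' @param cell_line label.
#' @param label condition/formulation label for generated records.
#' @return A list of class \code{design_template}.
#' @export
design_template <- function(plating_density, days, doses, replicates = 3,
                            cell_line = "cells", label = "drug") {
  check_scalar_num(plating_density, "plating_density", 0, strict = TRUE)
  check_num_vec(days, "days", lower = 0)
  check_num_vec(doses, "doses", lower = 0)
  check_scalar_num(replicates, "replicates", 1)
  structure(list(plating_density = plating_density, days = days,
                 doses = sort(unique(doses)),
                 replicates = as.integer(replicates),
                 cell_line = cell_line, label = label),
            class = "design_template")
}

#' Named design presets
#'
#' \describe{
#'   \item{\code{"growth"}}{14-day cell-count time course: 1000 cells/well
#'     (densities of 500-2000 are typical; 1000 is the midpoint), counts
#'     every other day from day 2 to 14, doses
#'     \{0, 5e-5, 5e-4, 5e-3, 5e-2\} ug/mL, 3 replicate wells.}
#'   \item{\code{"mtt"}}{MTT viability plate: 5000 cells/well, readouts at
#'     days 2, 4, 6, 8, nine-point twofold dilution series from 0.00625 to
#'     1.6 ug/mL, 3 replicates.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to \code{\link{design_template}} fields.
#' @return A \code{\link{design_template}}.
#' @export
design_preset <- function(name, ...) {
  presets <- list(
    growth = list(plating_density = 1000, days = seq(2, 14, by = 2),
                  doses = c(0, 5e-5, 5e-4, 5e-3, 5e-2), replicates = 3,
                  cell_line = "MCF-7", label = "drug"),
    mtt = list(plating_density = 5000, days = c(2, 4, 6, 8),
               doses = mtt_dose_grid(), replicates = 3,
               cell_line = "MCF-7", label = "drug")
  )
  if (!name %in% names(presets))
    stop_domain("unknown preset '%s'; available: %s", name,
                paste(names(presets), collapse = ", "))
  args <- modifyList(presets[[name]], list(...))
  do.call(design_template, args)
}

#' Generate a noisy replicated growth dataset
#'
#' Noise-free logistic/Emax trajectories from the forward model, perturbed
#' per the noise model, replicated per the design. The generating truth is
#' recorded in the dataset attributes for recovery tests. Deterministic
#' given the seed.
#'
#' @param params true \code{\link{growth_parameters}}; \code{N0} is taken
#'   from the template's plating density.
#' @param effect true \code{\link{drug_effect}}.
#' @param template a \code{\link{design_template}} (e.g.
#'   \code{design_preset("growth")}).
#' @param noise a \code{\link{noise_model}}.
#' @param seed RNG seed; overrides the one carried by \code{noise}.
#' @return A \code{\link{growth_dataset}} with
#'   \code{replicates * length(doses) * length(days)} records.
#' @export
generate_growth_dataset <- function(params, effect,
                                    template = design_preset("growth"),
                                    noise = noise_model(), seed = NULL) {
  stopifnot(inherits(params, "growth_parameters"),
            inherits(effect, "drug_effect"),
            inherits(template, "design_template"),
            inherits(noise, "noise_model"))
  params <- growth_parameters(params$lambda, params$K,
                              template$plating_density)
  grid <- expand.grid(replicate = seq_len(template$replicates),
                      day = template$days,
                      dose_ug_ml = template$doses,
                      KEEP.OUT.ATTRS = FALSE)
  rates <- effective_rate(params, efficacy(grid$dose_ug_ml, effect))
  clean <- logistic_solution(grid$day, params, rate = rates)
  seed <- seed %||% noise$seed
  counts <- with_seed(seed, apply_count_noise(clean, noise))
  growth_dataset(data.frame(
    cell_line = template$cell_line,
    condition = ifelse(grid$dose_ug_ml == 0, "control", template$label),
    dose_ug_ml = grid$dose_ug_ml,
    day = grid$day,
    replicate = grid$replicate,
    count = counts
  ), plating_density = template$plating_density,
     truth = list(params = params, effect = effect, noise = noise,
                  seed = seed))
}

#' Generate a noisy MTT viability dataset over measurement days
#'
#' For every (day, replicate) a control well and one well per dose are
#' simulated; noise is applied to the underlying cell counts and viability
#' is the treated/control count ratio, so dose-0 entries are exactly 1 and
#' sigma = 0 reproduces \code{\link{simulate_mtt}} output.
#'
#' @inheritParams generate_growth_dataset
#' @param template a \code{\link{design_template}} (e.g.
#'   \code{design_preset("mtt")}).
#' @return An object of class \code{mtt_dataset}: a data.frame with
#'   columns \code{day}, \code{dose_ug_ml}, \code{replicate},
#'   \code{viability}, with the generating truth in its attributes.
#' @export
generate_mtt_dataset <- function(params, effect,
                                 template = design_preset("mtt"),
                                 noise = noise_model(), seed = NULL) {
  stopifnot(inherits(params, "growth_parameters"),
            inherits(effect, "drug_effect"),
            inherits(template, "design_template"),
            inherits(noise, "noise_model"))
  params <- growth_parameters(params$lambda, params$K,
                              template$plating_density)
  grid <- expand.grid(replicate = seq_len(template$replicates),
                      dose_ug_ml = template$doses,
                      day = template$days,
                      KEEP.OUT.ATTRS = FALSE)
  rates <- effective_rate(params, efficacy(grid$dose_ug_ml, effect))
  treated_clean <- logistic_solution(grid$day, params, rate = rates)
  ctrl_grid <- expand.grid(replicate = seq_len(template$replicates),
                           day = template$days, KEEP.OUT.ATTRS = FALSE)
  ctrl_clean <- logistic_solution(ctrl_grid$day, params)
  seed <- seed %||% noise$seed
  viab <- with_seed(seed, {
    treated <- apply_count_noise(treated_clean, noise)
    ctrl <- apply_count_noise(ctrl_clean, noise)
    key <- match(paste(grid$replicate, grid$day),
                 paste(ctrl_grid$replicate, ctrl_grid$day))
    treated / ctrl[key]
  })
  viab[grid$dose_ug_ml == 0] <- 1  # dose 0 is its own control
  structure(data.frame(day = grid$day, dose_ug_ml = grid$dose_ug_ml,
                       replicate = grid$replicate, viability = viab),
            truth = list(params = params, effect = effect, noise = noise,
                         seed = seed),
            class = c("mtt_dataset", "data.frame"))
}
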