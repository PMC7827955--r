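# The replicated cell-count container shared by the fitting and I/O layers.

#' Replicated cell-count dataset
#'
#' Long-format container for hemocytometer growth-curve data: one row per
#' counted well, indexed by condition, dose, day and replicate. Dose 0
#' encodes the untreated control arm.
#'
#' @param df a data.frame with columns \code{cell_line}, \code{condition},
#'   \code{dose_ug_ml}, \code{day}, \code{replicate}, \code{count}.
#' @param plating_density known seeded cell count per well (cells/well), or
#'   NULL when unknown.
#' @param truth optional list of true generating parameters (recorded by
#'   the synthetic-data generators for recovery tests).
#' @return An object of classes \code{growth_dataset} and
#'   \code{data.frame}.
#' @export
growth_dataset <- function(df, plating_density = NULL, truth = NULL) {
  required <- c("cell_line", "condition", "dose_ug_ml", "day",
                "replicate", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_domain("missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  check_num_vec(df$dose_ug_ml, "dose_ug_ml", lower = 0)
  check_num_vec(df$day, "day", lower = 0)
  check_num_vec(df$count, "count", lower = 0)
  if (!is.null(plating_density))
    check_scalar_num(plating_density, "plating_density", 0, strict = TRUE)
  structure(df,
            plating_density = plating_density,
            truth = truth,
            class = c("growth_dataset", "data.frame"))
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf(
    "Growth dataset: %d records, %d dose(s), days %g-%g, %s\n",
    nrow(x), length(unique(x$dose_ug_ml)), min(x$day), max(x$day),
    paste(unique(x$cell_line), collapse = "/")))
  pd <- attr(x, "plating_density")
  if (!is.null(pd)) cat(sprintf("  plating density: %g cells/well\n", pd))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Subset keeping class and metadata.
subset_dataset <- function(dataset, keep) {
  out <- as.data.frame(dataset)[keep, , drop = FALSE]
  rownames(out) <- NULL
  growth_dataset(out,
                 plating_density = attr(dataset, "plating_density"),
                 truth = attr(dataset, "truth"))
}

#' Extract the control (dose 0) arm of a dataset
#' @param dataset a \code{\link{growth_dataset}}.
#' @return The dose-0 records as a \code{growth_dataset}.
#' @export
control_subset <- function(dataset) {
  stopifnot(inherits(dataset, "growth_dataset"))
  subset_dataset(dataset, dataset$dose_ug_ml == 0)
}

#' Extract the treated (dose > 0) arm of a dataset
#' @param dataset a \code{\link{growth_dataset}}.
#' @param condition optional condition label to restrict to.
#' @return The dose > 0 records as a \code{growth_dataset}.
#' @export
treated_subset <- function(dataset, condition = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  keep <- dataset$dose_ug_ml > 0
  if (!is.null(condition)) keep <- keep & dataset$condition == condition
  subset_dataset(dataset, keep)
}
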