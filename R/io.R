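# Delimited-text readers/writers, run configuration, and the CTCF utility.

growth_table_columns <- c("cell_line", "condition", "dose_ug_ml", "day",
                          "replicate", "count")

#' Read a growth-curve table
#'
#' Reads a comma-separated, UTF-8, header-row table with columns
#' \code{cell_line, condition, dose_ug_ml, day, replicate, count} into a
#' \code{\link{growth_dataset}}. Malformed rows are reported with their
#' file line numbers. If a sidecar metadata file (\code{<stem>_meta.json},
#' as written by \code{\link{write_growth_table}}) exists, the plating
#' density and any recorded generating truth are restored from it.
#'
#' @param path file path.
#' @param plating_density override for the plating density (cells/well).
#' @return A \code{\link{growth_dataset}}.
#' @export
read_growth_table <- function(path, plating_density = NULL) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(growth_table_columns, names(df))
  if (length(missing_cols))
    stop_domain("schema error: missing column(s) %s",
                paste(missing_cols, collapse = ", "))
  for (col in c("dose_ug_ml", "day", "count")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) | vals < 0)
    if (length(bad))
      stop_domain("validation error in column '%s' at line(s) %s (negative or non-numeric)",
                  col, paste(bad + 1L, collapse = ", "))
    df[[col]] <- vals
  }
  meta_path <- meta_sidecar_path(path)
  truth <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    plating_density <- plating_density %||% meta$plating_density
    if (!is.null(meta$truth))
      truth <- list(
        params = growth_parameters(meta$truth$lambda, meta$truth$K,
                                   meta$truth$N0),
        effect = drug_effect(meta$truth$Emax, meta$truth$IC50,
                             meta$truth$Emax_upper %||% 2))
  }
  growth_dataset(df, plating_density = plating_density, truth = truth)
}

meta_sidecar_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0("_meta.json")
}

#' Write a growth-curve table (plus metadata sidecar)
#'
#' Writes the dataset as CSV and, when a plating density or generating
#' truth is attached, a \code{<stem>_meta.json} sidecar so a round-trip
#' read restores them.
#'
#' @param dataset a \code{\link{growth_dataset}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_growth_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "growth_dataset"))
  write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  pd <- attr(dataset, "plating_density")
  truth <- attr(dataset, "truth")
  if (!is.null(pd) || !is.null(truth)) {
    meta <- list(plating_density = pd)
    if (!is.null(truth))
      meta$truth <- list(lambda = truth$params$lambda, K = truth$params$K,
                         N0 = truth$params$N0, Emax = truth$effect$Emax,
                         IC50 = truth$effect$IC50,
                         Emax_upper = truth$effect$Emax_upper)
    jsonlite::write_json(meta, meta_sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read / write MTT viability tables
#'
#' CSV with columns \code{day, dose_ug_ml, replicate, viability}
#' (replicate optional on read).
#'
#' @param path file path.
#' @return \code{read_mtt_table}: an \code{mtt_dataset} data.frame.
#' @export
read_mtt_table <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "dose_ug_ml", "viability")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_domain("schema error: missing column(s) %s",
                paste(missing_cols, collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  structure(df[c("day", "dose_ug_ml", "replicate", "viability")],
            class = c("mtt_dataset", "data.frame"))
}

#' @rdname read_mtt_table
#' @param dataset an \code{mtt_dataset} or \code{mtt_series}.
#' @export
write_mtt_table <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Corrected total cell fluorescence (CTCF)
#'
#' CTCF = integrated density - cell area * mean background fluorescence,
#' the standard background correction for per-cell fluorescence
#' quantification of segmented microscopy images. May legitimately be
#' negative (a dim cell on a bright background) and is returned unclipped.
#'
#' @param integrated_density integrated fluorescence density over the
#'   outlined cell, arbitrary units (>= 0; vectorised).
#' @param cell_area area of the outlined cell, px^2 (>= 0).
#' @param mean_background mean background fluorescence, a.u./px^2 (>= 0).
#' @return CTCF value(s) in the units of \code{integrated_density}.
#' @examples
#' compute_ctcf(1000, 50, 20)  # 0
#' @export
compute_ctcf <- function(integrated_density, cell_area, mean_background) {
  check_num_vec(integrated_density, "integrated_density", lower = 0)
  check_num_vec(cell_area, "cell_area", lower = 0)
  check_num_vec(mean_background, "mean_background", lower = 0)
  integrated_density - cell_area * mean_background
}

#' Run configuration
#'
#' A serialisable bag of fit, design, noise and output settings; a run is
#' reproducible from its config plus seed alone.
#'
#' @param fit a \code{\link{fit_config}}.
#' @param preset design preset name (see \code{\link{design_preset}}).
#' @param noise a \code{\link{noise_model}}.
#' @param seed top-level RNG seed.
#' @param out_dir output directory.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(fit = fit_config(), preset = "growth",
                       noise = noise_model(), seed = 1, out_dir = ".") {
  structure(list(fit = fit, preset = preset, noise = noise, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- do.call(fit_config, as.list(raw$fit %||% list()))
  noise_args <- as.list(raw$noise %||% list())
  noise_args$seed <- noise_args$seed %||% NULL
  noise <- do.call(noise_model, noise_args)
  run_config(fit = fit, preset = raw$preset %||% "growth", noise = noise,
             seed = raw$seed %||% 1, out_dir = raw$out_dir %||% ".")
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Write a fit report
#'
#' Emits a flat key-value report for a fit in both machine-readable JSON
#' and human-readable text, with parameter names \code{lambda}, \code{K},
#' \code{Emax}, \code{IC50}.
#'
#' @param fit a \code{chemofit_fit} or \code{chemofit_two_step}.
#' @param path output path without extension; writes \code{<path>.json}
#'   and \code{<path>.txt}.
#' @return The JSON path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  flat <- flatten_fit(fit)
  jsonlite::write_json(flat, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  txt <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    sprintf("%s: %s", k, paste(format(v, digits = 10), collapse = ", "))
  }, character(1))
  writeLines(txt, paste0(path, ".txt"))
  invisible(paste0(path, ".json"))
}

flatten_fit <- function(fit) {
  if (inherits(fit, "chemofit_two_step"))
    return(c(flatten_fit(fit$control), flatten_fit(fit$treated)))
  est <- as.list(fit$estimates)
  out <- est
  names(out) <- names(est)
  out[[paste0(fit$step, "_ssr")]] <- fit$ssr
  out[[paste0(fit$step, "_converged")]] <- fit$converged
  if (!is.null(fit$ci_lower)) {
    for (p in names(fit$estimates)) {
      out[[paste0(p, "_ci_lower")]] <- unname(fit$ci_lower[p])
      out[[paste0(p, "_ci_upper")]] <- unname(fit$ci_upper[p])
    }
  }
  if (length(fit$flags))
    out[[paste0(fit$step, "_flags")]] <- paste(fit$flags, collapse = "; ")
  out
}
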