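#' Read a REES dataset from CSV
#'
#' Expects numeric columns \code{excitation_nm} and \code{emission_nm};
#' lines starting with \code{#} are treated as comments.  Points are sorted
#' by excitation wavelength and the file path recorded as provenance.
#'
#' @param path CSV file path.
#' @return A \code{\link{rees_dataset}}.
#' @export
read_rees_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  for (col in c("excitation_nm", "emission_nm"))
    if (!col %in% names(df))
      stop("column '", col, "' missing from ", path)
  ex <- suppressWarnings(as.numeric(df$excitation_nm))
  em <- suppressWarnings(as.numeric(df$emission_nm))
  if (anyNA(ex) || anyNA(em))
    stop("non-numeric values in ", path)
  if (length(ex) < 2) stop("fewer than 2 data rows in ", path)
  rees_dataset(ex, em, meta = path)
}

#' Write a REES dataset to CSV
#'
#' @param data a \code{\link{rees_dataset}}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_rees_csv <- function(data, path) {
  utils::write.csv(
    data.frame(excitation_nm = data$ex_nm, emission_nm = data$em_nm),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## flatten an fel_fit for reporting
.fit_block <- function(fit) {
  list(a_ev = fit$fel$a, b = fit$fel$b, x_gs = fit$fel$x_gs, m = fit$fel$m,
       span_ev = fel_span(fit$fel), slsq_nm2 = fit$slsq,
       n_free_params = fit$n_free_params, aic = fit$aic)
}

#' Write a machine-readable fit report
#'
#' Serializes a full analysis - sigmoid fit, per-candidate model table,
#' best-model block, landscape report and optional binding decomposition -
#' as schema-versioned JSON, with a CSV landscape table and a CSV of the
#' best model's theoretical curve alongside.
#'
#' @param comparison a \code{\link{scan_models}} result.
#' @param sig the \code{\link{fit_sigmoid}} result the comparison used.
#' @param lig the \code{\link{ligand_photophysics}}.
#' @param path output JSON path; the CSVs replace the extension with
#'   \code{_landscape.csv} and \code{_curve.csv}.
#' @param cfg a \code{\link{model_config}}.
#' @param decomposition optional \code{\link{binding_decomposition}}.
#' @return Invisibly, the JSON path.
#' @export
write_fit_report <- function(comparison, sig, lig, path,
                             cfg = model_config(), decomposition = NULL) {
  stopifnot(inherits(comparison, "model_comparison"))
  if (!any(comparison$table$ok)) stop("empty comparison: nothing to write")
  fit <- best_model(comparison)
  rep <- landscape_report(fit$fel, cfg)
  out <- list(
    schema = "reesfel-report/1",
    ligand = list(x_ct = lig$x_ct, dg_ctgs0_ev = lig$dg_ctgs0,
                  dg_ctgsn_ev = lig$dg_ctgsn,
                  reorg_ev = reorg_energy(lig, cfg$kappa)),
    sigmoid = list(em_blue_nm = sig$em_blue_nm, em_red_nm = sig$em_red_nm,
                   mid_nm = sig$mid_nm, width_nm = sig$width_nm,
                   residual_ss_nm2 = sig$residual_ss, n = sig$n),
    candidates = comparison$table,
    criterion = comparison$criterion,
    best = .fit_block(fit),
    landscape = list(minima_ev = rep$minima_ev, gaps_ev = rep$gaps_ev,
                     barriers_ev = rep$barriers_ev,
                     gs_reorg_ev = rep$gs_reorg_ev,
                     span_ev = rep$span_ev,
                     span_kcal_mol = convert_energy(rep$span_ev, "eV",
                                                    "kcal/mol"),
                     span_kbt = convert_energy(rep$span_ev, "eV", "kbT",
                                               cfg$temperature_K)))
  if (!is.null(decomposition))
    out$binding <- unclass(decomposition)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  base <- sub("\\.json$", "", path)
  write_landscape_csv(rep, paste0(base, "_landscape.csv"))
  write_curve_csv(simulate_rees_curve(lig, fit$fel, cfg),
                  paste0(base, "_curve.csv"))
  invisible(path)
}

#' Read a fit report back
#'
#' @param path JSON path written by \code{\link{write_fit_report}}.
#' @return The report as a list.
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
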