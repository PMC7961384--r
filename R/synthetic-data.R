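#' Default excitation grid over the model transition band
#'
#' Evenly spaced excitation wavelengths covering the central band of the
#' theoretical REES transition (by default 2-98% of the emission span),
#' mirroring the roughly ten datapoints per complex of typical REES
#' experiments.
#'
#' @param lig a \code{\link{ligand_photophysics}}.
#' @param fel a \code{\link{fel_spec}}.
#' @param cfg a \code{\link{model_config}}.
#' @param n number of points.
#' @param band emission-fraction limits of the transition band.
#' @return Excitation wavelengths (nm).
#' @export
transition_ex_grid <- function(lig, fel, cfg = model_config(), n = 10,
                               band = c(0.02, 0.98)) {
  crv <- simulate_rees_curve(lig, fel, cfg)
  em_lo <- min(crv$em_nm)
  em_hi <- max(crv$em_nm)
  targets <- em_lo + band * (em_hi - em_lo)
  oe <- order(crv$em_nm)
  ex_band <- stats::approx(crv$em_nm[oe], crv$ex_nm[oe], xout = targets,
                           ties = "ordered")$y
  seq(min(ex_band), max(ex_band), length.out = n)
}

#' Generate a synthetic REES dataset
#'
#' Samples the theoretical REES curve at the requested excitation
#' wavelengths and adds independent Gaussian noise to the emission
#' wavelengths.  Reproducible for a given seed.
#'
#' @param lig a \code{\link{ligand_photophysics}}.
#' @param fel ground-truth \code{\link{fel_spec}}.
#' @param cfg a \code{\link{model_config}}.
#' @param ex_grid_nm excitation wavelengths (nm), within the model curve's
#'   excitation range; defaults to \code{\link{transition_ex_grid}}.
#' @param noise_sd_nm standard deviation of the emission noise (nm, >= 0).
#' @param seed integer seed (mandatory when noise is added).
#' @return A \code{\link{rees_dataset}}.
#' @export
generate_rees_dataset <- function(lig, fel, cfg = model_config(),
                                  ex_grid_nm = NULL, noise_sd_nm = 0,
                                  seed = NULL) {
  stopifnot(noise_sd_nm >= 0)
  if (is.null(ex_grid_nm)) ex_grid_nm <- transition_ex_grid(lig, fel, cfg)
  crv <- simulate_rees_curve(lig, fel, cfg)
  em <- resample_curve(crv, ex_grid_nm)
  if (noise_sd_nm > 0) {
    if (is.null(seed))
      stop("a seed is required when noise_sd_nm > 0")
    em <- em + withr::with_seed(seed,
                                stats::rnorm(length(em), 0, noise_sd_nm))
  }
  rees_dataset(ex_grid_nm, em,
               meta = sprintf(
                 "synthetic: A=%g b=%g x_gs=%g m=%d noise_sd=%g seed=%s",
                 fel$a, fel$b, fel$x_gs, fel$m, noise_sd_nm,
                 if (is.null(seed)) "none" else seed))
}

#' Reference fixtures reconstructed from fitted parameters
#'
#' The raw experimental excitation/emission points behind the two kinase
#' case studies are unpublished; these fixtures are synthetic
#' reconstructions built from the published fitted parameters.  Each fixture
#' pairs a ligand parameter set with its best-fit quadratic landscape and a
#' noiseless 10-point dataset sampled from the resulting model curve:
#' \itemize{
#'   \item \code{p38a}: x_CT = 0.891, gaps 3.347/3.223 eV; quadratic
#'     landscape A = 0.00178 eV, x_GS = 0.153, 10 microstates.
#'   \item \code{aph}: x_CT = 1.076, gaps 3.172/3.015 eV; quadratic
#'     landscape A = 0.00172 eV, x_GS = 0.258, 5 microstates.
#' }
#'
#' @return A list of two fixtures, each with \code{ligand}, \code{fel},
#'   \code{dataset} and \code{abs_max_ev} (the absorption maximum implied by
#'   the ligand parameters).
#' @examples
#' fx <- make_reference_fixtures()
#' fx$p38a$dataset
#' @export
make_reference_fixtures <- function() {
  build <- function(x_ct, dg0, dgn, a, x_gs, m, name) {
    lig <- ligand_photophysics(x_ct = x_ct, dg_ctgs0 = dg0, dg_ctgsn = dgn)
    fel <- fel_spec(a = a, b = 2, x_gs = x_gs, m = m)
    ds <- generate_rees_dataset(lig, fel)
    attr(ds, "meta") <- paste0("synthetic reconstruction: ", name)
    list(ligand = lig, fel = fel, dataset = ds,
         abs_max_ev = lig$dg_ctgs0 + reorg_energy(lig))
  }
  list(p38a = build(0.891, 3.347, 3.223, 0.00178, 0.153, 10, "p38a-like"),
       aph = build(1.076, 3.172, 3.015, 0.00172, 0.258, 5, "APH-like"))
}

#' Parameter-recovery experiment
#'
#' The self-validation loop of the analysis chain: for each requested
#' landscape span, build the ground-truth quadratic landscape, simulate a
#' noiseless REES dataset, fit the Boltzmann sigmoid, then refit the
#' landscape with the energy scale, spacing, microstate count and exponent
#' all free (m scanned, b optimized per candidate), and compare recovered
#' span, m and b with their inputs.
#'
#' By default the free landscape fit targets the simulated datapoints
#' themselves (\code{target = "data"}).  Fitting through the four-parameter
#' sigmoid compression instead (\code{target = "sigmoid"}) is available for
#' comparison, but on noiseless synthetic curves the sigmoid's small,
#' systematic representation error is enough to bias the ill-conditioned
#' free-(m, b) inversion toward smooth low-m landscapes; see the methods
#' vignette.
#'
#' @param span_values landscape spans (eV) to test.
#' @param m_true,b_true ground-truth microstate count and exponent; A is
#'   derived as \code{span / (m_true - 1)^b_true}.
#' @param lig a \code{\link{ligand_photophysics}}.
#' @param cfg a \code{\link{model_config}}.
#' @param x_gs_true ground-truth microstate spacing.
#' @param noise_sd_nm emission noise (default 0: the deterministic
#'   benchmark).
#' @param seed integer seed for the noise generator.
#' @param m_range candidate microstate counts for the free fit.
#' @param target \code{"data"} (default): the free landscape fit targets
#'   the simulated datapoints; \code{"sigmoid"}: it targets the sigmoid
#'   representation.
#' @return An object of class \code{recovery_result}: a data frame with one
#'   row per span holding the input and recovered (span, m, b) and their
#'   relative errors, plus the per-row \code{fel_fit}s as an attribute.
#' @export
recovery_experiment <- function(span_values, m_true = 10, b_true = 2,
                                lig = ligand_photophysics(0.891, 3.347,
                                                          3.223),
                                cfg = model_config(), x_gs_true = 0.153,
                                noise_sd_nm = 0, seed = 20210304,
                                m_range = 3:20,
                                target = c("data", "sigmoid")) {
  stopifnot(all(span_values > 0), m_true >= 2)
  target <- match.arg(target)
  rows <- vector("list", length(span_values))
  fits <- vector("list", length(span_values))
  for (s in seq_along(span_values)) {
    span <- span_values[s]
    truth <- fel_spec(a = span / (m_true - 1)^b_true, b = b_true,
                      x_gs = x_gs_true, m = m_true)
    row <- tryCatch({
      ds <- generate_rees_dataset(lig, truth, cfg,
                                  noise_sd_nm = noise_sd_nm,
                                  seed = seed + s)
      sig <- fit_sigmoid(ds)
      cmp <- scan_models(if (target == "data") ds else sig, lig,
                         m_range = m_range, b_values = "free",
                         cfg = cfg, eval_ex_nm = ds$ex_nm)
      fit <- best_model(cmp)
      fits[[s]] <- fit
      span_out <- fel_span(fit$fel)
      data.frame(span_in = span, m_in = m_true, b_in = b_true,
                 span_out = span_out, m_out = fit$fel$m, b_out = fit$fel$b,
                 rel_err_span = abs(span_out - span) / span,
                 rel_err_m = abs(fit$fel$m - m_true) / m_true,
                 rel_err_b = abs(fit$fel$b - b_true) / b_true,
                 ok = TRUE)
    }, error = function(e) {
      data.frame(span_in = span, m_in = m_true, b_in = b_true,
                 span_out = NA_real_, m_out = NA_real_, b_out = NA_real_,
                 rel_err_span = NA_real_, rel_err_m = NA_real_,
                 rel_err_b = NA_real_, ok = FALSE)
    })
    rows[[s]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("recovery_result", "data.frame")
  out
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Parameter-recovery experiment\n")
  print.data.frame(round(as.data.frame(x), 4))
  if (all(x$ok)) {
    worst <- max(x$rel_err_span, x$rel_err_m, x$rel_err_b)
    cat(sprintf("  worst relative deviation: %.1f%%\n", 100 * worst))
  }
  invisible(x)
}
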