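#' Construct a REES dataset
#'
#' Observed excitation/peak-emission wavelength pairs.  Points are sorted by
#' excitation wavelength.
#'
#' @param ex_nm excitation wavelengths (nm).
#' @param em_nm peak emission wavelengths (nm), same length.
#' @param meta free-text provenance string.
#' @return An object of class \code{rees_dataset} (a data frame).
#' @export
rees_dataset <- function(ex_nm, em_nm, meta = "") {
  stopifnot(is.numeric(ex_nm), is.numeric(em_nm),
            length(ex_nm) == length(em_nm))
  if (anyDuplicated(ex_nm))
    stop("duplicate excitation wavelengths in dataset")
  o <- order(ex_nm)
  out <- data.frame(ex_nm = ex_nm[o], em_nm = em_nm[o])
  attr(out, "meta") <- meta
  class(out) <- c("rees_dataset", "data.frame")
  out
}

#' @export
print.rees_dataset <- function(x, ...) {
  cat(sprintf("REES dataset: %d points, excitation %.1f-%.1f nm\n",
              nrow(x), min(x$ex_nm), max(x$ex_nm)))
  if (nzchar(attr(x, "meta"))) cat("  meta:", attr(x, "meta"), "\n")
  invisible(x)
}

## Boltzmann sigmoid: em(lambda); width > 0, em_blue is the asymptote for
## lambda << mid (blue edge), em_red for lambda >> mid.
.sigmoid_fun <- function(ex_nm, em_blue, em_red, mid, width) {
  em_red + (em_blue - em_red) / (1 + exp((ex_nm - mid) / width))
}

#' Evaluate a fitted sigmoid
#'
#' @param sig a \code{\link{fit_sigmoid}} result.
#' @param ex_nm excitation wavelengths (nm).
#' @return Emission wavelengths (nm).
#' @export
predict_sigmoid <- function(sig, ex_nm) {
  .sigmoid_fun(ex_nm, sig$em_blue_nm, sig$em_red_nm, sig$mid_nm,
               sig$width_nm)
}

#' Fit a Boltzmann sigmoid to REES data
#'
#' Least-squares fit of the four-parameter sigmoid
#' \deqn{em(\lambda) = em_{red} + (em_{blue} - em_{red}) /
#'       (1 + \exp((\lambda - mid)/width))}
#' - two parameters controlling the endpoints and two controlling the
#' mid-point position and slope.  Fitting is Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}) from a multi-start grid of initial mid-points
#' and widths derived from the data range, with a Nelder-Mead fallback; the
#' best converged start (smallest residual sum of squares) wins.
#'
#' @param data a \code{\link{rees_dataset}} with at least 5 points.
#' @param flat_tol emission spread (nm) below which the data are treated as
#'   flat and a degenerate fit is returned.
#' @return An object of class \code{sigmoid_fit}: \code{em_blue_nm},
#'   \code{em_red_nm}, \code{mid_nm}, \code{width_nm}, \code{residual_ss}
#'   (nm^2), \code{n}, \code{degenerate}.
#' @export
fit_sigmoid <- function(data, flat_tol = 1e-8) {
  if (nrow(data) < 5)
    stop("sigmoid fitting needs at least 5 points spanning a transition; ",
         "got ", nrow(data))
  ex <- data$ex_nm
  em <- data$em_nm
  if (diff(range(em)) < flat_tol) {
    return(structure(list(em_blue_nm = mean(em), em_red_nm = mean(em),
                          mid_nm = mean(ex), width_nm = diff(range(ex)) / 4,
                          residual_ss = sum((em - mean(em))^2),
                          n = length(ex), degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  span <- diff(range(ex))
  mids <- stats::quantile(ex, c(0.25, 0.5, 0.75), names = FALSE)
  widths <- span * c(0.05, 0.15, 0.4)
  best <- NULL
  for (m0 in mids) for (w0 in widths) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        em ~ .sigmoid_fun(ex, em_blue, em_red, mid, width),
        start = list(em_blue = min(em), em_red = max(em), mid = m0,
                     width = w0),
        lower = c(em_blue = min(em) - 50, em_red = min(em) - 50,
                  mid = min(ex) - span, width = span * 1e-4),
        upper = c(em_blue = max(em) + 50, em_red = max(em) + 50,
                  mid = max(ex) + span, width = span * 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) {
    ## derivative-free fallback from the most informative start
    obj <- function(p) sum((em - .sigmoid_fun(ex, p[1], p[2], p[3],
                                              abs(p[4]) + 1e-8))^2)
    o <- stats::optim(c(min(em), max(em), stats::median(ex), span / 6), obj,
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- list(par = c(em_blue = o$par[1], em_red = o$par[2],
                         mid = o$par[3], width = abs(o$par[4]) + 1e-8),
                 rss = o$value)
  }
  p <- best$par
  structure(list(em_blue_nm = unname(p["em_blue"]),
                 em_red_nm = unname(p["em_red"]),
                 mid_nm = unname(p["mid"]), width_nm = unname(p["width"]),
                 residual_ss = best$rss, n = length(ex),
                 degenerate = FALSE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Boltzmann sigmoid fit\n")
  cat(sprintf("  asymptotes: %.2f -> %.2f nm   mid: %.2f nm   width: %.2f nm\n",
              x$em_blue_nm, x$em_red_nm, x$mid_nm, x$width_nm))
  cat(sprintf("  residual SS: %.4g nm^2 over %d points%s\n", x$residual_ss,
              x$n, if (isTRUE(x$degenerate)) " (degenerate/flat)" else ""))
  invisible(x)
}

#' Default evaluation grid for a sigmoid
#'
#' 50 evenly spaced excitation wavelengths across the sigmoid's 1-99%
#' transition band, \code{mid +/- width * log(99)}.
#'
#' @param sig a \code{sigmoid_fit}.
#' @param n number of points.
#' @param band transition fractions defining the edges.
#' @return Excitation wavelengths (nm).
#' @export
sigmoid_eval_grid <- function(sig, n = 50, band = c(0.01, 0.99)) {
  half <- sig$width_nm * log((1 - band[1]) / band[1])
  half2 <- sig$width_nm * log(band[2] / (1 - band[2]))
  seq(sig$mid_nm - half, sig$mid_nm + half2, length.out = n)
}

## evaluation points and reference emission values for a fitting target:
## a sigmoid_fit (evaluated on a grid) or a rees_dataset (its raw points)
.target_points <- function(target, eval_ex_nm) {
  if (inherits(target, "rees_dataset")) {
    list(ex = target$ex_nm, em = target$em_nm)
  } else if (inherits(target, "sigmoid_fit")) {
    if (is.null(eval_ex_nm)) eval_ex_nm <- sigmoid_eval_grid(target)
    list(ex = eval_ex_nm, em = predict_sigmoid(target, eval_ex_nm))
  } else {
    stop("fitting target must be a sigmoid_fit or a rees_dataset")
  }
}

#' Sum of least squares between a landscape model and a fitting target
#'
#' Simulates the theoretical REES curve for the candidate landscape,
#' resamples its emission wavelengths onto the evaluation excitation grid,
#' and returns the sum of squared deviations (nm^2) from the target: either
#' the sigmoid representation of the data (evaluated on the grid) or the
#' raw datapoints themselves when a \code{rees_dataset} is supplied.  Grid
#' points outside the model curve's excitation range are clipped with a
#' warning; an empty overlap is an error.
#'
#' @param fel candidate \code{\link{fel_spec}}.
#' @param lig fixed \code{\link{ligand_photophysics}}.
#' @param sig reference \code{\link{fit_sigmoid}} result, or a
#'   \code{\link{rees_dataset}} to fit the raw points directly.
#' @param eval_ex_nm evaluation excitation wavelengths (nm); defaults to
#'   \code{\link{sigmoid_eval_grid}} for a sigmoid target and the data
#'   points for a dataset target.
#' @param cfg a \code{\link{model_config}}.
#' @param mode absorption convention, see
#'   \code{\link{microstate_abs_energy}}.
#' @return Sum of least squares in nm^2.
#' @export
fel_objective <- function(fel, lig, sig, eval_ex_nm = NULL,
                          cfg = model_config(),
                          mode = c("printed", "strict")) {
  mode <- match.arg(mode)
  tp <- .target_points(sig, eval_ex_nm)
  crv <- .ensemble_curve(lig, fel, cfg, mode = mode)
  if (is.null(crv))
    stop("ensemble excitation energy is not strictly decreasing along x; ",
         "review grid bounds or model parameters (x_ct must be positive)")
  rng <- range(crv$ex_nm)
  keep <- tp$ex >= rng[1] & tp$ex <= rng[2]
  if (!any(keep))
    stop("model excitation range [", round(rng[1], 1), ", ",
         round(rng[2], 1), "] nm does not overlap the evaluation grid")
  if (!all(keep))
    warning("clipped ", sum(!keep),
            " evaluation points outside the model excitation range")
  em <- stats::approx(crv$ex_nm, crv$em_nm, xout = tp$ex[keep],
                      ties = "ordered")$y
  sum((em - tp$em[keep])^2)
}

#' Akaike information criterion from a least-squares fit
#'
#' \eqn{AIC = 2k + n \ln(LSQ)}: the parameter-count penalty plus the
#' log of the residual sum of squares scaled by the number of datapoints.
#'
#' @param k number of free parameters.
#' @param n number of datapoints.
#' @param lsq residual sum of squares (> 0).
#' @return AIC value.
#' @examples
#' aic(2, 10, 10) # 2k = 4 plus n ln(LSQ) = 23.0
#' @export
aic <- function(k, n, lsq) {
  stopifnot(n >= 1, k >= 0)
  if (!is.numeric(lsq) || lsq <= 0)
    stop("AIC requires a positive residual sum of squares")
  2 * k + n * log(lsq)
}

## shared L-BFGS-B multi-start over (log10 A, x_gs [, b])
.fel_optim <- function(objective, a_bounds, xgs_bounds, b_bounds = NULL,
                       n_starts = 3) {
  la <- seq(log10(a_bounds[1]), log10(a_bounds[2]), length.out = n_starts)
  xs <- seq(xgs_bounds[1], xgs_bounds[2], length.out = n_starts + 2)[
    2:(n_starts + 1)]
  starts <- expand.grid(la = la, xs = xs)
  lower <- c(log10(a_bounds[1]), xgs_bounds[1])
  upper <- c(log10(a_bounds[2]), xgs_bounds[2])
  if (!is.null(b_bounds)) {
    starts <- merge(starts, data.frame(b = c(1, 2, 3)))
    lower <- c(lower, b_bounds[1])
    upper <- c(upper, b_bounds[2])
  }
  best <- NULL
  fails <- 0
  for (r in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[r, ])
    o <- tryCatch(
      stats::optim(p0, objective, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 200, factr = 1e5)),
      error = function(e) NULL)
    if (is.null(o)) { fails <- fails + 1; next }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all ", fails, " optimizer starts failed; check that the ligand ",
         "parameters and the sigmoid describe compatible wavelength ranges")
  best
}

#' Fit the free-energy landscape to a sigmoid representation
#'
#' With the ligand photophysics fixed from experiment and the microstate
#' count \code{m} and exponent \code{b} held at the requested values,
#' optimizes the energy scale A and the microstate spacing x_GS to minimize
#' the sum of least squares between the theoretical REES curve and the
#' sigmoid (\code{\link{fel_objective}}).  Optimization is bounded L-BFGS-B
#' on (log10 A, x_GS) from a multi-start grid; with \code{b = "free"}, the
#' exponent is optimized too.
#'
#' @param sig reference \code{\link{fit_sigmoid}} result, or a
#'   \code{\link{rees_dataset}} to fit the raw points directly.
#' @param lig \code{\link{ligand_photophysics}}.
#' @param m number of microstates (>= 2).
#' @param b landscape exponent, or \code{"free"} to optimize it in
#'   \code{[0.5, 4]}.
#' @param cfg a \code{\link{model_config}}.
#' @param eval_ex_nm evaluation grid (nm); default
#'   \code{\link{sigmoid_eval_grid}}.
#' @param a_bounds,xgs_bounds box constraints for A (eV) and x_GS (eV^0.5).
#' @param n_free_params parameter count used for AIC; defaults to 2 (A,
#'   x_GS) plus 1 if \code{b} is free.  Pass 3 when the fit is one candidate
#'   of a scan over m.
#' @return An object of class \code{fel_fit}: \code{fel} (fitted
#'   \code{fel_spec}), \code{slsq} (nm^2), \code{n_free_params},
#'   \code{aic}, \code{n_eval}, and \code{at_bound} flagging a fit pinned
#'   at the lower bound of A or x_GS (no transition to explain: a flat or
#'   degenerate target).
#' @export
fit_fel <- function(sig, lig, m, b = 2, cfg = model_config(),
                    eval_ex_nm = NULL, a_bounds = c(1e-5, 0.2),
                    xgs_bounds = c(0.005, 0.5), n_free_params = NULL,
                    n_grid_fit = 401) {
  stopifnot(m >= 2)
  free_b <- identical(b, "free")
  if (!free_b) stopifnot(is.numeric(b), b > 0)
  n_eval <- length(.target_points(sig, eval_ex_nm)$ex)
  if (is.null(n_free_params)) n_free_params <- if (free_b) 3L else 2L
  ## optimize on a coarser coordinate sweep (interpolation error far below
  ## the fit tolerance), then score the winner on the configured grid
  cfg_fit <- cfg
  cfg_fit$n_grid <- as.integer(n_grid_fit)
  obj <- function(p) {
    fel <- fel_spec(a = 10^p[1], b = if (free_b) p[3] else b,
                    x_gs = p[2], m = m)
    tryCatch(
      suppressWarnings(fel_objective(fel, lig, sig, eval_ex_nm, cfg_fit)),
      error = function(e) 1e10)
  }
  best <- .fel_optim(obj, a_bounds, xgs_bounds,
                     b_bounds = if (free_b) c(0.5, 4) else NULL)
  fel <- fel_spec(a = 10^best$par[1], b = if (free_b) best$par[3] else b,
                  x_gs = best$par[2], m = m)
  slsq <- suppressWarnings(fel_objective(fel, lig, sig, eval_ex_nm, cfg))
  structure(list(fel = fel, slsq = slsq,
                 n_free_params = as.integer(n_free_params),
                 aic = aic(n_free_params, n_eval, max(slsq, 1e-300)),
                 n_eval = n_eval,
                 at_bound = fel$a <= a_bounds[1] * 1.0001 ||
                   fel$x_gs <= xgs_bounds[1] * 1.0001),
            class = "fel_fit")
}

#' @export
print.fel_fit <- function(x, ...) {
  cat(sprintf("FEL fit: A = %.5g eV, x_GS = %.3f, b = %.3g, m = %d\n",
              x$fel$a, x$fel$x_gs, x$fel$b, x$fel$m))
  cat(sprintf("  SLSQ = %.4g nm^2 (%d eval pts)   AIC = %.2f (k = %d)%s\n",
              x$slsq, x$n_eval, x$aic, x$n_free_params,
              if (x$at_bound) "   [A at lower bound: flat data?]" else ""))
  invisible(x)
}

#' Scan candidate landscape models
#'
#' Fits every combination of microstate count and exponent in the candidate
#' set and ranks them by the configured criterion.  Candidates whose fit
#' fails are retained as flagged entries rather than aborting the scan.
#' Ties are broken toward smaller m (parsimony).
#'
#' @param sig reference \code{\link{fit_sigmoid}} result, or a
#'   \code{\link{rees_dataset}} to fit the raw points directly.
#' @param lig \code{\link{ligand_photophysics}}.
#' @param m_range integer vector of candidate microstate counts.
#' @param b_values numeric vector of candidate exponents, or \code{"free"}.
#' @param cfg a \code{\link{model_config}}.
#' @param eval_ex_nm evaluation grid (nm).
#' @param criterion \code{"slsq"} (default) or \code{"aic"}.
#' @return An object of class \code{model_comparison}: \code{results} (one
#'   \code{fel_fit} or error entry per candidate), \code{table} (data frame
#'   of m, b, a, x_gs, slsq, aic, ok), \code{best} (index), and
#'   \code{criterion}.
#' @examples
#' \donttest{
#' fx <- make_reference_fixtures()
#' sig <- fit_sigmoid(fx$p38a$dataset)
#' cmp <- scan_models(sig, fx$p38a$ligand, m_range = 8:12, b_values = 2,
#'                    eval_ex_nm = fx$p38a$dataset$ex_nm)
#' cmp$table
#' }
#' @export
scan_models <- function(sig, lig, m_range, b_values = 2,
                        cfg = model_config(), eval_ex_nm = NULL,
                        criterion = c("slsq", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(length(m_range) >= 1)
  free_b <- identical(b_values, "free")
  cand <- if (free_b) data.frame(m = m_range, b = NA_real_)
          else expand.grid(b = b_values, m = m_range)[, c("m", "b")]
  ## parameter bookkeeping: A and x_GS always free; +1 if m is scanned;
  ## +1 if b is free
  k <- 2L + (length(m_range) > 1L) + free_b
  results <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    results[[r]] <- tryCatch(
      fit_fel(sig, lig, m = cand$m[r],
              b = if (free_b) "free" else cand$b[r], cfg = cfg,
              eval_ex_nm = eval_ex_nm, n_free_params = k),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "fel_fit_error"))
  }
  ok <- !vapply(results, inherits, logical(1), "fel_fit_error")
  if (!any(ok)) stop("every candidate model failed to fit")
  tab <- data.frame(
    m = cand$m,
    b = vapply(seq_along(results), function(r)
      if (ok[r]) results[[r]]$fel$b else NA_real_, numeric(1)),
    a = vapply(seq_along(results), function(r)
      if (ok[r]) results[[r]]$fel$a else NA_real_, numeric(1)),
    x_gs = vapply(seq_along(results), function(r)
      if (ok[r]) results[[r]]$fel$x_gs else NA_real_, numeric(1)),
    slsq = vapply(seq_along(results), function(r)
      if (ok[r]) results[[r]]$slsq else NA_real_, numeric(1)),
    aic = vapply(seq_along(results), function(r)
      if (ok[r]) results[[r]]$aic else NA_real_, numeric(1)),
    ok = ok)
  crit <- if (criterion == "slsq") tab$slsq else tab$aic
  crit[!ok] <- Inf
  ## ties toward smaller m: candidates are ordered by m within the table
  best <- order(crit, tab$m)[1]
  structure(list(results = results, table = tab, best = best,
                 criterion = criterion),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  b <- x$table[x$best, ]
  cat(sprintf("Model comparison over %d candidates (criterion: %s)\n",
              nrow(x$table), x$criterion))
  cat(sprintf("  best: m = %d, b = %.3g, A = %.5g eV, x_GS = %.3f, SLSQ = %.4g\n",
              b$m, b$b, b$a, b$x_gs, b$slsq))
  invisible(x)
}

#' Best fitted landscape of a comparison
#'
#' @param cmp a \code{\link{scan_models}} result.
#' @return The winning \code{fel_fit}.
#' @export
best_model <- function(cmp) {
  cmp$results[[cmp$best]]
}
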