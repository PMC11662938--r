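#' Fit a dissociation constant to an ensemble FRET titration
#'
#' Nonlinear least squares of observed FRET against the 1:1 ligand-depletion
#' (quadratic mass-balance) isotherm
#' `F(L) = fret_free + fb(L; Kd, S) * (fret_bound - fret_free)` with
#' `fb = ((Kd + S + L) - sqrt((Kd + S + L)^2 - 4 S L)) / (2 S)`.
#' The depletion form is required because the sensor concentration (5 nM in
#' the plate assay) is comparable to the fitted Kd, so free and total ligand
#' differ appreciably at the transition. Standard errors come from the
#' Jacobian at the optimum. Degenerate inputs are flagged rather than
#' raising: a flat curve gives `flag = "non_identifiable"`, a fitted Kd
#' beyond ten times the concentration range also flags non-identifiable, and
#' a Kd collapsing to zero flags `"near_stoichiometric"`.
#'
#' @param curve A `titration_curve` (from [simulate_titration]) or data
#'   frame with columns `ligand_conc` and `fret`.
#' @param sensor_conc Sensor concentration (nM); taken from the curve
#'   attribute when present.
#' @return An object of class `titration_fit`: list with `kd`, `fret_free`,
#'   `fret_bound`, `se` (named vector), `flag` (`"ok"`,
#'   `"non_identifiable"` or `"near_stoichiometric"`), `converged`,
#'   `fitted`, `residuals`.
#' @export
fit_kd <- function(curve, sensor_conc = NULL) {
  if (is.null(sensor_conc)) sensor_conc <- attr(curve, "sensor_conc")
  stopifnot(!is.null(sensor_conc), sensor_conc > 0)
  L <- curve$ligand_conc
  y <- curve$fret
  if (length(L) < 5L) stop("need at least 5 concentrations")
  o <- order(L)
  L <- L[o]; y <- y[o]
  S <- sensor_conc

  span <- diff(range(y))
  noise_guess <- mad(diff(y)) / sqrt(2)
  if (span < 1e-12 || span < 4 * noise_guess / sqrt(length(y))) {
    # flat curve: no transition to fit
    return(structure(
      list(kd = NA_real_, fret_free = mean(y), fret_bound = mean(y),
           se = c(kd = NA_real_, fret_free = NA_real_,
                  fret_bound = NA_real_),
           flag = "non_identifiable", converged = FALSE,
           fitted = rep(mean(y), length(y)), residuals = y - mean(y)),
      class = "titration_fit"
    ))
  }

  # start values: plateaus from the extremes, Kd from the half-rise point
  f0 <- min(y); f1 <- max(y)
  half <- (f0 + f1) / 2
  kd0 <- tryCatch({
    cross <- approx(y, L, xout = half, ties = mean)$y
    max(min(cross, max(L)), min(L) / 10, 1e-4)
  }, error = function(e) sqrt(max(L) * min(L)))
  if (!is.finite(kd0)) kd0 <- sqrt(max(L) * min(L))

  try_nls <- function(kd_start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ f0p + bound_fraction_depletion(L, kd, S) * (f1p - f0p),
        start = list(kd = kd_start, f0p = f0, f1p = f1),
        lower = c(0, -Inf, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
  }
  fit <- try_nls(kd0)
  if (is.null(fit)) {
    # profile Kd on a grid (including the stoichiometric limit Kd = 0),
    # solving the plateaus by linear least squares at each Kd
    grid <- c(0, 10^seq(log10(max(min(L) / 100, 1e-6)),
                        log10(10 * max(L)), length.out = 120))
    prof <- vapply(grid, function(kd) {
      fb <- bound_fraction_depletion(L, kd, S)
      co <- tryCatch(coef(lm(y ~ fb)), error = function(e) c(NA, NA))
      if (anyNA(co)) return(Inf)
      sum((y - co[1] - co[2] * fb)^2)
    }, numeric(1))
    kd_best <- grid[which.min(prof)]
    fit <- try_nls(max(kd_best, 1e-6))
    if (is.null(fit)) {
      fb <- bound_fraction_depletion(L, kd_best, S)
      co <- coef(lm(y ~ fb))
      flag <- if (kd_best <= 1e-3) "near_stoichiometric" else
        if (kd_best > 10 * max(L)) "non_identifiable" else "ok"
      return(structure(
        list(kd = kd_best, fret_free = unname(co[1]),
             fret_bound = unname(co[1] + co[2]),
             se = c(kd = NA_real_, fret_free = NA_real_,
                    fret_bound = NA_real_),
             flag = flag, converged = FALSE,
             fitted = unname(co[1] + co[2] * fb),
             residuals = unname(y - co[1] - co[2] * fb),
             ligand_conc = L, sensor_conc = S),
        class = "titration_fit"
      ))
    }
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, 3L))
  flag <- "ok"
  if (cf[["kd"]] > 10 * max(L)) flag <- "non_identifiable"
  if (cf[["kd"]] <= 1e-3) flag <- "near_stoichiometric"
  structure(
    list(kd = cf[["kd"]], fret_free = cf[["f0p"]], fret_bound = cf[["f1p"]],
         se = c(kd = unname(se[1L]), fret_free = unname(se[2L]),
                fret_bound = unname(se[3L])),
         flag = flag, converged = TRUE,
         fitted = as.numeric(fitted(fit)),
         residuals = as.numeric(residuals(fit)),
         ligand_conc = L, sensor_conc = S),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit: Kd = %.4g nM (SE %.2g), flag = %s>\n",
              x$kd, x$se[["kd"]], x$flag))
  invisible(x)
}
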