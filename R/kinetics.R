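#' Spectrophotometric assay constants
#'
#' Extinction coefficients used throughout the enzyme assays: the product
#' veratraldehyde at 310 nm (9.3 mM^-1 cm^-1) for activity, and the heme
#' Soret band at 409 nm (168 mM^-1 cm^-1) for enzyme concentration.
#'
#' @param epsilon_product product extinction coefficient, mM^-1 cm^-1.
#' @param epsilon_soret heme Soret extinction coefficient, mM^-1 cm^-1.
#' @param path_cm cuvette path length, cm.
#' @export
assay_constants <- function(epsilon_product = 9.3, epsilon_soret = 168,
                            path_cm = 1) {
  stopifnot(epsilon_product > 0, epsilon_soret > 0, path_cm > 0)
  list(epsilon_product = epsilon_product, epsilon_soret = epsilon_soret,
       path_cm = path_cm)
}

#' Specific activity from an absorbance slope
#'
#' Beer-Lambert conversion of the initial-rate absorbance slope into
#' product formation (one unit U = 1 µmol product per minute), per mg of
#' enzyme.
#'
#' @param abs_slope absorbance change, A per minute (>= 0).
#' @param enzyme_mg enzyme mass in the reaction, mg (> 0).
#' @param volume_ml reaction volume, ml.
#' @param constants an [assay_constants()] list.
#' @return Specific activity, U per mg.
#' @export
specific_activity <- function(abs_slope, enzyme_mg, volume_ml = 1,
                              constants = assay_constants()) {
  if (abs_slope < 0) stop("absorbance slope must be non-negative")
  stopifnot(enzyme_mg > 0, volume_ml > 0)
  conc_mM_per_min <- abs_slope / (constants$epsilon_product *
                                  constants$path_cm)
  umol_per_min <- conc_mM_per_min * volume_ml  # mM * ml = µmol
  umol_per_min / enzyme_mg
}

#' Enzyme concentration from the heme Soret band
#'
#' @param a409 absorbance at 409 nm.
#' @param constants an [assay_constants()] list.
#' @return Holoenzyme concentration, mM.
#' @export
soret_concentration <- function(a409, constants = assay_constants()) {
  stopifnot(a409 >= 0)
  a409 / (constants$epsilon_soret * constants$path_cm)
}

#' Fit a first-order thermal deactivation constant
#'
#' Linear regression of ln(residual activity) on time; the deactivation
#' constant kd is minus the slope, and the half-life is ln(2)/kd.
#' Activities are normalised to the t = 0 measurement first; non-positive
#' activities (whose log is undefined) are excluded with a message.
#'
#' @param time_min times, minutes (non-negative, increasing).
#' @param activity residual activities (fraction of the initial value).
#' @param normalize divide by the t = 0 activity first?
#' @return Object of class `deactivation_fit`: `kd` (min^-1), `kd_se`,
#'   `kd_ci` (95%), `t_half` (min, ln 2 / kd), `r_squared`, `n_used`,
#'   `n_excluded`, `negative_kd` flag (activity rising with time), `lm`.
#' @examples
#' t <- seq(0, 300, by = 30)
#' fit <- fit_deactivation(t, exp(-0.01 * t))
#' fit$kd      # 0.01
#' fit$t_half  # 69.3 min
#' @export
fit_deactivation <- function(time_min, activity, normalize = TRUE) {
  stopifnot(length(time_min) == length(activity),
            all(time_min >= 0), !is.unsorted(time_min))
  if (normalize) {
    a0 <- activity[which.min(time_min)]
    if (!is.finite(a0) || a0 <= 0) stop("t = 0 activity must be positive")
    activity <- activity / a0
  }
  keep <- is.finite(activity) & activity > 0
  if (any(!keep)) {
    message("fit_deactivation: excluded ", sum(!keep),
            " non-positive activity point(s) from the log fit")
  }
  if (sum(keep) < 3L) stop("need at least 3 positive-activity points")
  t <- time_min[keep]
  y <- log(activity[keep])
  fit <- stats::lm(y ~ t)
  kd <- -unname(stats::coef(fit)[2L])
  # exact data triggers the harmless perfect-fit note from summary.lm
  fit_summary <- suppressWarnings(summary(fit))
  se <- fit_summary$coefficients[2L, 2L]
  ci <- suppressWarnings(-rev(unname(stats::confint(fit)[2L, ])))
  negative <- kd < 0
  if (negative) warning("fitted kd is negative (activity rising with time)")
  out <- list(kd = kd, kd_se = se, kd_ci = ci,
              t_half = if (kd > 0) log(2) / kd else NA_real_,
              r_squared = fit_summary$r.squared,
              n_used = sum(keep), n_excluded = sum(!keep),
              negative_kd = negative, lm = fit)
  class(out) <- "deactivation_fit"
  out
}

#' @export
print.deactivation_fit <- function(x, ...) {
  cat(sprintf("First-order deactivation: kd = %.4g min^-1 (se %.2g), t1/2 = %s\n",
              x$kd, x$kd_se,
              if (is.na(x$t_half)) "undefined (kd <= 0)"
              else sprintf("%.1f min", x$t_half)))
  cat(sprintf("  n = %d (%d excluded), R^2 = %.4f\n",
              x$n_used, x$n_excluded, x$r_squared))
  invisible(x)
}

#' Half-life from a deactivation constant
#'
#' @param kd first-order deactivation constant, min^-1 (> 0).
#' @return t1/2 = ln(2)/kd, minutes.
#' @export
half_life <- function(kd) {
  if (any(kd <= 0)) stop("kd must be positive")
  log(2) / kd
}

#' Fold improvement in half-life
#'
#' @param t_half_variant,t_half_ref half-lives, same unit.
#' @return Ratio variant / reference; swapping arguments inverts it.
#' @export
fold_improvement <- function(t_half_variant, t_half_ref) {
  stopifnot(t_half_variant > 0, t_half_ref > 0)
  t_half_variant / t_half_ref
}

#' Fit Michaelis-Menten saturation kinetics
#'
#' Nonlinear least squares of v = Vmax * S / (KM + S), with starting
#' values Vmax0 = max rate and KM0 = substrate concentration at half the
#' maximum rate, and parameters bounded positive. When the enzyme
#' concentration is supplied, kcat = Vmax / \[E\] and kcat/KM are reported.
#'
#' @param conc_uM substrate concentrations, µM (>= 4 points).
#' @param rate observed rates (any consistent unit; Vmax inherits it).
#' @param enzyme_conc optional enzyme concentration in the same
#'   concentration unit family as Vmax/kcat (e.g. µM when rates are µM/s).
#' @return Object of class `mm_fit`: `vmax`, `km` (µM), standard errors,
#'   `kcat`, `kcat_over_km` (when `enzyme_conc` given), `km_boundary`
#'   flag (fit pinned at the lower KM bound, rates already saturated),
#'   and the underlying `nls` fit.
#' @examples
#' s <- c(50, 100, 200, 400, 800, 1200, 1600, 2000)
#' v <- 10 * s / (200 + s)
#' fit_michaelis_menten(s, v)$km  # 200
#' @export
fit_michaelis_menten <- function(conc_uM, rate, enzyme_conc = NULL) {
  stopifnot(length(conc_uM) == length(rate), all(conc_uM > 0),
            all(rate >= 0))
  if (length(unique(conc_uM)) < 4L) {
    stop("need rates at >= 4 distinct substrate concentrations")
  }
  vmax0 <- max(rate)
  km0 <- conc_uM[which.min(abs(rate - vmax0 / 2))]
  km_lower <- min(conc_uM) * 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ vmax * conc_uM / (km + conc_uM),
                      start = list(vmax = vmax0, km = max(km0, km_lower)),
                      lower = c(vmax = 1e-12, km = km_lower),
                      control = minpack.lm::nls.lm.control(maxiter = 200L)),
    error = function(e) {
      stop("Michaelis-Menten fit failed (starts vmax0 = ", signif(vmax0, 4L),
           ", km0 = ", signif(km0, 4L), "): ", conditionMessage(e))
    })
  est <- summary(fit)$coefficients
  km <- est["km", "Estimate"]
  out <- list(vmax = est["vmax", "Estimate"], vmax_se = est["vmax", "Std. Error"],
              km = km, km_se = est["km", "Std. Error"],
              km_boundary = km <= km_lower * (1 + 1e-6),
              nls = fit)
  if (!is.null(enzyme_conc)) {
    stopifnot(enzyme_conc > 0)
    out$kcat <- out$vmax / enzyme_conc
    out$kcat_over_km <- out$kcat / out$km
  }
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.4g (se %.2g), KM = %.4g uM (se %.2g)%s\n",
              x$vmax, x$vmax_se, x$km, x$km_se,
              if (x$km_boundary) " [KM at lower bound: rates saturated]" else ""))
  if (!is.null(x$kcat)) {
    cat(sprintf("  kcat = %.4g, kcat/KM = %.4g\n", x$kcat, x$kcat_over_km))
  }
  invisible(x)
}
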