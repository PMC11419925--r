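#' Per-variant ratio regressors of a panel
#'
#' Expands a variant panel into the five regressors behind the HemeLock
#' index: the four frequency/distance ratios (zero when the frequency is
#' zero) and the inverse residue volume at the contact position.
#'
#' @param panel data.frame with columns `aa181`, `BBCHI`, `BBCHD`, `SCHI`,
#'   `SCHD`, `SCCHI`, `SCCHD`, `SCSBI`, `SCSBD`.
#' @param volumes named volume table.
#' @return Numeric matrix with columns `x1`..`x5`.
#' @export
panel_ratios <- function(panel, volumes = aa_volumes()) {
  need <- c("aa181", "BBCHI", "BBCHD", "SCHI", "SCHD", "SCCHI", "SCCHD",
            "SCSBI", "SCSBD")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(panel)
  x <- matrix(0, nrow = n, ncol = 5L,
              dimnames = list(panel$variant, paste0("x", 1:5)))
  pairs <- list(c("BBCHI", "BBCHD"), c("SCHI", "SCHD"),
                c("SCCHI", "SCCHD"), c("SCSBI", "SCSBD"))
  for (j in 1:4) {
    for (i in seq_len(n)) {
      x[i, j] <- safe_ratio(panel[[pairs[[j]][1L]]][i],
                            panel[[pairs[[j]][2L]]][i])
    }
  }
  x[, 5L] <- 1 / volumes[canonical_aa(panel$aa181)]
  x
}

panel_index <- function(panel, weights, volumes = aa_volumes()) {
  x <- panel_ratios(panel, volumes)
  as.vector(x %*% c(weights$w1, weights$w2, weights$w3, weights$w4,
                    weights$w5))
}

ols_ab <- function(index, tm) {
  sx <- stats::sd(index)
  if (!is.finite(sx) || sx < 1e-12) stop("degenerate fit: all indices equal")
  fit <- stats::lm(tm ~ index)
  ab <- unname(stats::coef(fit))
  sst <- sum((tm - mean(tm))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst < 1e-12) 0 else 1 - ssr / sst
  list(a = ab[2L], b = ab[1L], r_squared = r2,
       mse = mean(stats::residuals(fit)^2), lm = fit)
}

#' Fit the HemeLock index-to-Tm model
#'
#' Fits `Tm = a * index(w) + b` to a variant panel. When `weights` is
#' supplied only the linear coefficients (a, b) are estimated by ordinary
#' least squares; otherwise the interaction weights w1..w4 are optimised
#' (non-negative, w5 anchored at `anchor_w5` to fix the scale degeneracy —
#' rescaling the whole weight vector is absorbed by a) to maximise the
#' coefficient of determination, by multi-start bounded local search under
#' a fixed seed. One start is the closed-form warm start from the multiple
#' regression of Tm on the five per-term ratio regressors.
#'
#' @param panel data.frame with columns `variant`, `aa181`, the eight
#'   frequency/distance fields, and `Tm_obs` (°C).
#' @param weights optional fixed [hemelock_weights()].
#' @param anchor_w5 value at which w5 is held when weights are optimised.
#' @param n_starts random multi-starts in addition to the warm starts.
#' @param seed seed for the random starts.
#' @param volumes named volume table.
#' @return Object of class `hemelock` with `weights`, `a`, `b`,
#'   `r_squared`, `mse`, `index`, `fitted`, `residuals` and the usual
#'   methods (`print`, `summary`, `coef`, `predict`, `plot`, `simulate`,
#'   `confint`).
#' @examples
#' panel <- make_variant_panel(seed = 1)$panel
#' fit <- hemelock(panel, weights = hemelock_weights())
#' coef(fit)
#' @export
hemelock <- function(panel, weights = NULL, anchor_w5 = 282.3,
                     n_starts = 10L, seed = 1L, volumes = aa_volumes()) {
  cl <- match.call()
  if (!("Tm_obs" %in% names(panel))) stop("panel lacks Tm_obs")
  tm <- panel$Tm_obs
  if (any(tm <= 0 | tm >= 120)) stop("Tm_obs outside the plausible 0-120 C")
  x <- panel_ratios(panel, volumes)
  n <- nrow(panel)

  if (!is.null(weights)) {
    if (n < 2L) stop("need at least 2 variants to fit (a, b)")
    w <- weights
    fixed <- TRUE
  } else {
    if (n < 3L) stop("need at least 3 variants to optimise weights")
    fixed <- FALSE
    wvec <- function(w14) c(w14, anchor_w5)
    objective <- function(w14) {
      idx <- as.vector(x %*% wvec(w14))
      if (stats::sd(idx) < 1e-12) return(1)  # minimising 1 - R^2
      r <- suppressWarnings(stats::cor(idx, tm))
      if (!is.finite(r)) return(1)
      1 - r^2
    }
    starts <- list(c(2.974, 0.9201, 0, 0))
    # warm start: unconstrained multiple OLS on the ratio regressors,
    # refactored as a * w and clamped to the non-negative orthant
    co <- tryCatch(stats::coef(stats::lm(tm ~ x)), error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co[-1L])) && abs(co[6L]) > 1e-12) {
      a0 <- co[6L] / anchor_w5
      starts <- c(starts, list(pmax(0, unname(co[2:5]) / a0)))
    }
    set.seed(seed)
    for (k in seq_len(n_starts)) {
      starts <- c(starts, list(stats::runif(4L, 0, 10)))
    }
    best <- NULL
    for (s in starts) {
      opt <- tryCatch(
        stats::optim(s, objective, method = "L-BFGS-B", lower = 0,
                     upper = 1e4, control = list(maxit = 500L)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    if (is.null(best)) stop("weight optimisation failed on every start")
    w <- hemelock_weights(best$par[1L], best$par[2L], best$par[3L],
                          best$par[4L], anchor_w5)
  }

  wv <- c(w$w1, w$w2, w$w3, w$w4, w$w5)
  idx <- as.vector(x %*% wv)
  ab <- ols_ab(idx, tm)
  model <- structure(list(a = ab$a, b = ab$b, weights = w,
                          provenance = if (fixed) "fixed weights + OLS"
                                       else "multi-start weight fit + OLS"),
                     class = "hemelock_model")
  out <- list(call = cl, panel = panel, ratios = x, weights = w,
              a = ab$a, b = ab$b, model = model,
              r_squared = ab$r_squared, mse = ab$mse, n = n,
              index = idx, fitted = stats::fitted(ab$lm),
              residuals = stats::residuals(ab$lm), lm = ab$lm,
              fixed_weights = fixed, anchor_w5 = anchor_w5,
              volumes = volumes)
  class(out) <- "hemelock"
  out
}

#' @export
print.hemelock <- function(x, digits = 4L, ...) {
  cat("HemeLock index-to-Tm linear model\n")
  cat(sprintf("  Tm = %.*g * index + %.*g  (n = %d, R^2 = %.3f, MSE = %.3g)\n",
              digits, x$a, digits, x$b, x$n, x$r_squared, x$mse))
  cat(sprintf("  weights%s: w1=%.4g w2=%.4g w3=%.4g w4=%.4g w5=%.4g\n",
              if (x$fixed_weights) " (fixed)" else " (fitted, w5 anchored)",
              x$weights$w1, x$weights$w2, x$weights$w3, x$weights$w4,
              x$weights$w5))
  invisible(x)
}

#' @export
coef.hemelock <- function(object, ...) {
  c(w1 = object$weights$w1, w2 = object$weights$w2, w3 = object$weights$w3,
    w4 = object$weights$w4, w5 = object$weights$w5,
    a = object$a, b = object$b)
}

#' @export
summary.hemelock <- function(object, ...) {
  tab <- data.frame(
    variant = object$panel$variant %||% rownames(object$panel),
    aa181 = canonical_aa(object$panel$aa181),
    index = object$index,
    observed = object$panel$Tm_obs,
    predicted = as.vector(object$fitted)
  )
  tab$difference <- tab$predicted - tab$observed
  out <- list(coefficients = coef(object), table = tab,
              r_squared = object$r_squared, mse = object$mse, n = object$n,
              fixed_weights = object$fixed_weights)
  class(out) <- "summary.hemelock"
  out
}

#' @export
print.summary.hemelock <- function(x, ...) {
  cat("HemeLock model summary\n")
  print(round(x$coefficients, 4L))
  cat(sprintf("R^2 = %.4f, MSE = %.4g, n = %d\n", x$r_squared, x$mse, x$n))
  print(x$table, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' @export
predict.hemelock <- function(object, newdata = NULL, ...) {
  idx <- if (is.null(newdata)) object$index
         else panel_index(newdata, object$weights, object$volumes)
  object$a * idx + object$b
}

#' @export
fitted.hemelock <- function(object, ...) as.vector(object$fitted)

#' @export
residuals.hemelock <- function(object, ...) as.vector(object$residuals)

#' @export
confint.hemelock <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$lm, level = level)
  rownames(ci) <- c("b", "a")
  ci <- ci[c("a", "b"), , drop = FALSE]
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.hemelock <- function(x, ...) {
  graphics::plot(x$index, x$panel$Tm_obs, xlab = "HemeLock index",
                 ylab = expression(T[m] ~ (degree * C)),
                 main = sprintf("Tm = %.3f index + %.2f (R² = %.3f)",
                                x$a, x$b, x$r_squared), pch = 19, ...)
  graphics::abline(a = x$b, b = x$a, col = "firebrick")
  invisible(x)
}

#' @export
simulate.hemelock <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(sum(object$residuals^2) / max(1L, object$n - 2L))
  out <- as.data.frame(replicate(nsim, {
    object$fitted + stats::rnorm(object$n, sd = sigma)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Evaluate a model on a panel
#'
#' Computes indices with the model's weights, predicts Tm, and reports
#' R² (1 - SSres/SStot against the observed values), MSE (denominator n)
#' and the per-variant residual table with `difference = predicted -
#' observed`.
#'
#' @param panel variant panel with `Tm_obs`.
#' @param model a `hemelock_model` (e.g. [published_model()] or the
#'   `$model` of a [hemelock()] fit).
#' @param volumes named volume table.
#' @return list with `r_squared`, `mse`, `table`.
#' @export
evaluate_panel <- function(panel, model = published_model(),
                           volumes = aa_volumes()) {
  idx <- panel_index(panel, model$weights, volumes)
  pred <- model$a * idx + model$b
  obs <- panel$Tm_obs
  sst <- sum((obs - mean(obs))^2)
  ssr <- sum((obs - pred)^2)
  list(
    r_squared = if (sst < 1e-12) 0 else 1 - ssr / sst,
    mse = mean((pred - obs)^2),
    table = data.frame(
      variant = panel$variant %||% seq_len(nrow(panel)),
      index = idx, observed = obs, predicted = pred,
      difference = pred - obs)
  )
}

#' Refit the size weight w5 for one isozyme
#'
#' Holds the interaction weights and the linear coefficients (a, b) of a
#' base model fixed and finds the w5 minimising the mean squared Tm
#' prediction error on a panel — the per-isozyme adjustment used when a
#' model trained on one isozyme is transferred to a homologue. The
#' prediction is linear in w5, so the error curve is an exact parabola;
#' a 1-D minimisation on `interval` locates its minimum.
#'
#' @param panel variant panel with `Tm_obs` (>= 2 variants).
#' @param base_model a `hemelock_model`.
#' @param interval search interval for w5.
#' @param volumes named volume table.
#' @return list with `w5`, `mse_before` (base w5), `mse_after`, and
#'   `model`, the adjusted `hemelock_model`.
#' @export
refit_w5 <- function(panel, base_model = published_model(),
                     interval = c(0, 1000), volumes = aa_volumes()) {
  if (nrow(panel) < 2L) stop("degenerate panel: need >= 2 variants")
  x <- panel_ratios(panel, volumes)
  w <- base_model$weights
  iscore <- as.vector(x[, 1:4, drop = FALSE] %*% c(w$w1, w$w2, w$w3, w$w4))
  invvol <- x[, 5L]
  if (stats::sd(invvol) < 1e-15 && stats::sd(iscore) < 1e-15) {
    stop("degenerate panel: no variation in index components")
  }
  obs <- panel$Tm_obs
  mse_at <- function(w5) {
    mean((base_model$a * (iscore + w5 * invvol) + base_model$b - obs)^2)
  }
  opt <- stats::optimize(mse_at, interval = interval, tol = 1e-8)
  w_new <- hemelock_weights(w$w1, w$w2, w$w3, w$w4, opt$minimum)
  model <- structure(list(a = base_model$a, b = base_model$b,
                          weights = w_new,
                          provenance = sprintf("w5 refit (%.4g -> %.4g)",
                                               w$w5, opt$minimum)),
                     class = "hemelock_model")
  list(w5 = opt$minimum, mse_before = mse_at(w$w5),
       mse_after = opt$objective, model = model)
}

#' Read / write a variant panel CSV
#'
#' Columns: `variant`, `aa181`, `BBCHI`, `BBCHD`, `SCHI`, `SCHD`, `SCCHI`,
#' `SCCHD`, `SCSBI`, `SCSBD`, `Tm_obs` (and optionally `Tm_sd`). Empty
#' distance cells are the undefined distances of zero-frequency
#' categories.
#'
#' @param path CSV path.
#' @return data.frame panel.
#' @export
read_panel <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_panel
#' @param panel panel data.frame.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}
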