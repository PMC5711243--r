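#' Fit the VMSBR threshold model to calibration records
#'
#' Ordinary least squares of `ln(w)` on the fixed seven-term basis
#' \{x^(1/3), y^(1/3), ln z, x^(1/3) ln z, y^(1/3) ln z, (xy)^(1/3), 1\}.
#' Fitting is done in log space, so multiplicative errors in the optimal
#' threshold `w` become additive; this matches the model's functional form
#' and makes the noiseless fit exactly reproducible.
#'
#' @param data a data.frame of calibration records with columns `x` (tumor
#'   volume cm^3), `y` (motion extent mm), `z` (non-degraded SBR), and
#'   either `w` (optimal threshold normalized to background, > 0) or
#'   `log_w`.
#' @return an object of class `vmsbr_fit` with components `coefficients`
#'   (a [vmsbr_coefficients()]), `fitted`, `residuals`, `r_squared`,
#'   `sigma`, `n` and `data`.
#' @seealso [rc_fit()] for the recovery-coefficient model,
#'   [calibration_records()] for generating records from simulated phantoms.
#' @export
vmsbr_fit <- function(data) {
  data <- as.data.frame(data)
  need <- c("x", "y", "z")
  if (!all(need %in% names(data)))
    stop("calibration records need columns x, y, z and w (or log_w)",
         call. = FALSE)
  lw <- if ("log_w" %in% names(data)) data$log_w
        else if ("w" %in% names(data)) {
          if (any(data$w <= 0)) stop("w must be > 0", call. = FALSE)
          log(data$w)
        } else stop("calibration records need a w or log_w column", call. = FALSE)
  keep <- is.finite(lw) & is.finite(data$x) & is.finite(data$y) &
    is.finite(data$z) & data$z > 0 & data$x >= 0 & data$y >= 0
  data <- data[keep, , drop = FALSE]
  lw <- lw[keep]
  X <- vmsbr_basis(data$x, data$y, data$z)
  colnames(X) <- vmsbr_basis_names()
  fit <- ols_fixed_basis(X, lw, "VMSBR threshold")
  structure(
    list(coefficients = vmsbr_coefficients(fit$beta),
         fitted = fit$fitted, residuals = fit$residuals,
         r_squared = fit$r_squared, sigma = fit$sigma,
         n = length(lw), data = data, response = lw,
         model = "vmsbr"),
    class = c("vmsbr_fit", "threshold_model_fit")
  )
}

#' Fit the SBR recovery-coefficient model
#'
#' Ordinary least squares of `RC = z_true / z_measured` on the fixed basis
#' \{1/x, y, y/x, 1\}.
#'
#' @param data data.frame with columns `x`, `y` and either `rc` or both
#'   `z_true` and `z_measured`.
#' @return an object of class `rc_fit` with the same components as
#'   [vmsbr_fit()], coefficients being an [rc_coefficients()].
#' @export
rc_fit <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("x", "y") %in% names(data)))
    stop("recovery records need columns x, y and rc (or z_true, z_measured)",
         call. = FALSE)
  rc <- if ("rc" %in% names(data)) data$rc
        else if (all(c("z_true", "z_measured") %in% names(data)))
          data$z_true / data$z_measured
        else stop("recovery records need rc or z_true and z_measured",
                  call. = FALSE)
  keep <- is.finite(rc) & is.finite(data$x) & is.finite(data$y) & data$x > 0
  data <- data[keep, , drop = FALSE]
  rc <- rc[keep]
  X <- rc_basis(data$x, data$y)
  colnames(X) <- rc_basis_names()
  fit <- ols_fixed_basis(X, rc, "recovery coefficient")
  structure(
    list(coefficients = rc_coefficients(fit$beta),
         fitted = fit$fitted, residuals = fit$residuals,
         r_squared = fit$r_squared, sigma = fit$sigma,
         n = length(rc), data = data, response = rc,
         model = "rc"),
    class = c("rc_fit", "threshold_model_fit")
  )
}

## shared OLS on a fixed basis with an informative rank check
ols_fixed_basis <- function(X, yv, what) {
  p <- ncol(X)
  if (length(yv) < p)
    stop(sprintf(
      "fitting the %s model needs at least %d records (got %d): under-determined",
      what, p, length(yv)), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf(
      "rank-deficient design for the %s model: collinear term(s) %s (degenerate x/y/z coverage)",
      what, paste(dropped, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrX, yv)
  fitted <- drop(X %*% beta)
  res <- yv - fitted
  ss_tot <- sum((yv - mean(yv))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  dfree <- length(yv) - p
  sigma <- if (dfree > 0) sqrt(sum(res^2) / dfree) else 0
  list(beta = as.numeric(beta), fitted = fitted, residuals = res,
       r_squared = r2, sigma = sigma)
}

#' @export
coef.threshold_model_fit <- function(object, ...) object$coefficients

#' @export
residuals.threshold_model_fit <- function(object, ...) object$residuals

#' @export
print.threshold_model_fit <- function(x, ...) {
  lab <- if (x$model == "vmsbr") "VMSBR threshold model (ln w ~ basis(x, y, z))"
         else "SBR recovery-coefficient model (RC ~ basis(x, y))"
  cat(lab, "\n")
  cat(sprintf("  n = %d records, R^2 = %.4f, residual sigma = %.4g\n",
              x$n, x$r_squared, x$sigma))
  cat("  coefficients:\n")
  print(round(as.numeric(x$coefficients), 6))
  cat("  terms:", paste(names(x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.threshold_model_fit <- function(object, ...) {
  out <- list(model = object$model, n = object$n,
              coefficients = object$coefficients,
              r_squared = object$r_squared, sigma = object$sigma,
              residual_quartiles = stats::quantile(object$residuals,
                                                   c(0, .25, .5, .75, 1)))
  class(out) <- "summary.threshold_model_fit"
  out
}

#' @export
print.summary.threshold_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, R^2 = %.4f, sigma = %.4g\n",
              if (x$model == "vmsbr") "VMSBR" else "RC", x$n,
              x$r_squared, x$sigma))
  cat("coefficients:\n"); print(x$coefficients)
  cat("residual quartiles:\n"); print(signif(x$residual_quartiles, 4))
  invisible(x)
}

#' Predict from a fitted threshold or recovery model
#'
#' For `vmsbr_fit`, `newdata` needs columns `x`, `y`, `z`; the return is
#' `ln(w)` (`type = "log_w"`, default) or `w` (`type = "w"`).  For
#' `rc_fit`, `newdata` needs `x`, `y` and the return is RC.
#'
#' @param object a `vmsbr_fit` or `rc_fit`.
#' @param newdata data.frame of predictor columns; defaults to the training
#'   records.
#' @param type for `vmsbr_fit`: `"log_w"` or `"w"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.vmsbr_fit <- function(object, newdata = NULL,
                              type = c("log_w", "w"), ...) {
  type <- match.arg(type)
  nd <- if (is.null(newdata)) object$data else as.data.frame(newdata)
  lw <- vmsbr_log_threshold(nd$x, nd$y, nd$z, object$coefficients)
  if (type == "w") exp(lw) else lw
}

#' @rdname predict.vmsbr_fit
#' @export
predict.rc_fit <- function(object, newdata = NULL, ...) {
  nd <- if (is.null(newdata)) object$data else as.data.frame(newdata)
  recovery_coefficient(nd$x, nd$y, object$coefficients)
}

#' @export
plot.threshold_model_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$response,
                 xlab = "fitted", ylab = "observed",
                 main = if (x$model == "vmsbr") "VMSBR fit: ln(w)" else "RC fit",
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate responses from a fitted model
#'
#' Draws `nsim` replicates of the response (ln w for `vmsbr_fit`, RC for
#' `rc_fit`) at the training design points, adding Gaussian noise with the
#' fitted residual standard deviation.
#'
#' @param object a fitted model.
#' @param nsim number of replicate response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.threshold_model_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim,
    object$fitted + stats::rnorm(n, 0, object$sigma), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
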