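# Multistart bounded Levenberg-Marquardt least squares.
#
# Starts: the supplied center plus (n_starts - 1) points from a seeded
# Latin hypercube over the box. Ties between converged starts are broken by
# lowest objective, then lowest start index (the first minimum found wins).
ms_fit <- function(resid_fn, start, lower, upper, n_starts = 20,
                   seed = NULL, ftol = 1e-10, maxiter = 1000) {
  k <- length(start)
  stopifnot(length(lower) == k, length(upper) == k)
  nm <- names(start)
  center <- pmin(pmax(start, lower), upper)
  starts <- matrix(center, nrow = 1)
  if (n_starts > 1) {
    u <- with_seed(seed, lhs::randomLHS(n_starts - 1, k))
    starts <- rbind(starts,
                    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+"))
  }
  best <- NULL
  best_dev <- Inf
  best_idx <- NA_integer_
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = ftol,
                                     maxiter = maxiter)
  for (i in seq_len(nrow(starts))) {
    p0 <- starts[i, ]
    names(p0) <- nm
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- fit$deviance
    if (is.finite(dev) && dev < best_dev * (1 - 1e-12)) {
      best <- fit
      best_dev <- dev
      best_idx <- i
    }
  }
  if (is.null(best)) {
    stop("nonlinear least squares failed to converge from any start")
  }
  list(fit = best, par = best$par, deviance = best$deviance,
       start_index = best_idx)
}

# Standard errors from the Gauss-Newton Hessian at the optimum;
# NA (with a note) when the information matrix is singular.
se_from_fit <- function(fit, n_points) {
  p <- length(fit$par)
  se <- rep(NA_real_, p)
  if (n_points > p) {
    s2 <- fit$deviance / (n_points - p)
    cv <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  names(se) <- names(fit$par)
  se
}

# A parameter resting on its box bound is a degenerate optimum, not a
# converged estimate.
at_bounds <- function(par, lower, upper, tol = 1e-4) {
  rng <- pmax(upper - lower, 1e-12)
  (par - lower) / rng < tol | (upper - par) / rng < tol
}

new_pharmfit <- function(subclass, params, se, fixed, fit, n_points,
                         converged, reason, predfun, data, call) {
  structure(
    list(params = params, se = se, fixed = fixed,
         rss = fit$deviance, n_points = n_points,
         df = n_points - sum(!(names(params) %in% fixed)),
         converged = converged, reason = reason,
         predfun = predfun, data = data, call = call),
    class = c(subclass, "pharmfit"))
}

#' @export
print.pharmfit <- function(x, ...) {
  cat("Model:", class(x)[1], "\n")
  cat(sprintf("n = %d points, RSS = %.6g, converged = %s%s\n",
              x$n_points, x$rss, x$converged,
              if (nzchar(x$reason)) paste0(" (", x$reason, ")") else ""))
  est <- format(signif(x$params, 4))
  tag <- ifelse(names(x$params) %in% x$fixed, " (fixed)", "")
  cat("Parameters:\n")
  for (i in seq_along(est)) {
    cat(sprintf("  %-12s %s%s\n", names(est)[i], est[i], tag[i]))
  }
  invisible(x)
}

#' @export
coef.pharmfit <- function(object, ...) object$params

#' @export
summary.pharmfit <- function(object, ...) {
  free <- setdiff(names(object$params), object$fixed)
  tab <- data.frame(
    estimate = unname(object$params[free]),
    std_error = unname(object$se[free]),
    row.names = free)
  out <- list(model = class(object)[1], coefficients = tab,
              fixed = object$params[object$fixed],
              rss = object$rss, n_points = object$n_points,
              df = object$df, converged = object$converged,
              reason = object$reason)
  class(out) <- "summary.pharmfit"
  out
}

#' @export
print.summary.pharmfit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  printCoefmat(as.matrix(x$coefficients), digits = 4)
  if (length(x$fixed)) {
    cat("Fixed:", paste(names(x$fixed), signif(x$fixed, 4),
                        sep = " = ", collapse = ", "), "\n")
  }
  cat(sprintf("RSS %.6g on %d residual df; converged = %s\n",
              x$rss, x$df, x$converged))
  invisible(x)
}

#' @export
predict.pharmfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  object$predfun(object$params, newdata)
}

#' @export
residuals.pharmfit <- function(object, ...) {
  object$data$.response - predict(object)
}

#' Simulate replicate datasets from a fitted pharmacological model
#'
#' Draws `nsim` noisy copies of the fitted curve under the proportional
#' Gaussian error model used throughout the package
#' (`y = mu * (1 + eps)`, `eps ~ N(0, noise_cv)`).
#'
#' @param object a `pharmfit` object.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param noise_cv proportional noise SD as a fraction of the prediction.
#' @param ... unused.
#' @return data frame of `nsim` columns of simulated responses.
#' @export
simulate.pharmfit <- function(object, nsim = 1, seed = NULL,
                              noise_cv = 0.05, ...) {
  mu <- predict(object)
  with_seed(seed, {
    out <- replicate(nsim, mu * (1 + stats::rnorm(length(mu), 0, noise_cv)))
    as.data.frame(out)
  })
}
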