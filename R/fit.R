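PK_BOUNDS <- c(3, 12)
LOG_BOUNDS <- c(-4, 4)

#' Fit a one-site inhibitory mass-action competition curve
#'
#' Least-squares fit of [predict_one_site] to a competition binding curve.
#' Estimates `top`, `bottom` and `log_ic50`; [ki_from_ic50] converts the
#' IC50 to a K_I given the radioligand concentration and K_D.
#'
#' @param data data frame with columns `conc` (molar competitor
#'   concentration, > 0) and `binding` (specific binding).
#' @param n_starts,seed multistart settings (seeded Latin hypercube).
#' @return a `pharmfit` object (subclass `one_site_fit`). Flat curves and
#'   boundary-pinned optima are returned with `converged = FALSE` and a
#'   reason code.
#' @examples
#' truth <- c(top = 100, bottom = 5, log_ic50 = -7)
#' d <- data.frame(conc = 10^seq(-9, -5, 0.5))
#' d$binding <- predict_one_site(truth, log10(d$conc))
#' coef(fit_one_site(d))
#' @export
fit_one_site <- function(data, n_starts = 20, seed = 1L) {
  stopifnot(all(c("conc", "binding") %in% names(data)))
  data <- data[is.finite(data$conc) & data$conc > 0, ]
  if (length(unique(data$conc)) < 4) {
    stop("need >= 4 distinct competitor concentrations")
  }
  x <- log10(data$conc)
  y <- data$binding
  yr <- diff(range(y))
  lower <- c(top = min(y) - abs(yr), bottom = min(y) - abs(yr),
             log_ic50 = -PK_BOUNDS[2])
  upper <- c(top = max(y) + abs(yr) + 1, bottom = max(y) + abs(yr) + 1,
             log_ic50 = -PK_BOUNDS[1])
  start <- c(top = max(y), bottom = min(y), log_ic50 = stats::median(x))
  res <- ms_fit(function(p) predict_one_site(p, x) - y,
                start, lower, upper, n_starts = n_starts, seed = seed)
  par <- res$par
  reason <- ""
  conv <- TRUE
  if (yr < max(1e-8, 0.02 * max(abs(y), 1))) {
    conv <- FALSE; reason <- "flat_curve"
  } else if (at_bounds(par, lower, upper)[["log_ic50"]]) {
    conv <- FALSE; reason <- "boundary_log_ic50"
  }
  df <- data.frame(conc = data$conc, .response = y)
  new_pharmfit("one_site_fit", par, se_from_fit(res$fit, length(y)),
               character(0), res$fit, length(y), conv, reason,
               function(p, nd) predict_one_site(p, log10(nd$conc)),
               df, match.call())
}

#' Fit a three-parameter Hill concentration-response curve
#'
#' @param data data frame with columns `conc` (molar agonist concentration,
#'   >= 0) and `response`.
#' @inheritParams fit_one_site
#' @return a `pharmfit` object (subclass `hill_fit`) with parameters
#'   `basal`, `emax`, `pEC50`. Flat curves are flagged
#'   (`converged = FALSE`, reason `"flat_curve"`).
#' @export
fit_hill <- function(data, n_starts = 20, seed = 1L) {
  stopifnot(all(c("conc", "response") %in% names(data)))
  data <- data[is.finite(data$conc) & data$conc >= 0, ]
  if (length(unique(data$conc)) < 4) {
    stop("need >= 4 distinct agonist concentrations")
  }
  y <- data$response
  yr <- diff(range(y))
  lower <- c(basal = min(y) - abs(yr) - 1, emax = min(y) - abs(yr) - 1,
             pEC50 = PK_BOUNDS[1])
  upper <- c(basal = max(y) + abs(yr) + 1, emax = max(y) + abs(yr) + 1,
             pEC50 = PK_BOUNDS[2])
  start <- c(basal = min(y), emax = max(y),
             pEC50 = -stats::median(log10(data$conc[data$conc > 0])))
  res <- ms_fit(function(p) predict_hill(p, data$conc) - y,
                start, lower, upper, n_starts = n_starts, seed = seed)
  conv <- TRUE
  reason <- ""
  if (yr < max(1e-8, 0.02 * max(abs(y), 1))) {
    conv <- FALSE; reason <- "flat_curve"
  } else if (at_bounds(res$par, lower, upper)[["pEC50"]]) {
    conv <- FALSE; reason <- "boundary_pEC50"
  }
  df <- data.frame(conc = data$conc, .response = y)
  new_pharmfit("hill_fit", res$par, se_from_fit(res$fit, length(y)),
               character(0), res$fit, length(y), conv, reason,
               function(p, nd) predict_hill(p, nd$conc), df, match.call())
}

check_interaction_data <- function(data, min_modulator_levels) {
  need <- c("radioligand_conc", "agonist_conc", "modulator_conc", "binding")
  if (!all(need %in% names(data))) {
    stop("interaction binding data needs columns: ",
         paste(need, collapse = ", "))
  }
  if (!any(data$modulator_conc == 0)) {
    stop("modulator-free (B = 0) control points are required")
  }
  nb <- length(setdiff(unique(data$modulator_conc), 0))
  if (nb < min_modulator_levels) {
    stop(sprintf(
      "need >= %d non-zero modulator concentrations (got %d): %s",
      min_modulator_levels, nb,
      "the cooperativity and modulator affinity are not separable otherwise"))
  }
  invisible(data)
}

#' Globally fit the allosteric ternary complex model
#'
#' Fits [predict_atcm] simultaneously to all rows of an interaction binding
#' table (all replicates, all modulator concentrations) by bounded
#' multistart Levenberg-Marquardt, sharing `pKB`, `pKI`, `log_alpha_I`,
#' `log_alpha_A` and `bmax` across curves. The radioligand affinity `pKA`
#' is constrained to the value determined from saturation binding, as is
#' standard for this model.
#'
#' Parameters are estimated in log10 space (pK in [3, 12], log
#' cooperativities in [-4, 4]); `alpha_A` (modulator vs radioligand
#' cooperativity) is free by default and can be fixed to 1 (neutral) with
#' `fix_alpha_A = TRUE`.
#'
#' @param data data frame with columns `radioligand_conc`, `agonist_conc`,
#'   `modulator_conc` (molar), `binding`, and optionally `replicate`. Must
#'   contain B = 0 control points and at least two non-zero modulator
#'   concentrations.
#' @param pKA fixed radioligand affinity (-log10 molar).
#' @param fix_alpha_A if `TRUE`, hold the modulator-radioligand
#'   cooperativity at 1.
#' @param bmax optional fixed maximal binding; estimated when `NULL`.
#' @inheritParams fit_one_site
#' @return a `pharmfit` object (subclass `atcm_fit`) whose parameters are
#'   `bmax`, `pKA`, `pKB`, `pKI`, `log_alpha_A`, `log_alpha_I`.
#' @export
fit_atcm <- function(data, pKA, fix_alpha_A = FALSE, bmax = NULL,
                     n_starts = 20, seed = 1L) {
  check_interaction_data(data, min_modulator_levels = 2)
  y <- data$binding
  free <- c(if (is.null(bmax)) "bmax", "pKB", "pKI",
            if (!fix_alpha_A) "log_alpha_A", "log_alpha_I")
  full <- c(bmax = if (is.null(bmax)) max(y) else bmax, pKA = pKA,
            pKB = 5, pKI = 6, log_alpha_A = 0, log_alpha_I = 0)
  lower <- c(bmax = 0, pKA = PK_BOUNDS[1], pKB = PK_BOUNDS[1],
             pKI = PK_BOUNDS[1], log_alpha_A = LOG_BOUNDS[1],
             log_alpha_I = LOG_BOUNDS[1])
  upper <- c(bmax = max(y) * 10 + 10, pKA = PK_BOUNDS[2],
             pKB = PK_BOUNDS[2], pKI = PK_BOUNDS[2],
             log_alpha_A = LOG_BOUNDS[2], log_alpha_I = LOG_BOUNDS[2])
  resid_fn <- function(p) {
    prm <- full
    prm[free] <- p
    predict_atcm(prm, data$radioligand_conc, data$agonist_conc,
                 data$modulator_conc) - y
  }
  res <- ms_fit(resid_fn, full[free], lower[free], upper[free],
                n_starts = n_starts, seed = seed)
  full[free] <- res$par
  se <- rep(NA_real_, length(full))
  names(se) <- names(full)
  se[free] <- se_from_fit(res$fit, length(y))
  pinned <- at_bounds(res$par, lower[free], upper[free])
  conv <- !any(pinned)
  reason <- if (any(pinned)) {
    paste0("boundary_", paste(free[pinned], collapse = ","))
  } else ""
  df <- data
  df$.response <- y
  fitobj <- new_pharmfit(
    "atcm_fit", full, se, setdiff(names(full), free), res$fit,
    length(y), conv, reason,
    function(p, nd) predict_atcm(p, nd$radioligand_conc, nd$agonist_conc,
                                 nd$modulator_conc),
    df, match.call())
  fitobj
}

check_functional_data <- function(data, min_modulator_levels) {
  need <- c("agonist_conc", "modulator_conc", "response")
  if (!all(need %in% names(data))) {
    stop("functional data needs columns: ", paste(need, collapse = ", "))
  }
  if (!any(data$modulator_conc == 0)) {
    stop("modulator-free (B = 0) control curve is required")
  }
  nb <- length(setdiff(unique(data$modulator_conc), 0))
  if (nb < min_modulator_levels) {
    stop(sprintf("need >= %d non-zero modulator concentrations (got %d)",
                 min_modulator_levels, nb))
  }
  invisible(data)
}

#' Globally fit the operational model of allosterism
#'
#' Fits [predict_operational] to a family of agonist concentration-response
#' curves at several modulator concentrations. Orthosteric agonist and
#' modulator affinities (`pKA`, `pKB`) are constrained to the values
#' determined from radioligand binding; by default the transducer slope is
#' fixed at `n = 1` and the binding cooperativity `log_alpha` at its
#' binding estimate, leaving `em`, `log_tau_A`, `log_tau_B` and `log_beta`
#' free. The composite functional cooperativity
#' `log_alphabeta = log_alpha + log_beta` is reported alongside the raw
#' parameters.
#'
#' @param data data frame with columns `agonist_conc`, `modulator_conc`
#'   (molar), `response` (% normalized), optionally `replicate`. Needs a
#'   B = 0 curve and at least three non-zero modulator concentrations.
#' @param pKA,pKB fixed affinities (-log10 molar) from binding.
#' @param log_alpha binding cooperativity (log10); fixed unless
#'   `fit_alpha = TRUE`.
#' @param n transducer slope; fixed unless `fit_n = TRUE`.
#' @param fit_alpha,fit_n set `TRUE` to free the respective parameter.
#' @inheritParams fit_one_site
#' @return a `pharmfit` object (subclass `operational_fit`) with parameters
#'   `em`, `pKA`, `pKB`, `log_tau_A`, `log_tau_B`, `log_alpha`, `log_beta`,
#'   `n`, plus the derived `log_alphabeta` in `$derived` (with its SE,
#'   which equals the SE of `log_beta` when `log_alpha` is fixed).
#' @export
fit_operational <- function(data, pKA, pKB, log_alpha = 0, n = 1,
                            fit_alpha = FALSE, fit_n = FALSE,
                            n_starts = 20, seed = 1L) {
  check_functional_data(data, min_modulator_levels = 3)
  y <- data$response
  free <- c("em", "log_tau_A", "log_tau_B",
            if (fit_alpha) "log_alpha", "log_beta", if (fit_n) "n")
  full <- c(em = max(y), pKA = pKA, pKB = pKB, log_tau_A = 0,
            log_tau_B = 0, log_alpha = log_alpha, log_beta = 0, n = n)
  lower <- c(em = 1e-3, pKA = PK_BOUNDS[1], pKB = PK_BOUNDS[1],
             log_tau_A = LOG_BOUNDS[1], log_tau_B = LOG_BOUNDS[1],
             log_alpha = LOG_BOUNDS[1], log_beta = LOG_BOUNDS[1], n = 0.1)
  upper <- c(em = max(y) * 10 + 10, pKA = PK_BOUNDS[2], pKB = PK_BOUNDS[2],
             log_tau_A = LOG_BOUNDS[2], log_tau_B = LOG_BOUNDS[2],
             log_alpha = LOG_BOUNDS[2], log_beta = LOG_BOUNDS[2], n = 5)
  resid_fn <- function(p) {
    prm <- full
    prm[free] <- p
    predict_operational(prm, data$agonist_conc, data$modulator_conc) - y
  }
  res <- ms_fit(resid_fn, full[free], lower[free], upper[free],
                n_starts = n_starts, seed = seed)
  full[free] <- res$par
  se <- rep(NA_real_, length(full))
  names(se) <- names(full)
  se[free] <- se_from_fit(res$fit, length(y))
  pinned <- at_bounds(res$par, lower[free], upper[free])
  conv <- !any(pinned)
  reason <- if (any(pinned)) {
    paste0("boundary_", paste(free[pinned], collapse = ","))
  } else ""
  df <- data
  df$.response <- y
  fitobj <- new_pharmfit(
    "operational_fit", full, se, setdiff(names(full), free), res$fit,
    length(y), conv, reason,
    function(p, nd) predict_operational(p, nd$agonist_conc,
                                        nd$modulator_conc),
    df, match.call())
  ab_se <- if (fit_alpha) {
    sqrt(sum(se[c("log_alpha", "log_beta")]^2))  # ignores covariance
  } else {
    se[["log_beta"]]
  }
  fitobj$derived <- c(log_alphabeta = unname(full["log_alpha"] +
                                               full["log_beta"]),
                      log_alphabeta_se = unname(ab_se))
  fitobj
}
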