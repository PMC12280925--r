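#' One-site inhibitory mass-action competition curve
#'
#' Specific radioligand binding as a function of competitor concentration:
#' \deqn{Y = Bottom + (Top - Bottom) / (1 + 10^{X - \log IC_{50}})}
#' with \eqn{X} the log10 molar competitor concentration.
#'
#' @param params named vector or list with `top`, `bottom`, `log_ic50`
#'   (log10 molar).
#' @param x log10 molar competitor concentration (vectorized).
#' @return predicted specific binding, same units as `top`/`bottom`.
#' @seealso [fit_one_site], [ki_from_ic50]
#' @export
predict_one_site <- function(params, x) {
  p <- as.list(params)
  p$bottom + (p$top - p$bottom) / (1 + 10^(x - p$log_ic50))
}

#' Cheng-Prusoff correction of a competition IC50
#'
#' Converts an IC50 from a competition binding experiment to the
#' competitor's equilibrium dissociation constant:
#' \deqn{K_I = IC_{50} / (1 + [A]/K_D)}
#' where \eqn{[A]} is the radioligand concentration and \eqn{K_D} its
#' equilibrium dissociation constant.
#'
#' @param ic50 molar IC50 (> 0).
#' @param radioligand_conc molar radioligand concentration (>= 0).
#' @param radioligand_kd molar radioligand K_D (> 0).
#' @return molar K_I.
#' @examples
#' ki_from_ic50(10e-9, 1e-9, 1e-9)  # 5 nM
#' @export
ki_from_ic50 <- function(ic50, radioligand_conc, radioligand_kd) {
  if (any(ic50 <= 0) || any(radioligand_kd <= 0) ||
      any(radioligand_conc < 0)) {
    stop("ic50 and radioligand_kd must be positive, radioligand_conc >= 0")
  }
  ic50 / (1 + radioligand_conc / radioligand_kd)
}

#' Allosteric ternary complex model for radioligand interaction binding
#'
#' Predicts specific radioligand binding in the simultaneous presence of an
#' orthosteric competitor (agonist, I) and an allosteric modulator (B):
#' \deqn{Y = \frac{B_{max}[A]}{[A] +
#'   \frac{K_A K_B}{\alpha_A [B] + K_B}
#'   \left(1 + \frac{[I]}{K_I} + \frac{[B]}{K_B} +
#'         \frac{\alpha_I [I][B]}{K_I K_B}\right)}}
#' where \eqn{K_A, K_B, K_I} are the equilibrium dissociation constants of
#' the radioligand, modulator and agonist, and \eqn{\alpha_A, \alpha_I} the
#' binding cooperativities of the modulator with the radioligand and the
#' agonist (\eqn{\alpha > 1} positive, \eqn{< 1} negative, \eqn{= 1}
#' neutral).
#'
#' @param params named vector or list with `bmax`, `pKA`, `pKB`, `pKI`,
#'   `log_alpha_A`, `log_alpha_I` (pK in -log10 molar, cooperativities in
#'   log10).
#' @param radioligand_conc molar radioligand concentration \eqn{[A]}.
#' @param agonist_conc molar orthosteric agonist concentration \eqn{[I]}.
#' @param modulator_conc molar modulator concentration \eqn{[B]}.
#' @return predicted specific binding in `bmax` units.
#' @seealso [fit_atcm]
#' @export
predict_atcm <- function(params, radioligand_conc, agonist_conc,
                         modulator_conc) {
  p <- as.list(params)
  if (any(radioligand_conc < 0) || any(agonist_conc < 0) ||
      any(modulator_conc < 0)) {
    stop("concentrations must be non-negative")
  }
  A <- radioligand_conc
  I <- agonist_conc
  B <- modulator_conc
  KA <- 10^-p$pKA
  KB <- 10^-p$pKB
  KI <- 10^-p$pKI
  aA <- 10^p$log_alpha_A
  aI <- 10^p$log_alpha_I
  denom <- A + (KA * KB / (aA * B + KB)) *
    (1 + I / KI + B / KB + aI * I * B / (KI * KB))
  p$bmax * A / denom
}

#' Operational model of allosterism
#'
#' Predicts the functional response to an orthosteric agonist (A) in the
#' presence of an allosteric ligand (B):
#' \deqn{E = \frac{E_m(\tau_A [A](K_B + \alpha\beta [B]) +
#'   \tau_B [B] K_A)^n}{([A]K_B + K_A K_B + [B]K_A + \alpha [A][B])^n +
#'   (\tau_A [A](K_B + \alpha\beta [B]) + \tau_B [B] K_A)^n}}
#' \eqn{\tau_A, \tau_B} are operational efficacies, \eqn{\alpha} the binding
#' cooperativity, \eqn{\beta} the modulation of agonist efficacy, and
#' \eqn{n} the transducer slope. The composite \eqn{\log\alpha\beta} is the
#' functional cooperativity usually reported.
#'
#' @param params named vector or list with `em`, `pKA`, `pKB`, `log_tau_A`,
#'   `log_tau_B`, `log_alpha`, `log_beta`, `n`.
#' @param agonist_conc molar agonist concentration \eqn{[A]}.
#' @param modulator_conc molar modulator concentration \eqn{[B]}.
#' @return predicted response in `em` units.
#' @seealso [fit_operational]
#' @export
predict_operational <- function(params, agonist_conc, modulator_conc) {
  p <- as.list(params)
  if (any(agonist_conc < 0) || any(modulator_conc < 0)) {
    stop("concentrations must be non-negative")
  }
  A <- agonist_conc
  B <- modulator_conc
  KA <- 10^-p$pKA
  KB <- 10^-p$pKB
  tA <- 10^p$log_tau_A
  tB <- 10^p$log_tau_B
  ab <- 10^(p$log_alpha + p$log_beta)
  al <- 10^p$log_alpha
  num <- tA * A * (KB + ab * B) + tB * B * KA
  den <- A * KB + KA * KB + B * KA + al * A * B
  # scale before the ^n to keep large-tau / micromolar-K products stable
  s <- pmax(num, den)
  s[s == 0] <- 1
  rn <- (num / s)^p$n
  rd <- (den / s)^p$n
  p$em * rn / (rd + rn)
}

#' Three-parameter Hill (concentration-response) curve
#'
#' \deqn{E = Basal + (E_{max} - Basal)\,[A] / (EC_{50} + [A])}
#'
#' @param params named vector or list with `basal`, `emax`, `pEC50`
#'   (-log10 molar).
#' @param agonist_conc molar agonist concentration (vectorized).
#' @return predicted response.
#' @seealso [fit_hill]
#' @export
predict_hill <- function(params, agonist_conc) {
  p <- as.list(params)
  ec50 <- 10^-p$pEC50
  p$basal + (p$emax - p$basal) * agonist_conc / (ec50 + agonist_conc)
}

#' Normalize a cAMP accumulation response
#'
#' Linear normalization anchored on the plate controls: the forskolin-alone
#' response maps to 0% and the buffer-alone response to 100%. For a
#' Gi-coupled receptor, agonist-mediated inhibition of forskolin-stimulated
#' cAMP therefore rises from 0 toward 100.
#'
#' @param raw raw response values (vectorized).
#' @param forskolin_ref forskolin-alone reference (maps to 0).
#' @param buffer_ref buffer-alone reference (maps to 100).
#' @return normalized response in percent.
#' @export
normalize_camp <- function(raw, forskolin_ref, buffer_ref) {
  if (forskolin_ref == buffer_ref) {
    stop("forskolin and buffer references are identical; cannot normalize")
  }
  100 * (raw - forskolin_ref) / (buffer_ref - forskolin_ref)
}
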