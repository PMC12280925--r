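#' Replicate shifts in agonist affinity and potency across a screen
#'
#' For each compound, pairs control and modulator-treated replicate
#' estimates of orthosteric agonist affinity (pK_I) and potency (pEC50),
#' forms per-replicate differences (treated - control) and tests each
#' endpoint against zero with a two-sided one-sample t test.
#'
#' @param control,treated data frames with columns `compound`, `replicate`,
#'   `pKI`, `pEC50`; replicates must match one-to-one within each compound
#'   and there must be at least 3 per compound.
#' @return data frame (class `screen_summary`) with one row per compound:
#'   mean deltas, replicate counts, t statistics and p values for both
#'   endpoints. Compounds whose deltas have zero variance get `NA`
#'   statistics (flagged, never hits).
#' @seealso [call_hits]
#' @export
screen_deltas <- function(control, treated) {
  need <- c("compound", "replicate", "pKI", "pEC50")
  stopifnot(all(need %in% names(control)), all(need %in% names(treated)))
  m <- merge(control, treated, by = c("compound", "replicate"),
             suffixes = c("_ctrl", "_trt"))
  if (nrow(m) != nrow(control) || nrow(m) != nrow(treated)) {
    stop("control and treated replicates do not match one-to-one")
  }
  m$d_pKI <- m$pKI_trt - m$pKI_ctrl
  m$d_pEC50 <- m$pEC50_trt - m$pEC50_ctrl
  one_t <- function(d) {
    n <- length(d)
    if (n < 3) stop("need >= 3 matched replicates per compound")
    s <- stats::sd(d)
    if (s == 0) return(c(mean(d), n, NA_real_, NA_real_))
    t <- mean(d) / (s / sqrt(n))
    c(mean(d), n, t, 2 * stats::pt(-abs(t), n - 1))
  }
  out <- do.call(rbind, lapply(split(m, m$compound), function(g) {
    a <- one_t(g$d_pKI)
    p <- one_t(g$d_pEC50)
    data.frame(compound = g$compound[1], n = a[2],
               delta_pKI = a[1], t_affinity = a[3], p_affinity = a[4],
               delta_pEC50 = p[1], t_potency = p[3], p_potency = p[4])
  }))
  rownames(out) <- NULL
  class(out) <- c("screen_summary", class(out))
  out
}

#' Call screening hits from a screen summary
#'
#' A compound is a hit when it *enhances* both orthosteric agonist affinity
#' and potency: both one-sample tests significant at `alpha` and both mean
#' deltas positive. The hit rate is expressed as a percentage of compounds
#' tested, to one decimal.
#'
#' @param summary a `screen_summary` from [screen_deltas].
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `hits` (compound ids), `n_tested`, `n_hits`,
#'   `hit_rate` (percent, one decimal) and the annotated `summary`
#'   (logical `hit` column added).
#' @examples
#' \dontrun{
#' sc <- gen_screen(seed = 7)
#' call_hits(screen_deltas(sc$control, sc$treated))$hit_rate
#' }
#' @export
call_hits <- function(summary, alpha = 0.05) {
  if (!nrow(summary)) stop("empty screen summary")
  hit <- !is.na(summary$p_affinity) & !is.na(summary$p_potency) &
    summary$p_affinity < alpha & summary$p_potency < alpha &
    summary$delta_pKI > 0 & summary$delta_pEC50 > 0
  summary$hit <- hit
  list(hits = summary$compound[hit],
       n_tested = nrow(summary),
       n_hits = sum(hit),
       hit_rate = round(100 * sum(hit) / nrow(summary), 1),
       summary = summary)
}
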