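#' ROC curve for a ranked screening library
#'
#' Ranks molecules by docking score (lower energy = better by default) and
#' traces the stepwise ROC of actives versus negatives (decoys and
#' experimentally inactive compounds are treated identically). Tied scores
#' are resolved by averaging: all tied molecules advance the curve
#' simultaneously along a diagonal segment, so the AUC equals the
#' Mann-Whitney U normalization with the usual 1/2 tie credit.
#'
#' @param library data frame with columns `molecule_id`, `score`, `label`
#'   (one of `"active"`, `"decoy"`, `"inactive"`, `"unknown"`). Unknown
#'   labels and missing scores are excluded (counts kept in attributes).
#' @param higher_is_better set `TRUE` when larger scores mean better.
#' @return object of class `roc_curve`: `points` (data frame of FPR, TPR
#'   from (0,0) to (1,1)), `auc`, `n_active`, `n_negative`.
#' @seealso [adjusted_logauc]
#' @export
roc_enrichment <- function(library, higher_is_better = FALSE) {
  stopifnot(all(c("molecule_id", "score", "label") %in% names(library)))
  n_unknown <- sum(library$label == "unknown")
  n_missing <- sum(!is.finite(library$score))
  d <- library[library$label != "unknown" & is.finite(library$score), ]
  pos <- d$label == "active"
  neg <- d$label %in% c("decoy", "inactive")
  if (!any(pos) || !any(neg)) {
    stop("enrichment needs at least one active and one negative")
  }
  d <- d[pos | neg, ]
  s <- if (higher_is_better) -d$score else d$score
  act <- d$label == "active"
  np <- sum(act)
  nn <- sum(!act)
  o <- order(s)
  s <- s[o]
  act <- act[o]
  # group ties; each group contributes one (possibly diagonal) segment
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(act, grp, sum))
  fp <- cumsum(tapply(!act, grp, sum))
  pts <- data.frame(fpr = c(0, unname(fp) / nn),
                    tpr = c(0, unname(tp) / np))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc, n_active = np, n_negative = nn,
                 n_excluded_unknown = n_unknown,
                 n_excluded_missing = n_missing),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %d actives vs %d negatives, AUC = %.4f\n",
              x$n_active, x$n_negative, x$auc))
  cat(sprintf("adjusted logAUC (lambda = 0.001) = %.2f\n",
              adjusted_logauc(x)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, log_fpr = FALSE, lambda = 0.001, ...) {
  p <- x$points
  if (log_fpr) {
    keep <- p$fpr > 0
    plot(pmax(p$fpr, lambda), p$tpr, type = "l", log = "x",
         xlab = "FPR (log scale)", ylab = "TPR", ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  } else {
    plot(p$fpr, p$tpr, type = "l", xlab = "FPR", ylab = "TPR", ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  }
  invisible(x)
}

#' Adjusted logAUC early-enrichment metric
#'
#' Area under the ROC curve plotted against log10 FPR from a lower bound
#' `lambda`, normalized to percent and corrected by the random-ranking
#' expectation:
#' \deqn{logAUC = \frac{100}{\log_{10}(1/\lambda)}
#'   \int_{\lambda}^{1} TPR \; d\log_{10} FPR}
#' minus \eqn{100 (1-\lambda) / (\ln 10 \cdot \log_{10}(1/\lambda))}
#' (about 14.462 for `lambda = 0.001`). Random rankings score ~0; a perfect
#' classifier scores 100 - 14.462 = 85.54 at the default `lambda`. The
#' integral is evaluated in closed form on each linear ROC segment;
#' segments starting below `lambda` are clamped to `lambda` with the TPR
#' interpolated there.
#'
#' @param x a `roc_curve` from [roc_enrichment].
#' @param lambda lower FPR integration bound in (0, 1).
#' @return adjusted logAUC in percent.
#' @export
adjusted_logauc <- function(x, lambda = 0.001) {
  stopifnot(inherits(x, "roc_curve"))
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  p <- x$points
  total <- 0
  for (i in seq_len(nrow(p) - 1)) {
    f1 <- p$fpr[i]; f2 <- p$fpr[i + 1]
    t1 <- p$tpr[i]; t2 <- p$tpr[i + 1]
    if (f2 <= lambda || f2 == f1) next
    # TPR(F) = c + d F on the segment
    d <- (t2 - t1) / (f2 - f1)
    cc <- t1 - d * f1
    a <- max(f1, lambda)
    total <- total + (cc * log(f2 / a) + d * (f2 - a)) / log(10)
  }
  logauc <- 100 * total / log10(1 / lambda)
  random <- 100 * (1 - lambda) / (log(10) * log10(1 / lambda))
  logauc - random
}

#' Combine docking scores across an ensemble of snapshots
#'
#' For each molecule, takes the best (minimum) energy over the snapshots in
#' which it docked, mirroring best-pose-across-snapshots selection.
#' Molecules that docked in no snapshot are excluded; their count is kept
#' in the `n_excluded` attribute and reported with a warning.
#'
#' @param scores numeric matrix, molecules x snapshots, `NA` = did not
#'   dock; rownames are molecule ids.
#' @param method aggregation method; only `"best"` (minimum energy).
#' @param higher_is_better set `TRUE` when larger scores are better.
#' @return data frame `molecule_id`, `score`, with attribute `n_excluded`.
#' @export
ensemble_combine <- function(scores, method = c("best"),
                             higher_is_better = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            ncol(scores) >= 1)
  all_na <- rowSums(!is.na(scores)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " molecule(s) docked in no snapshot; excluded")
  }
  keep <- scores[!all_na, , drop = FALSE]
  agg <- if (higher_is_better) {
    apply(keep, 1, max, na.rm = TRUE)
  } else {
    apply(keep, 1, min, na.rm = TRUE)
  }
  out <- data.frame(molecule_id = rownames(keep), score = unname(agg),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(all_na)
  out
}

#' Rank snapshots by single-snapshot enrichment
#'
#' Computes the adjusted logAUC of each snapshot's own ranking (molecules
#' missing from a snapshot are simply absent from that ranking) and
#' returns the top `k` snapshots, best first; ties broken by snapshot id.
#'
#' @param scores molecules x snapshots score matrix (rownames molecule
#'   ids, colnames snapshot ids; `NA` = did not dock).
#' @param labels data frame `molecule_id`, `label`.
#' @param k number of snapshots to keep.
#' @param lambda lower FPR bound for [adjusted_logauc].
#' @param higher_is_better passed to [roc_enrichment].
#' @return data frame `snapshot_id`, `adj_logauc` for the selected
#'   snapshots, in selection order.
#' @export
select_snapshots <- function(scores, labels, k, lambda = 0.001,
                             higher_is_better = FALSE) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)),
            all(c("molecule_id", "label") %in% names(labels)))
  if (k > ncol(scores)) stop("k exceeds the number of snapshots")
  lab <- labels$label[match(rownames(scores), labels$molecule_id)]
  if (anyNA(lab)) stop("unlabeled molecules in the score matrix")
  vals <- vapply(colnames(scores), function(sn) {
    lib <- data.frame(molecule_id = rownames(scores),
                      score = scores[, sn], label = lab,
                      stringsAsFactors = FALSE)
    adjusted_logauc(
      roc_enrichment(lib[is.finite(lib$score), ],
                     higher_is_better = higher_is_better),
      lambda = lambda)
  }, numeric(1))
  ord <- order(-vals, colnames(scores))
  data.frame(snapshot_id = colnames(scores)[ord][seq_len(k)],
             adj_logauc = unname(vals[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Property-matched decoy selection
#'
#' For each active, selects the `n_per_active` pool molecules nearest in a
#' standardized physicochemical property space, excluding pool molecules
#' topologically similar to *any* active (fingerprint Tanimoto >=
#' `tc_exclude`), in the spirit of the DUD-E decoy protocol. Properties are
#' z-scored over the pool; distance is Euclidean. Decoys are not reused
#' across actives (greedy assignment in active input order; ties broken by
#' molecule id).
#'
#' @param actives,pool data frames with `molecule_id` and the property
#'   columns in `properties`.
#' @param active_fps,pool_fps 0/1 fingerprint matrices with molecule ids
#'   as rownames; set `NULL` to skip the similarity exclusion.
#' @param n_per_active decoys requested per active (typically 40-50).
#' @param tc_exclude Tanimoto threshold above which a pool molecule is
#'   excluded as too similar to an active.
#' @param properties property columns used for matching.
#' @return data frame `active_id`, `decoy_id`, `distance`, `rank`;
#'   attribute `shortfall` is a named vector of unmet counts per active
#'   (all zero when the pool sufficed; a warning is raised otherwise).
#' @export
match_decoys <- function(actives, pool, active_fps = NULL, pool_fps = NULL,
                         n_per_active = 50, tc_exclude = 0.35,
                         properties = c("mw", "clogp", "hbd", "hba",
                                        "charge", "rotb")) {
  stopifnot("molecule_id" %in% names(actives),
            "molecule_id" %in% names(pool),
            all(properties %in% names(actives)),
            all(properties %in% names(pool)))
  pm <- as.matrix(pool[, properties])
  am <- as.matrix(actives[, properties])
  mu <- colMeans(pm)
  sg <- apply(pm, 2, stats::sd)
  sg[sg == 0] <- 1
  pz <- sweep(sweep(pm, 2, mu), 2, sg, "/")
  az <- sweep(sweep(am, 2, mu), 2, sg, "/")
  banned <- rep(FALSE, nrow(pool))
  if (!is.null(active_fps) && !is.null(pool_fps)) {
    for (j in seq_len(nrow(pool))) {
      fp <- pool_fps[pool$molecule_id[j], ]
      tcs <- vapply(actives$molecule_id, function(a) {
        tanimoto(active_fps[a, ], fp)
      }, numeric(1))
      banned[j] <- any(tcs >= tc_exclude)
    }
  }
  used <- rep(FALSE, nrow(pool))
  res <- list()
  shortfall <- stats::setNames(integer(nrow(actives)),
                               actives$molecule_id)
  for (i in seq_len(nrow(actives))) {
    d <- sqrt(colSums((t(pz) - az[i, ])^2))
    avail <- which(!used & !banned)
    ord <- avail[order(d[avail], pool$molecule_id[avail])]
    take <- utils::head(ord, n_per_active)
    shortfall[i] <- n_per_active - length(take)
    used[take] <- TRUE
    if (length(take)) {
      res[[i]] <- data.frame(active_id = actives$molecule_id[i],
                             decoy_id = pool$molecule_id[take],
                             distance = d[take],
                             rank = seq_along(take),
                             stringsAsFactors = FALSE)
    }
  }
  if (any(shortfall > 0)) {
    warning("decoy pool exhausted; shortfall for: ",
            paste(names(shortfall)[shortfall > 0], collapse = ", "))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "shortfall") <- shortfall
  out
}
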