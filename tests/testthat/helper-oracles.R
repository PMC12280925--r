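# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by the most literal route available so the fast
# implementations are checked against something that cannot share their
# bugs.

# Eq-by-eq literal evaluation of the ternary complex expression
oracle_atcm <- function(p, A, I, B) {
  KA <- 10^-p[["pKA"]]; KB <- 10^-p[["pKB"]]; KI <- 10^-p[["pKI"]]
  aA <- 10^p[["log_alpha_A"]]; aI <- 10^p[["log_alpha_I"]]
  p[["bmax"]] * A /
    (A + (KA * KB / (aA * B + KB)) *
       (1 + I / KI + B / KB + aI * I * B / (KI * KB)))
}

# literal operational-model expression, no rescaling
oracle_operational <- function(p, A, B) {
  KA <- 10^-p[["pKA"]]; KB <- 10^-p[["pKB"]]
  tA <- 10^p[["log_tau_A"]]; tB <- 10^p[["log_tau_B"]]
  al <- 10^p[["log_alpha"]]; be <- 10^p[["log_beta"]]
  num <- (tA * A * (KB + al * be * B) + tB * B * KA)^p[["n"]]
  den <- (A * KB + KA * KB + B * KA + al * A * B)^p[["n"]]
  p[["em"]] * num / (den + num)
}

# ROC AUC by concordant-pair counting (ties get half credit);
# lower score = better
oracle_auc_pairs <- function(score, is_active) {
  a <- score[is_active]
  n <- score[!is_active]
  conc <- 0
  for (x in a) conc <- conc + sum(x < n) + 0.5 * sum(x == n)
  conc / (length(a) * length(n))
}

# adjusted logAUC by fine-grid quadrature of the stepwise-linear ROC
oracle_logauc_quadrature <- function(pts, lambda = 0.001,
                                     n_grid = 2e5) {
  f <- seq(log10(lambda), 0, length.out = n_grid)
  fpr <- 10^f
  tpr <- sapply(fpr, function(x) {
    i <- max(which(pts$fpr <= x))
    if (i == nrow(pts)) return(pts$tpr[i])
    f1 <- pts$fpr[i]; f2 <- pts$fpr[i + 1]
    # skip vertical pieces: take the highest point at this fpr
    j <- max(which(pts$fpr == f1))
    if (pts$fpr[j] == x) return(pts$tpr[j])
    t1 <- pts$tpr[j]; t2 <- pts$tpr[j + 1]
    t1 + (t2 - t1) * (x - f1) / (pts$fpr[j + 1] - f1)
  })
  dx <- diff(f)
  area <- sum(dx * (tpr[-1] + tpr[-length(tpr)]) / 2)
  100 * area / log10(1 / lambda) -
    100 * (1 - lambda) / (log(10) * log10(1 / lambda))
}

# greedy leader clustering, written independently from scratch
oracle_leader <- function(fps, scores, threshold) {
  ids <- rownames(fps)
  ids <- ids[order(scores[ids], ids)]
  left <- ids
  out <- list()
  while (length(left)) {
    lead <- left[1]
    sims <- sapply(left, function(m) {
      u <- sum(fps[lead, ] | fps[m, ])
      if (u == 0) 0 else sum(fps[lead, ] & fps[m, ]) / u
    })
    mem <- left[sims >= threshold | left == lead]
    out[[length(out) + 1]] <- list(rep = lead, members = mem)
    left <- setdiff(left, mem)
  }
  out
}

# literal evaluation of the hydrogen-bond retention predicate
oracle_hbond <- function(contacts, required, dmax, amin) {
  ids <- unique(contacts$molecule_id)
  keep <- sapply(ids, function(m) {
    cc <- contacts[contacts$molecule_id == m, ]
    all(sapply(required, function(s) {
      any(cc$site == s & cc$distance <= dmax & cc$angle >= amin)
    }))
  })
  sort(ids[keep])
}

rand_fps <- function(n, nbits = 64, density = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(as.integer(runif(n * nbits) < density), n, nbits)
  rownames(m) <- sprintf("m%03d", seq_len(n))
  m
}
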