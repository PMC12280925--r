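toy_library <- function(scores_a, scores_n) {
  data.frame(
    molecule_id = sprintf("m%03d", seq_len(length(scores_a) +
                                             length(scores_n))),
    score = c(scores_a, scores_n),
    label = rep(c("active", "decoy"), c(length(scores_a),
                                        length(scores_n))))
}

test_that("ROC AUC equals the concordant-pair-counting oracle", {
  # 5-molecule toy with a tie across classes
  lib <- toy_library(c(-12, -9), c(-10, -9, -5))
  r <- roc_enrichment(lib)
  expect_equal(r$auc, oracle_auc_pairs(lib$score, lib$label == "active"))
  set.seed(21)
  for (i in 1:10) {
    lib <- toy_library(round(rnorm(8, -1), 1), round(rnorm(15), 1))
    r <- roc_enrichment(lib)
    expect_equal(r$auc,
                 oracle_auc_pairs(lib$score, lib$label == "active"))
  }
})

test_that("ROC AUC equals the Mann-Whitney U normalization", {
  set.seed(4)
  lib <- toy_library(rnorm(20, -2), rnorm(50))
  r <- roc_enrichment(lib)
  w <- wilcox.test(lib$score[lib$label == "decoy"],
                   lib$score[lib$label == "active"])$statistic
  expect_equal(r$auc, unname(w) / (20 * 50))
})

test_that("perfect and random rankings bound the AUC", {
  lib <- toy_library(seq(-30, -25), seq(-20, -1))
  expect_equal(roc_enrichment(lib)$auc, 1)
  set.seed(99)
  big <- toy_library(rnorm(500), rnorm(500))
  expect_equal(roc_enrichment(big)$auc, 0.5, tolerance = 0.06)
  expect_error(roc_enrichment(toy_library(-1, numeric(0))), "at least one")
})

test_that("adjusted logAUC hits the analytic perfect and random values", {
  lib <- toy_library(seq(-30, -29.5, length.out = 50),
                     seq(-20, -1, length.out = 1000))
  r <- roc_enrichment(lib)
  expect_equal(adjusted_logauc(r, 0.001),
               100 - 100 * (1 - 0.001) / (log(10) * 3),
               tolerance = 1e-10)
  expect_equal(adjusted_logauc(r, 0.001), 85.54, tolerance = 1e-2)
  # an exactly diagonal ROC scores 0: fabricate alternating ranks via ties
  diag_lib <- toy_library(rep(1, 40), rep(1, 400))
  expect_equal(adjusted_logauc(roc_enrichment(diag_lib), 0.001), 0,
               tolerance = 1e-10)
  expect_error(adjusted_logauc(r, 0), "lambda")
  expect_error(adjusted_logauc(r, 1.2), "lambda")
})

test_that("adjusted logAUC agrees with fine-grid quadrature", {
  set.seed(12)
  for (i in 1:5) {
    lib <- toy_library(rnorm(15, -1.5), rnorm(60))
    r <- roc_enrichment(lib)
    expect_equal(adjusted_logauc(r, 0.001),
                 oracle_logauc_quadrature(r$points, 0.001),
                 tolerance = 1e-3)
  }
})

test_that("moving an active up in rank never lowers adjusted logAUC", {
  set.seed(33)
  for (rep in 1:10) {
    lib <- toy_library(rnorm(10, -0.5), rnorm(40))
    base <- adjusted_logauc(roc_enrichment(lib))
    i <- sample(which(lib$label == "active"), 1)
    lib2 <- lib
    lib2$score[i] <- min(lib$score) - runif(1)  # promote to best rank
    expect_gte(adjusted_logauc(roc_enrichment(lib2)) + 1e-10, base)
  }
})

test_that("ensemble best-score aggregation equals the row-min oracle", {
  m <- matrix(c(-20, -25, NA,
                -10, NA, -12,
                NA, NA, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:3)))
  expect_warning(out <- ensemble_combine(m), "excluded")
  expect_equal(out$score[out$molecule_id == "a"], -25)
  expect_equal(attr(out, "n_excluded"), 1)
  # single snapshot: identity
  one <- m[1:2, 1, drop = FALSE]
  expect_equal(ensemble_combine(one)$score, one[, 1],
               ignore_attr = TRUE)
  # random matrix vs exhaustive scan
  set.seed(6)
  rm_ <- matrix(rnorm(200), 20, 10,
                dimnames = list(sprintf("m%02d", 1:20), NULL))
  colnames(rm_) <- sprintf("s%02d", 1:10)
  rm_[sample(200, 30)] <- NA
  rm_[3, ] <- NA
  expect_warning(out <- ensemble_combine(rm_))
  oracle <- apply(rm_[rowSums(!is.na(rm_)) > 0, ], 1,
                  function(r) min(r[!is.na(r)]))
  expect_equal(out$score, unname(oracle))
  # ensemble best is never worse than any single snapshot
  for (j in 1:10) {
    sj <- rm_[out$molecule_id, j]
    ok <- !is.na(sj)
    expect_true(all(out$score[ok] <= sj[ok]))
  }
})

test_that("snapshot selection ranks by per-snapshot enrichment", {
  sl <- gen_score_library(n_actives = 20, n_decoys = 300,
                          n_snapshots = 10, active_shift = 1.5,
                          correlation = 0.3, seed = 14)
  sel <- select_snapshots(sl$scores, sl$labels, k = 10)
  lab <- sl$labels$label[match(rownames(sl$scores),
                               sl$labels$molecule_id)]
  oracle <- sapply(colnames(sl$scores), function(sn) {
    lib <- data.frame(molecule_id = rownames(sl$scores),
                      score = sl$scores[, sn], label = lab)
    adjusted_logauc(roc_enrichment(lib))
  })
  expect_equal(sel$snapshot_id,
               colnames(sl$scores)[order(-oracle, colnames(sl$scores))])
  expect_equal(sel$adj_logauc, unname(sort(oracle, decreasing = TRUE)))
  expect_equal(nrow(select_snapshots(sl$scores, sl$labels, k = 3)), 3)
  expect_error(select_snapshots(sl$scores, sl$labels, k = 11), "exceeds")
})

test_that("decoy matching equals exhaustive nearest-neighbour search", {
  set.seed(41)
  props <- function(n, pre) data.frame(
    molecule_id = sprintf("%s%03d", pre, 1:n),
    mw = runif(n, 150, 350), clogp = runif(n, 1, 5),
    hbd = rpois(n, 1), hba = rpois(n, 3),
    charge = sample(-1:1, n, TRUE), rotb = rpois(n, 4))
  act <- props(3, "act")
  pool <- props(60, "dec")
  got <- match_decoys(act, pool, n_per_active = 10)
  # independent re-derivation
  pm <- as.matrix(pool[, 3:8 - 1])
  mu <- colMeans(pm); sg <- apply(pm, 2, sd)
  pz <- scale(pm, mu, sg)
  az <- scale(as.matrix(act[, 2:7]), mu, sg)
  used <- character(0)
  for (i in 1:3) {
    d <- sqrt(colSums((t(pz) - az[i, ])^2))
    ord <- order(d, pool$molecule_id)
    pick <- setdiff(pool$molecule_id[ord], used)[1:10]
    expect_equal(got$decoy_id[got$active_id == act$molecule_id[i]], pick)
    used <- c(used, pick)
  }
  # no decoy reused
  expect_false(any(duplicated(got$decoy_id)))
})

test_that("decoy matching excludes topologically similar pool members", {
  act <- data.frame(molecule_id = "a1", mw = 250, clogp = 3, hbd = 1,
                    hba = 3, charge = 0, rotb = 4)
  pool <- data.frame(molecule_id = c("clone", "twin", "far"),
                     mw = c(250, 250, 500), clogp = c(3, 3, 6),
                     hbd = c(1, 1, 5), hba = c(3, 3, 9),
                     charge = c(0, 0, 1), rotb = c(4, 4, 12))
  fps <- rbind(a1 = c(1, 1, 1, 0, 0, 0))
  pfps <- rbind(clone = c(0, 0, 0, 1, 1, 1),  # property clone, distinct 2D
                twin = c(1, 1, 1, 0, 0, 0),   # same structure: excluded
                far = c(0, 1, 0, 1, 0, 1))
  got <- match_decoys(act, pool, active_fps = fps, pool_fps = pfps,
                      n_per_active = 1, tc_exclude = 0.35)
  expect_equal(got$decoy_id, "clone")
  expect_equal(got$distance, 0, tolerance = 1e-12)
  # pool exhaustion is reported per active
  expect_warning(
    short <- match_decoys(act, pool, active_fps = fps, pool_fps = pfps,
                          n_per_active = 5),
    "shortfall")
  expect_equal(unname(attr(short, "shortfall")["a1"]), 3)
})

test_that("expected adjusted logAUC under label permutation is near zero", {
  sl <- gen_score_library(n_actives = 25, n_decoys = 475,
                          n_snapshots = 1, active_shift = 0, seed = 50)
  comb <- ensemble_combine(sl$scores)
  set.seed(50)
  vals <- replicate(200, {
    lab <- sample(sl$labels$label)
    lib <- data.frame(molecule_id = comb$molecule_id,
                      score = comb$score, label = lab)
    adjusted_logauc(roc_enrichment(lib))
  })
  expect_lt(abs(mean(vals)), 1.0)
})
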