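test_that("library partition applies the MW/LogP windows and boundaries", {
  props <- data.frame(
    molecule_id = sprintf("m%d", 1:7),
    mw = c(200, 300, 300, 250, 349.9, 350, NA),
    clogp = c(3.0, 5.0, 4.5, 2.5, 2.5, 3.0, 3.0))
  p <- partition_library(props)
  expect_equal(p$category,
               c("fragment", "excluded", "lead_like", "lead_like",
                 "lead_like", "excluded", "excluded"))
  expect_equal(p$reason[2], "logp_window")
  expect_equal(p$reason[6], "mw_window")
  expect_equal(p$reason[7], "missing_properties")
  # a partition: every molecule in exactly one class
  expect_equal(sum(table(p$category)), nrow(props))
})

test_that("top-fraction cut keeps ceil(fraction*N), ties resolved by id", {
  lib <- data.frame(molecule_id = sprintf("m%04d", 1:1000),
                    score = rep(seq(-50, -1, length.out = 200), 5))
  out <- top_fraction(lib, 0.005)
  expect_equal(nrow(out), 5)
  # oracle: stable sort by (score, id)
  oracle <- lib[order(lib$score, lib$molecule_id), ][1:5, ]
  expect_equal(out$molecule_id, oracle$molecule_id)
  expect_equal(nrow(top_fraction(lib, 1.0)), 1000)
  expect_error(top_fraction(lib[0, ], 0.005), "empty")
  expect_error(top_fraction(lib, 0), "fraction")
  # deterministic under permutation of input order
  set.seed(8)
  perm <- lib[sample(nrow(lib)), ]
  expect_equal(top_fraction(perm, 0.005)$molecule_id, out$molecule_id)
})

test_that("hydrogen-bond filter matches the literal predicate", {
  cts <- data.frame(
    molecule_id = c("good", "good", "oneSite", "badGeom", "badGeom"),
    site = c("S246_sidechain", "L276_backbone", "S246_sidechain",
             "S246_sidechain", "L276_backbone"),
    distance = c(2.9, 3.1, 2.8, 2.9, 4.2),
    angle = c(160, 155, 170, 150, 160))
  keep <- hbond_filter(cts, molecules = c("good", "oneSite", "badGeom",
                                          "noPose"))
  expect_equal(as.character(keep), "good")
  expect_equal(attr(keep, "n_no_pose"), 1L)
  # randomized tables vs oracle, and order independence
  set.seed(15)
  for (i in 1:5) {
    n <- 120
    tab <- data.frame(
      molecule_id = sample(sprintf("m%02d", 1:25), n, TRUE),
      site = sample(c("S246_sidechain", "L276_backbone", "other"),
                    n, TRUE),
      distance = runif(n, 2.5, 5),
      angle = runif(n, 80, 180))
    req <- c("S246_sidechain", "L276_backbone")
    got <- hbond_filter(tab)
    expect_equal(as.character(got), oracle_hbond(tab, req, 3.5, 120))
    perm <- tab[sample(nrow(tab)), ]
    expect_equal(as.character(hbond_filter(perm)), as.character(got))
  }
  expect_error(hbond_filter(transform(cts, angle = 200)), "out of range")
})

test_that("Tanimoto similarity equals the popcount oracle", {
  a <- c(1, 1, 0, 1, 0, 0)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, 1 - a), 0)
  expect_equal(tanimoto(rep(0, 6), rep(0, 6)), 0)
  expect_error(tanimoto(a, c(1, 0)), "mismatch")
  set.seed(23)
  for (i in 1:20) {
    x <- rbinom(128, 1, 0.3)
    y <- rbinom(128, 1, 0.3)
    expect_equal(tanimoto(x, y), sum(x & y) / sum(x | y))
  }
})

test_that("leader clustering equals an independent greedy oracle", {
  fps <- rand_fps(20, nbits = 48, density = 0.35, seed = 77)
  scores <- setNames(rnorm(20, -30, 3), rownames(fps))
  cl <- leader_cluster(fps, scores, threshold = 0.5)
  oracle <- oracle_leader(fps, scores, 0.5)
  expect_equal(length(cl), length(oracle))
  for (i in seq_along(cl)) {
    expect_equal(cl[[i]]$representative_id, oracle[[i]]$rep)
    expect_setequal(cl[[i]]$member_ids, oracle[[i]]$members)
  }
  # coverage: every molecule in exactly one cluster
  members <- unlist(lapply(cl, `[[`, "member_ids"))
  expect_setequal(members, rownames(fps))
  expect_false(any(duplicated(members)))
  # founders are their cluster's best score and members pass threshold
  for (c_ in cl) {
    expect_equal(c_$representative_score,
                 min(scores[c_$member_ids]))
    for (m in c_$member_ids) {
      expect_gte(tanimoto(fps[c_$representative_id, ], fps[m, ]), 0.5)
    }
  }
})

test_that("clustering degenerate cases: all-distinct and all-identical", {
  fps <- diag(1, 5)  # pairwise Tanimoto 0
  rownames(fps) <- sprintf("m%d", 1:5)
  scores <- setNames(c(-3, -5, -1, -4, -2), rownames(fps))
  cl <- leader_cluster(fps, scores, threshold = 0.5)
  expect_equal(length(cl), 5)
  expect_equal(cl[[1]]$representative_id, "m2")  # best score founds first
  fps2 <- matrix(1, 4, 8, dimnames = list(sprintf("x%d", 1:4), NULL))
  cl2 <- leader_cluster(fps2, setNames(c(-1, -9, -4, -2),
                                       rownames(fps2)), 0.5)
  expect_equal(length(cl2), 1)
  expect_equal(cl2[[1]]$representative_id, "x2")
})

test_that("representatives are capped, ordered and pairwise dissimilar", {
  fps <- rand_fps(30, nbits = 64, density = 0.3, seed = 5)
  scores <- setNames(rnorm(30, -25, 4), rownames(fps))
  cl <- leader_cluster(fps, scores, threshold = 0.5)
  reps <- select_representatives(cl, max_clusters = 1000)
  expect_equal(nrow(reps), length(cl))
  expect_equal(reps$score, sort(reps$score))  # founding order = score order
  expect_equal(nrow(select_representatives(cl, max_clusters = 1)), 1)
  # all-pairs check: representatives below the clustering threshold
  for (i in seq_len(nrow(reps) - 1)) {
    for (j in (i + 1):nrow(reps)) {
      expect_lt(tanimoto(fps[reps$molecule_id[i], ],
                         fps[reps$molecule_id[j], ]), 0.5)
    }
  }
})

test_that("analog search agrees with an exhaustive scan", {
  mt <- gen_molecule_table(n = 50, seed = 61)
  lib <- mt$molecules[, c("molecule_id", "smiles")]
  query <- lib$smiles[1]
  got <- analog_search(query, lib, mode = "both", tc_min = 0.5)
  # oracle: per-molecule similarity + substructure by linear scan
  fps <- morgan_fp(lib$smiles, lib$molecule_id)
  qfp <- morgan_fp(query)[1, ]
  tcs <- apply(fps, 1, function(f) tanimoto(qfp, f))
  subs <- as.numeric(
    ChemmineOB::smartsSearch_OB(
      ChemmineOB::forEachMol("SMILES",
                             paste(lib$smiles, collapse = "\n"),
                             identity),
      query)) > 0
  expect_setequal(got$molecule_id,
                  lib$molecule_id[tcs >= 0.5 | subs])
  # the query itself is returned by both arms
  self <- got[got$molecule_id == lib$molecule_id[1], ]
  expect_true(self$substructure)
  expect_equal(self$tc, 1)
  # tc_min = 1 keeps only exact-fingerprint matches
  strict <- analog_search(query, lib, mode = "similarity", tc_min = 1)
  expect_setequal(strict$molecule_id, lib$molecule_id[tcs == 1])
  expect_error(analog_search("not_a_smiles((", lib), "unparseable")
})
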