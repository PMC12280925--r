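#' Partition a screening library into fragment and lead-like sets
#'
#' Applies the lipophilicity window (2.5 <= LogP <= 4.5, inclusive) and
#' molecular-weight classes: fragment (MW < 250 Da) and lead-like
#' (250 <= MW < 350 Da). MW exactly 250 goes to lead-like
#' (inclusive-lower convention). Molecules outside either window, or with
#' missing properties, are excluded with a reason.
#'
#' @param properties data frame with `molecule_id`, `mw`, `clogp`.
#' @return the input with added `category` (`"fragment"`, `"lead_like"`,
#'   `"excluded"`) and `reason` columns.
#' @export
partition_library <- function(properties) {
  stopifnot(all(c("molecule_id", "mw", "clogp") %in% names(properties)))
  mw <- properties$mw
  lp <- properties$clogp
  cat_ <- rep("excluded", nrow(properties))
  reason <- rep("", nrow(properties))
  missing <- !is.finite(mw) | !is.finite(lp)
  in_logp <- !missing & lp >= 2.5 & lp <= 4.5
  cat_[in_logp & mw < 250] <- "fragment"
  cat_[in_logp & mw >= 250 & mw < 350] <- "lead_like"
  reason[missing] <- "missing_properties"
  reason[!missing & !in_logp] <- "logp_window"
  reason[in_logp & mw >= 350] <- "mw_window"
  properties$category <- cat_
  properties$reason <- reason
  properties
}

#' Take the top-scoring fraction of a ranked library
#'
#' Keeps `ceiling(fraction * N)` molecules, ranked by score (best energy
#' first) with ties broken deterministically by molecule id.
#'
#' @param library data frame with `molecule_id` and `score`.
#' @param fraction fraction of the library to keep, in (0, 1]; the
#'   screening default is 0.005 (top 0.5%).
#' @param higher_is_better set `TRUE` when larger scores are better.
#' @return the retained rows, in rank order.
#' @export
top_fraction <- function(library, fraction = 0.005,
                         higher_is_better = FALSE) {
  stopifnot(all(c("molecule_id", "score") %in% names(library)))
  if (!nrow(library)) stop("empty library")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  s <- if (higher_is_better) -library$score else library$score
  k <- ceiling(fraction * nrow(library))
  out <- library[order(s, library$molecule_id), , drop = FALSE]
  out <- out[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond pose filter
#'
#' Retains a molecule only if its (best) docking pose makes a
#' geometrically sound hydrogen bond at *every* required site -- by
#' default the S246 (6.47) side chain and the L276 (7.41) backbone
#' carbonyl of the A1 receptor's extrahelical pocket: heavy-atom
#' donor-acceptor distance <= `dmax` and donor-H...acceptor angle >=
#' `amin`.
#'
#' @param contacts data frame with `molecule_id`, `site`, `distance`
#'   (Angstrom), `angle` (degrees), one row per candidate contact of each
#'   molecule's selected pose.
#' @param required site labels that must all be satisfied.
#' @param dmax,amin geometric cutoffs (defaults 3.5 Angstrom, 120 deg).
#' @param molecules optional universe of molecule ids; ids without any
#'   contact record are dropped and counted in attribute `n_no_pose`.
#' @return sorted character vector of retained molecule ids, with
#'   attribute `n_no_pose`.
#' @export
hbond_filter <- function(contacts,
                         required = c("S246_sidechain", "L276_backbone"),
                         dmax = 3.5, amin = 120, molecules = NULL) {
  stopifnot(all(c("molecule_id", "site", "distance", "angle") %in%
                  names(contacts)))
  if (any(contacts$distance <= 0) ||
      any(contacts$angle < 0 | contacts$angle > 180)) {
    stop("contact geometry out of range (distance > 0, angle in [0, 180])")
  }
  ok <- contacts$distance <= dmax & contacts$angle >= amin &
    contacts$site %in% required
  good <- contacts[ok, c("molecule_id", "site")]
  retained <- if (nrow(good)) {
    n_sites <- tapply(good$site, good$molecule_id,
                      function(s) length(unique(s)))
    sort(names(n_sites)[n_sites == length(required)])
  } else {
    character(0)
  }
  n_no_pose <- 0L
  if (!is.null(molecules)) {
    n_no_pose <- sum(!(molecules %in% contacts$molecule_id))
  }
  structure(retained, n_no_pose = n_no_pose)
}

#' Greedy leader clustering of scored molecules
#'
#' The best-scoring unassigned molecule founds a cluster; every unassigned
#' molecule with fingerprint Tanimoto >= `threshold` to the founder joins
#' it; repeat until all molecules are assigned. Clusters are emitted in
#' founding order, so they are ordered by representative score; the
#' founder is the best-scoring member by construction. Ties in score are
#' broken by molecule id, making the clustering deterministic.
#'
#' @param fingerprints 0/1 matrix with molecule ids as rownames.
#' @param scores named numeric vector of docking scores (lower = better),
#'   names matching the fingerprint rownames.
#' @param threshold Tanimoto similarity threshold (default 0.5).
#' @return list of clusters, each `list(representative_id, member_ids,
#'   representative_score)`; class `leader_clustering`.
#' @export
leader_cluster <- function(fingerprints, scores, threshold = 0.5) {
  stopifnot(is.matrix(fingerprints), !is.null(rownames(fingerprints)),
            all(rownames(fingerprints) %in% names(scores)))
  ids <- rownames(fingerprints)
  ord <- order(scores[ids], ids)
  ids <- ids[ord]
  fp <- fingerprints[ids, , drop = FALSE] > 0
  assigned <- rep(FALSE, length(ids))
  clusters <- list()
  while (!all(assigned)) {
    lead <- which(!assigned)[1]
    cand <- which(!assigned)
    sims <- vapply(cand, function(j) {
      u <- sum(fp[lead, ] | fp[j, ])
      if (u == 0) 0 else sum(fp[lead, ] & fp[j, ]) / u
    }, numeric(1))
    members <- cand[sims >= threshold | cand == lead]
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1]] <- list(
      representative_id = ids[lead],
      member_ids = ids[members],
      representative_score = unname(scores[ids[lead]]))
  }
  structure(clusters, class = "leader_clustering")
}

#' @export
print.leader_clustering <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "member_ids"))
  cat(sprintf("%d clusters over %d molecules (sizes: %s)\n",
              length(x), sum(sizes),
              paste(utils::head(sizes, 10), collapse = ", ")))
  invisible(x)
}

#' Best-scoring cluster representatives
#'
#' Takes the representative of each of the first `max_clusters` clusters
#' (clusters arrive ordered by representative score from
#' [leader_cluster]).
#'
#' @param clusters a `leader_clustering`.
#' @param max_clusters number of clusters to draw from (screening default
#'   1000).
#' @return data frame `molecule_id`, `score`, `cluster_size` in cluster
#'   order.
#' @export
select_representatives <- function(clusters, max_clusters = 1000) {
  take <- utils::head(clusters, max_clusters)
  data.frame(
    molecule_id = vapply(take, `[[`, "", "representative_id"),
    score = vapply(take, `[[`, 0, "representative_score"),
    cluster_size = vapply(take, function(cl) length(cl$member_ids), 0L),
    stringsAsFactors = FALSE)
}

#' Substructure and similarity analog search
#'
#' Finds library molecules containing the query as a substructure and/or
#' with circular-fingerprint Tanimoto >= `tc_min` to the query; the union
#' is deduplicated by molecule id.
#'
#' @param query_smiles SMILES of the query molecule.
#' @param library data frame with `molecule_id` and `smiles`.
#' @param mode `"substructure"`, `"similarity"` or `"both"`.
#' @param tc_min Tanimoto threshold for the similarity arm (default 0.5).
#' @return data frame `molecule_id`, `substructure` (logical), `tc`.
#' @export
analog_search <- function(query_smiles, library,
                          mode = c("both", "substructure", "similarity"),
                          tc_min = 0.5) {
  mode <- match.arg(mode)
  stopifnot(all(c("molecule_id", "smiles") %in% names(library)))
  qm <- tryCatch(ob_parse(query_smiles),
                 error = function(e) stop("unparseable query SMILES"))
  lib_mols <- ob_parse(library$smiles)
  sub_hit <- rep(FALSE, nrow(library))
  if (mode %in% c("both", "substructure")) {
    counts <- ChemmineOB::smartsSearch_OB(lib_mols, query_smiles)
    sub_hit <- as.numeric(counts) > 0
  }
  tc <- rep(NA_real_, nrow(library))
  sim_hit <- rep(FALSE, nrow(library))
  if (mode %in% c("both", "similarity")) {
    qfp <- morgan_fp(query_smiles)[1, ]
    lfp <- morgan_fp(library$smiles, library$molecule_id)
    tc <- vapply(seq_len(nrow(library)),
                 function(i) tanimoto(qfp, lfp[i, ]), numeric(1))
    sim_hit <- tc >= tc_min
  }
  keep <- sub_hit | sim_hit
  out <- data.frame(molecule_id = library$molecule_id[keep],
                    substructure = sub_hit[keep], tc = tc[keep],
                    stringsAsFactors = FALSE)
  out[!duplicated(out$molecule_id), , drop = FALSE]
}
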