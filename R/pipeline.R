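# Deterministic fan-out of a single top-level seed into per-stage child
# seeds (pure double arithmetic, result < 2^31).
child_seed <- function(seed, stage) {
  ((seed %% 100003) * 7919 + stage * 104729) %% 2147483647L
}

default_config <- function() {
  list(mode = "pharmacology",
       seed = 1L,
       preset = "compound12",
       n_experiments = 1L,
       design = list(),          # sim_design overrides
       lambda = 0.001,
       alpha = 0.05,
       top_fraction = 0.005,
       tc_threshold = 0.5,
       max_clusters = 1000L,
       hbond = list(dmax = 3.5, amin = 120),
       n_snapshots_keep = 5L,
       score_library = list(),   # gen_score_library overrides
       n_molecules = 100L,
       out_dir = NULL)
}

#' Run an end-to-end analysis pipeline
#'
#' Two modes, both fully seeded and reproducible:
#' \describe{
#'   \item{`"pharmacology"`}{simulate interaction-binding and functional
#'     data for a preset compound, fit the allosteric ternary complex
#'     model and the operational model of allosterism, and report the
#'     recovered pKB, log alpha, log alphabeta, log tau_B with SEs.}
#'   \item{`"screening"`}{generate a synthetic docking score library and
#'     molecule table, evaluate per-snapshot and ensemble enrichment
#'     (adjusted logAUC), then run the triage funnel: library partition,
#'     top-fraction cut, hydrogen-bond pose filter, leader clustering and
#'     representative selection.}
#' }
#' The top-level seed fans out deterministically into per-stage child
#' seeds, and the effective configuration is echoed into the report.
#'
#' @param config list overriding the defaults (see
#'   `allomod:::default_config()`); unknown keys are rejected. May also be
#'   a path to a JSON config file.
#' @return the run report (list, class `allomod_report`), also written to
#'   `file.path(out_dir, "report.json")` when `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(base, config)
  report <- list(config = cfg, stages = list(), warnings = character(0),
                 seeds = list(top = cfg$seed))
  run_stage <- function(name, expr) {
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    report$stages[[name]] <<- res
    res
  }

  if (cfg$mode == "pharmacology") {
    truth <- pam_truth(cfg$preset)
    des_b <- do.call(sim_design,
                     c(list(assay = "binding"), cfg$design))
    des_f <- do.call(sim_design,
                     c(list(assay = "functional"), cfg$design))
    s1 <- child_seed(cfg$seed, 1L)
    s2 <- child_seed(cfg$seed, 2L)
    report$seeds$binding <- s1
    report$seeds$functional <- s2
    run_stage("simulate", list(
      preset = cfg$preset,
      n_binding_points = length(des_b$agonist_concs) *
        length(des_b$modulator_concs) * des_b$n_replicates,
      n_functional_points = length(des_f$agonist_concs) *
        length(des_f$modulator_concs) * des_f$n_replicates))
    bdat <- gen_interaction_binding(truth$binding, des_b, seed = s1)
    fdat <- gen_functional(truth$functional, des_f, seed = s2)
    bfit <- fit_atcm(bdat, pKA = truth$binding[["pKA"]], seed = s1)
    run_stage("fit_binding", list(
      params = as.list(bfit$params), se = as.list(bfit$se),
      rss = bfit$rss, converged = bfit$converged))
    ffit <- fit_operational(
      fdat, pKA = truth$functional[["pKA"]],
      pKB = bfit$params[["pKB"]],
      log_alpha = bfit$params[["log_alpha_I"]], seed = s2)
    run_stage("fit_functional", list(
      params = as.list(ffit$params), se = as.list(ffit$se),
      derived = as.list(ffit$derived),
      rss = ffit$rss, converged = ffit$converged))
    report$estimates <- list(
      pKB = bfit$params[["pKB"]],
      log_alpha = bfit$params[["log_alpha_I"]],
      log_alphabeta = unname(ffit$derived[["log_alphabeta"]]),
      log_tau_B = ffit$params[["log_tau_B"]])
  } else if (cfg$mode == "screening") {
    s1 <- child_seed(cfg$seed, 1L)
    s2 <- child_seed(cfg$seed, 2L)
    report$seeds$scores <- s1
    report$seeds$molecules <- s2
    lib <- do.call(gen_score_library,
                   c(cfg$score_library, list(seed = s1)))
    snaps <- select_snapshots(lib$scores, lib$labels,
                              k = min(cfg$n_snapshots_keep,
                                      ncol(lib$scores)),
                              lambda = cfg$lambda)
    combined <- ensemble_combine(
      lib$scores[, snaps$snapshot_id, drop = FALSE])
    ranked <- merge(combined, lib$labels, by = "molecule_id")
    roc <- roc_enrichment(ranked)
    run_stage("enrich", list(
      n_molecules = nrow(ranked),
      snapshots = snaps,
      auc = roc$auc,
      adj_logauc = adjusted_logauc(roc, cfg$lambda)))
    mt <- gen_molecule_table(n = cfg$n_molecules, seed = s2)
    part <- partition_library(mt$molecules)
    in_window <- part[part$category != "excluded", ]
    cut <- top_fraction(
      data.frame(molecule_id = in_window$molecule_id,
                 score = in_window$dock_score),
      fraction = cfg$top_fraction)
    keep_contacts <- mt$contacts[mt$contacts$molecule_id %in%
                                   cut$molecule_id, ]
    retained <- hbond_filter(keep_contacts,
                             dmax = cfg$hbond$dmax,
                             amin = cfg$hbond$amin,
                             molecules = cut$molecule_id)
    fps <- mt$fingerprints[retained, , drop = FALSE]
    scores <- stats::setNames(mt$molecules$dock_score,
                              mt$molecules$molecule_id)[retained]
    cand <- if (length(retained)) {
      select_representatives(
        leader_cluster(fps, scores, threshold = cfg$tc_threshold),
        max_clusters = cfg$max_clusters)
    } else {
      data.frame(molecule_id = character(0), score = numeric(0),
                 cluster_size = integer(0))
    }
    run_stage("triage", list(
      counts = c(total = nrow(mt$molecules),
                 in_window = nrow(in_window),
                 after_rank_cut = nrow(cut),
                 after_hbond = length(retained),
                 candidates = nrow(cand)),
      candidates = cand))
  } else {
    stop("unknown pipeline mode: ", cfg$mode)
  }

  class(report) <- "allomod_report"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.allomod_report <- function(x, ...) {
  cat("allomod pipeline report (mode:", x$config$mode, ")\n")
  cat("stages:", paste(names(x$stages), collapse = " -> "), "\n")
  if (!is.null(x$estimates)) {
    cat("estimates:\n")
    for (nm in names(x$estimates)) {
      cat(sprintf("  %-14s %8.3f\n", nm, x$estimates[[nm]]))
    }
  }
  if (!is.null(x$stages$triage)) {
    print(x$stages$triage$counts)
  }
  if (length(x$warnings)) {
    cat("warnings:\n"); for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}
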