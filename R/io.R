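# Readers and writers for the plain-text dialects the pipeline consumes:
# CSV assay tables (with explicit unit column), TSV score matrices and
# label files, .smi structure files, JSON fit reports.

#' Read an assay CSV
#'
#' Binding files have columns
#' `replicate,radioligand_conc,agonist_conc,modulator_conc,response,unit`;
#' functional files omit `radioligand_conc`. Concentrations are converted
#' to molar using the per-row `unit` column.
#'
#' @param path CSV path.
#' @param type `"binding"` or `"functional"`.
#' @return data frame in the package's molar-concentration format
#'   (`binding` or `response` response column).
#' @export
read_assay_csv <- function(path, type = c("binding", "functional")) {
  type <- match.arg(type)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "agonist_conc", "modulator_conc", "response",
            "unit")
  if (type == "binding") need <- c(need, "radioligand_conc")
  if (!all(need %in% names(d))) {
    stop("missing columns: ", paste(setdiff(need, names(d)),
                                    collapse = ", "))
  }
  d$agonist_conc <- to_molar(d$agonist_conc, d$unit)
  d$modulator_conc <- to_molar(d$modulator_conc, d$unit)
  if (type == "binding") {
    d$radioligand_conc <- to_molar(d$radioligand_conc, d$unit)
    d$binding <- d$response
    d[c("replicate", "radioligand_conc", "agonist_conc",
        "modulator_conc", "binding")]
  } else {
    d[c("replicate", "agonist_conc", "modulator_conc", "response")]
  }
}

#' Write an assay table as CSV (molar concentrations, unit column "M")
#' @param data assay data frame from the generators.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(data, path) {
  d <- data
  d$unit <- "M"
  if ("binding" %in% names(d)) d$response <- d$binding
  utils::write.csv(
    d[intersect(c("replicate", "radioligand_conc", "agonist_conc",
                  "modulator_conc", "response", "unit"), names(d))],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format TSV score matrix
#'
#' Expects columns `molecule_id`, `snapshot_id`, `score`; returns the
#' molecules x snapshots matrix with `NA` for pairs not listed.
#'
#' @param path TSV path.
#' @return numeric matrix.
#' @export
read_scores_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("molecule_id", "snapshot_id", "score") %in% names(d)))
  mols <- sort(unique(d$molecule_id))
  snaps <- sort(unique(d$snapshot_id))
  m <- matrix(NA_real_, length(mols), length(snaps),
              dimnames = list(mols, snaps))
  m[cbind(match(d$molecule_id, mols), match(d$snapshot_id, snaps))] <-
    d$score
  m
}

#' Write a score matrix as long-format TSV (missing entries omitted)
#' @param scores molecules x snapshots matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  long <- data.frame(
    molecule_id = rep(rownames(scores), ncol(scores)),
    snapshot_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores))
  long <- long[is.finite(long$score), ]
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a molecule label TSV (`molecule_id`, `label`)
#' @param path TSV path.
#' @return data frame.
#' @export
read_labels_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("molecule_id", "label") %in% names(d)))
  d
}

#' Read a .smi structure file (`SMILES<whitespace>molecule_id` per line)
#' @param path .smi path.
#' @return data frame `molecule_id`, `smiles`.
#' @export
read_smi <- function(path) {
  d <- utils::read.table(path, col.names = c("smiles", "molecule_id"),
                         stringsAsFactors = FALSE)
  d[c("molecule_id", "smiles")]
}

#' Serialize a fit as JSON
#'
#' Writes parameters, standard errors, the fixed-parameter list, RSS and
#' convergence status.
#'
#' @param fit a `pharmfit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(model = class(fit)[1],
                  params = as.list(fit$params),
                  std_errors = as.list(fit$se),
                  fixed = fit$fixed,
                  rss = fit$rss, n_points = fit$n_points,
                  converged = fit$converged, reason = fit$reason)
  if (!is.null(fit$derived)) payload$derived <- as.list(fit$derived)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
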