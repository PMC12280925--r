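#' Simulation design for synthetic assay data
#'
#' Captures the experimental design the generators reproduce: the agonist
#' concentration grid, the modulator concentrations, the radioligand
#' concentration, replicate count and proportional noise level. Defaults
#' mirror the interaction-binding design (NECA 0.3 nM-10 uM in half-log
#' steps plus an agonist-free point; modulator 0/3/10/30 uM; ~1 nM
#' radioligand; n = 4 replicates; 5% CV) and the functional design
#' (agonist 0.01 nM-100 uM).
#'
#' @param assay `"binding"` or `"functional"`; picks the default agonist
#'   grid.
#' @param agonist_concs molar agonist grid (includes 0).
#' @param modulator_concs molar modulator concentrations (must include 0).
#' @param radioligand_conc molar radioligand concentration (binding only).
#' @param n_replicates simulated experiments per dataset.
#' @param noise_cv proportional Gaussian noise SD as a fraction of the
#'   predicted value.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(assay = c("binding", "functional"),
                       agonist_concs = NULL,
                       modulator_concs = c(0, 3e-6, 1e-5, 3e-5),
                       radioligand_conc = 1e-9,
                       n_replicates = 4, noise_cv = 0.05) {
  assay <- match.arg(assay)
  if (is.null(agonist_concs)) {
    agonist_concs <- if (assay == "binding") {
      c(0, 10^seq(-9.5, -5, by = 0.5))
    } else {
      c(0, 10^seq(-11, -4, by = 0.5))
    }
  }
  stopifnot(length(agonist_concs) > 0, length(modulator_concs) > 0,
            noise_cv >= 0, n_replicates >= 1)
  structure(list(assay = assay, agonist_concs = agonist_concs,
                 modulator_concs = modulator_concs,
                 radioligand_conc = radioligand_conc,
                 n_replicates = n_replicates, noise_cv = noise_cv),
            class = "sim_design")
}

#' Ground-truth parameter bundles for the characterized PAM compounds
#'
#' Binding (allosteric ternary complex) and functional (operational model)
#' parameter sets for the reference PAM (compound 1) and the
#' 2-aminothiazole PAMs (compounds 12, 54, 56), built from their reported
#' affinity, cooperativity and efficacy estimates. Values not determinable
#' from those reports (radioligand and agonist affinities, agonist
#' efficacy, the modulator-radioligand cooperativity, compound 56's
#' affinity) are package defaults documented in the methods vignette.
#'
#' @param compound one of `"compound1"`, `"compound12"`, `"compound54"`,
#'   `"compound56"`.
#' @return list with elements `binding` (parameters for [predict_atcm])
#'   and `functional` (parameters for [predict_operational]).
#' @export
pam_truth <- function(compound = c("compound1", "compound12",
                                   "compound54", "compound56")) {
  compound <- match.arg(compound)
  # shared assay constants
  pKA_radio <- 8.70   # [3H]DPCPX
  pKI_neca <- 6.50    # NECA binding affinity
  pKA_neca <- 6.50    # NECA functional affinity (constrained from binding)
  log_tau_A <- 1.0    # full agonist with receptor reserve
  log_alpha_A <- log10(0.7)  # modest negative cooperativity vs antagonist
  tab <- list(
    compound1  = c(pKB = 5.18, log_alpha = 2.09, log_ab = 0.78,
                   log_tau_B = 0.56),
    compound12 = c(pKB = 4.63, log_alpha = 0.99, log_ab = 0.68,
                   log_tau_B = -0.65),
    compound54 = c(pKB = 5.15, log_alpha = 1.15, log_ab = 0.84,
                   log_tau_B = -0.37),
    compound56 = c(pKB = 4.60, log_alpha = 1.30, log_ab = 0.92,
                   log_tau_B = -0.07))[[compound]]
  list(
    binding = c(bmax = 100, pKA = pKA_radio, pKB = unname(tab["pKB"]),
                pKI = pKI_neca, log_alpha_A = log_alpha_A,
                log_alpha_I = unname(tab["log_alpha"])),
    functional = c(em = 100, pKA = pKA_neca, pKB = unname(tab["pKB"]),
                   log_tau_A = log_tau_A,
                   log_tau_B = unname(tab["log_tau_B"]),
                   log_alpha = unname(tab["log_alpha"]),
                   log_beta = unname(tab["log_ab"] - tab["log_alpha"]),
                   n = 1))
}

sim_noise <- function(mu, noise_cv) {
  mu * (1 + stats::rnorm(length(mu), 0, noise_cv))
}

#' Generate synthetic radioligand interaction-binding data
#'
#' Draws `n_replicates` replicate experiments from the allosteric ternary
#' complex model over the (agonist x modulator) design grid, with
#' independent proportional Gaussian noise
#' (`Y = mu * (1 + eps)`, `eps ~ N(0, noise_cv)`).
#'
#' @param truth named parameter vector for [predict_atcm].
#' @param design a [sim_design] (binding assay).
#' @param seed integer seed; the output is a pure function of
#'   (truth, design, seed).
#' @return data frame `replicate`, `radioligand_conc`, `agonist_conc`,
#'   `modulator_conc`, `binding`; attributes `truth` and `seed`.
#' @export
gen_interaction_binding <- function(truth, design = sim_design("binding"),
                                    seed = 1L) {
  grid <- expand.grid(agonist_conc = design$agonist_concs,
                      modulator_conc = design$modulator_concs,
                      KEEP.OUT.ATTRS = FALSE)
  mu <- predict_atcm(truth, design$radioligand_conc, grid$agonist_conc,
                     grid$modulator_conc)
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(design$n_replicates), function(r) {
      data.frame(replicate = r,
                 radioligand_conc = design$radioligand_conc,
                 agonist_conc = grid$agonist_conc,
                 modulator_conc = grid$modulator_conc,
                 binding = sim_noise(mu, design$noise_cv))
    }))
  })
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  out
}

#' Generate synthetic cAMP functional data
#'
#' As [gen_interaction_binding] but from the operational model of
#' allosterism over the functional design grid.
#'
#' @param truth named parameter vector for [predict_operational].
#' @param design a [sim_design] (functional assay).
#' @param seed integer seed.
#' @return data frame `replicate`, `agonist_conc`, `modulator_conc`,
#'   `response`; attributes `truth` and `seed`.
#' @export
gen_functional <- function(truth, design = sim_design("functional"),
                           seed = 1L) {
  grid <- expand.grid(agonist_conc = design$agonist_concs,
                      modulator_conc = design$modulator_concs,
                      KEEP.OUT.ATTRS = FALSE)
  mu <- predict_operational(truth, grid$agonist_conc, grid$modulator_conc)
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(design$n_replicates), function(r) {
      data.frame(replicate = r,
                 agonist_conc = grid$agonist_conc,
                 modulator_conc = grid$modulator_conc,
                 response = sim_noise(mu, design$noise_cv))
    }))
  })
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  out
}

#' Generate replicate-level screen data (control vs treated pK_I / pEC50)
#'
#' Simulates a primary screen: each compound has a true effect on agonist
#' affinity and potency (zero under the null), and per-replicate control
#' and treated estimates are drawn with Gaussian replicate noise.
#'
#' @param effects data frame `compound`, `d_pKI`, `d_pEC50`; by default a
#'   26-compound screen in which compounds hit1-hit3 carry a strong
#'   (+0.5 log unit) enhancement of both endpoints and the rest are null.
#' @param control_pKI,control_pEC50 true control values.
#' @param n_replicates matched replicates per compound.
#' @param rep_sd replicate SD of each estimate (log units).
#' @param seed integer seed.
#' @return list with `control` and `treated` data frames for
#'   [screen_deltas].
#' @export
gen_screen <- function(effects = NULL, control_pKI = 6.5,
                       control_pEC50 = 7.5, n_replicates = 4,
                       rep_sd = 0.1, seed = 1L) {
  if (is.null(effects)) {
    effects <- data.frame(
      compound = c(paste0("hit", 1:3), paste0("cmpd", 4:26)),
      d_pKI = c(rep(0.5, 3), rep(0, 23)),
      d_pEC50 = c(rep(0.5, 3), rep(0, 23)))
  }
  stopifnot(all(c("compound", "d_pKI", "d_pEC50") %in% names(effects)),
            all(is.finite(effects$d_pKI)), all(is.finite(effects$d_pEC50)))
  with_seed(seed, {
    reps <- expand.grid(replicate = seq_len(n_replicates),
                        compound = effects$compound,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    i <- match(reps$compound, effects$compound)
    nr <- nrow(reps)
    control <- data.frame(
      compound = reps$compound, replicate = reps$replicate,
      pKI = control_pKI + stats::rnorm(nr, 0, rep_sd),
      pEC50 = control_pEC50 + stats::rnorm(nr, 0, rep_sd))
    treated <- data.frame(
      compound = reps$compound, replicate = reps$replicate,
      pKI = control_pKI + effects$d_pKI[i] + stats::rnorm(nr, 0, rep_sd),
      pEC50 = control_pEC50 + effects$d_pEC50[i] +
        stats::rnorm(nr, 0, rep_sd))
    list(control = control, treated = treated, effects = effects)
  })
}

#' Generate a synthetic docking score library
#'
#' Scores are correlated Gaussians across snapshots
#' (`score = base + shift_i + sd * (sqrt(rho) z_mol + sqrt(1-rho) e)`),
#' with actives shifted toward better (more negative) energies by
#' `active_shift`. Missing entries (failed docking) are inserted at
#' `missing_rate`.
#'
#' @param n_actives,n_decoys,n_snapshots library dimensions.
#' @param active_shift energy advantage of actives (kcal/mol-like units).
#' @param sd score SD.
#' @param correlation cross-snapshot score correlation in [0, 1].
#' @param missing_rate fraction of entries missing, in [0, 1).
#' @param base mean decoy score.
#' @param seed integer seed.
#' @return list with `scores` (molecules x snapshots matrix, `NA` for
#'   missing) and `labels` (data frame `molecule_id`, `label`).
#' @export
gen_score_library <- function(n_actives = 50, n_decoys = 2000,
                              n_snapshots = 10, active_shift = 2,
                              sd = 1, correlation = 0.5,
                              missing_rate = 0, base = -20, seed = 1L) {
  stopifnot(n_actives > 0, n_decoys > 0, n_snapshots > 0,
            correlation >= 0, correlation <= 1,
            missing_rate >= 0, missing_rate < 1)
  n <- n_actives + n_decoys
  ids <- c(sprintf("act%04d", seq_len(n_actives)),
           sprintf("dec%05d", seq_len(n_decoys)))
  labels <- data.frame(molecule_id = ids,
                       label = rep(c("active", "decoy"),
                                   c(n_actives, n_decoys)),
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    z <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * n_snapshots), n, n_snapshots)
    sc <- base + sd * (sqrt(correlation) * z +
                         sqrt(1 - correlation) * e)
    sc[seq_len(n_actives), ] <- sc[seq_len(n_actives), ] - active_shift
    if (missing_rate > 0) {
      sc[stats::runif(length(sc)) < missing_rate] <- NA
    }
    dimnames(sc) <- list(ids, sprintf("snap%03d", seq_len(n_snapshots)))
    list(scores = sc, labels = labels)
  })
}

# decoration fragments appended to the scaffold attachment point
.decorations <- c("", "C", "CC", "CCC", "CCCC", "C(C)C", "F", "Cl", "Br",
                  "OC", "OCC", "C(F)(F)F")
.scaffolds <- c(
  aminothiazole_aryl = "Nc1scc(n1)-c1ccc(cc1)%s",
  aminothiazole_naph = "Nc1sc(%s)c(n1)-c1ccc2ccccc2c1",
  biphenyl = "c1ccc(cc1)-c1ccc(cc1)%s",
  indole = "c1ccc2c(c1)cc([nH]2)%s")

#' Generate a synthetic molecule table with poses
#'
#' Builds template-derived SMILES (2-aminothiazole-like and related
#' scaffolds with small decorations), samples physicochemical properties
#' so the set populates the fragment and lead-like screening windows,
#' computes circular fingerprints, draws docking scores, and emits
#' per-molecule hydrogen-bond contact records whose probability of
#' satisfying the pose filter is `hbond_prob`.
#'
#' @param n number of molecules.
#' @param frac_fragment,frac_lead fractions targeted at the fragment and
#'   lead-like windows; the remainder is sampled outside the windows.
#' @param hbond_prob probability a molecule's best pose hydrogen-bonds at
#'   both required sites within the filter cutoffs.
#' @param scaffolds subset of the built-in scaffold templates to draw
#'   from (names of `allomod:::.scaffolds`).
#' @param decorations substituent SMILES fragments to sample.
#' @param seed integer seed.
#' @return list with `molecules` (data frame: `molecule_id`, `smiles`,
#'   `mw`, `clogp`, `hbd`, `hba`, `charge`, `rotb`, `dock_score`),
#'   `fingerprints` (0/1 matrix) and `contacts` (pose contact records for
#'   [hbond_filter]).
#' @export
gen_molecule_table <- function(n = 100, frac_fragment = 0.4,
                               frac_lead = 0.4, hbond_prob = 0.5,
                               scaffolds = names(.scaffolds),
                               decorations = .decorations, seed = 1L) {
  stopifnot(n > 0, frac_fragment + frac_lead <= 1)
  scaffolds <- .scaffolds[scaffolds]
  with_seed(seed, {
    ids <- sprintf("mol%05d", seq_len(n))
    smi <- sprintf(sample(scaffolds, n, replace = TRUE),
                   sample(decorations, n, replace = TRUE))
    grp <- sample(c("fragment", "lead", "outside"), n, replace = TRUE,
                  prob = c(frac_fragment, frac_lead,
                           max(0, 1 - frac_fragment - frac_lead)))
    mw <- ifelse(grp == "fragment", stats::runif(n, 150, 249),
          ifelse(grp == "lead", stats::runif(n, 250, 349),
                 stats::runif(n, 360, 500)))
    clogp <- ifelse(grp == "outside", stats::runif(n, 4.6, 6.5),
                    stats::runif(n, 2.5, 4.5))
    mols <- data.frame(
      molecule_id = ids, smiles = smi, mw = mw, clogp = clogp,
      hbd = stats::rpois(n, 1), hba = stats::rpois(n, 3),
      charge = sample(c(-1, 0, 0, 0, 0, 1), n, replace = TRUE),
      rotb = stats::rpois(n, 4),
      dock_score = stats::rnorm(n, -30, 5),
      stringsAsFactors = FALSE)
    good <- stats::runif(n) < hbond_prob
    contacts <- do.call(rbind, lapply(seq_len(n), function(i) {
      sites <- c("S246_sidechain", "L276_backbone")
      if (good[i]) {
        data.frame(molecule_id = ids[i], site = sites,
                   distance = stats::runif(2, 2.6, 3.4),
                   angle = stats::runif(2, 130, 175))
      } else {
        # fail at least one required site: bad geometry or absent contact
        mode <- sample(c("bad_dist", "bad_angle", "one_site"), 1)
        switch(mode,
          bad_dist = data.frame(molecule_id = ids[i], site = sites,
                                distance = stats::runif(2, 3.6, 6),
                                angle = stats::runif(2, 130, 175)),
          bad_angle = data.frame(molecule_id = ids[i], site = sites,
                                 distance = stats::runif(2, 2.6, 3.4),
                                 angle = stats::runif(2, 60, 115)),
          one_site = data.frame(molecule_id = ids[i], site = sites[1],
                                distance = stats::runif(1, 2.6, 3.4),
                                angle = stats::runif(1, 130, 175)))
      }
    }))
    fps <- morgan_fp(mols$smiles, ids)
    list(molecules = mols, fingerprints = fps, contacts = contacts)
  })
}
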