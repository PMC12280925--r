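# SMILES handling and circular fingerprints, backed by Open Babel
# (ChemmineOB). Fingerprints are ECFP-style radius-2 circular bits folded
# to 2048.

ob_parse <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  if (length(mols) != length(smiles)) {
    stop("unparseable SMILES in input (",
         length(smiles) - length(mols), " rejected)")
  }
  mols
}

#' Radius-2 circular (ECFP4-type) fingerprints from SMILES
#'
#' Computes 2048-bit binary circular fingerprints (radius 2, no counts)
#' for a vector of SMILES. The underlying Open Babel ECFP4 bits are folded
#' to the declared 2048-bit length.
#'
#' @param smiles character vector of SMILES.
#' @param ids rownames for the result (default the SMILES themselves).
#' @return integer 0/1 matrix, one row per molecule, 2048 columns.
#' @seealso [tanimoto], [leader_cluster]
#' @export
morgan_fp <- function(smiles, ids = smiles) {
  stopifnot(length(ids) == length(smiles))
  f <- ChemmineOB::fingerprint_OB(ob_parse(smiles), "ECFP4")
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  half <- ncol(f) / 2
  folded <- (f[, seq_len(half), drop = FALSE] +
               f[, half + seq_len(half), drop = FALSE]) > 0
  m <- matrix(as.integer(folded), nrow = nrow(f))
  rownames(m) <- ids
  m
}

#' Physicochemical properties from SMILES
#'
#' Molecular weight, cLogP, H-bond donor/acceptor counts, net formal
#' charge and rotatable-bond count -- the six-field property vector used
#' for decoy matching and library partitioning. MW, LogP, HBD and HBA come
#' from Open Babel descriptors; rotatable bonds from a SMARTS count and
#' the net charge from the canonical SMILES.
#'
#' @param smiles character vector of SMILES.
#' @param ids molecule ids for the result.
#' @return data frame `molecule_id`, `mw`, `clogp`, `hbd`, `hba`,
#'   `charge`, `rotb`.
#' @export
mol_properties <- function(smiles, ids = smiles) {
  mols <- ob_parse(smiles)
  p <- ChemmineOB::prop_OB(mols)
  rot <- ChemmineOB::smartsSearch_OB(
    mols, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  charge <- vapply(p$cansmi, function(s) {
    chunks <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    sum(vapply(chunks, function(ch) {
      plus <- lengths(regmatches(ch, gregexpr("\\+", ch)))
      minus <- lengths(regmatches(ch, gregexpr("-", ch)))
      plus - minus
    }, numeric(1)))
  }, numeric(1))
  data.frame(molecule_id = ids, mw = p$MW, clogp = p$logP,
             hbd = p$HBD, hba = p$HBA2, charge = unname(charge),
             rotb = as.integer(rot), stringsAsFactors = FALSE)
}

#' Tanimoto similarity between two bit fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}; defined as 0 when both fingerprints
#' are empty. Inputs must be equal-length 0/1 (or logical) vectors.
#'
#' @param fp_a,fp_b fingerprint vectors.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprint length mismatch: ", length(fp_a), " vs ",
         length(fp_b))
  }
  a <- as.logical(fp_a)
  b <- as.logical(fp_b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}
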