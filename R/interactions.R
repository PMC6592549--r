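#' Ionic-contact criterion
#'
#' The headline scoring rule for aminergic GPCRs: a docked pose is counted
#' as forming the charged interaction when the distance between the anchor
#' carboxyl carbon (CG of ASP, CD of GLU) and a positively charged ligand
#' atom is at most `max_distance`.  The boundary is inclusive: 6.00 Angstrom
#' counts, 6.01 does not.
#'
#' @param max_distance cutoff in Angstrom (default 6.0).
#' @param inclusive treat the boundary as `<=` (default) rather than `<`.
#' @return list of class `ionic_criterion`.
#' @export
ionic_criterion <- function(max_distance = 6.0, inclusive = TRUE) {
  if (!is.numeric(max_distance) || max_distance <= 0)
    stop("max_distance must be positive")
  structure(list(max_distance = max_distance, inclusive = inclusive),
            class = "ionic_criterion")
}

# carboxyl carbon of an acidic residue
carboxyl_carbon_name <- function(resname) {
  switch(resname, ASP = "CG", GLU = "CD",
         stop("anchor residue must be ASP or GLU, got ", resname))
}

#' Positively charged atoms of a pose
#'
#' Returns the indices of all atoms with formal charge >= +1, regardless of
#' element: screened head groups (guanidino, tetramethylpiperidino,
#' quaternary and protonated amines) place the formal charge on different
#' atoms depending on the file dialect, so the rule is charge-based, not
#' element-based.  If no formal charge is present and `heuristic = TRUE`,
#' protonatable amine nitrogens are inferred from the bond table (N bonded
#' only to C, and not an amide N) and flagged via the "inferred" attribute.
#'
#' @param pose a [ligand_pose()].
#' @param heuristic fall back to the protonatable-amine rule when the pose
#'   carries no formal charges (requires a bond table).
#' @return integer vector of atom indices (possibly empty), with attribute
#'   `inferred` = TRUE when the heuristic produced it.
#' @export
cationic_atoms <- function(pose, heuristic = FALSE) {
  idx <- which(pose$atoms$formal_charge >= 1L)
  if (length(idx) || !heuristic) return(idx)
  b <- pose$bonds
  if (is.null(b)) return(idx)
  el <- pose$atoms$element
  cand <- which(el == "N")
  inferred <- integer(0)
  for (i in cand) {
    nb <- c(b$to[b$from == i], b$from[b$to == i])
    heavy_nb <- nb[el[nb] != "H"]
    if (length(heavy_nb) == 0L || any(el[heavy_nb] != "C")) next
    # amide check: a neighbouring carbon double-bonded to O disqualifies
    amide <- FALSE
    for (cc in heavy_nb) {
      cb <- b[(b$from == cc | b$to == cc) & b$order == 2, , drop = FALSE]
      partners <- setdiff(c(cb$from, cb$to), cc)
      if (any(el[partners] == "O")) amide <- TRUE
    }
    if (!amide) inferred <- c(inferred, i)
  }
  structure(inferred, inferred = TRUE)
}

#' Detect the charged interaction between a pose and the anchor carboxylate
#'
#' Measures the minimum Euclidean distance from the single carboxyl carbon
#' of the anchor residue (CG for ASP, CD for GLU - the carbon, not the
#' oxygens) to any cationic ligand atom and applies the criterion.
#' Poses without a cationic atom score `FALSE` with `min_distance = Inf`.
#'
#' @param pose a [ligand_pose()].
#' @param anchor_residue data.frame of the anchor residue's atoms, e.g. from
#'   [resolve_bw()]; must be ASP or GLU with its carboxyl carbon present.
#' @param criterion an [ionic_criterion()].
#' @param heuristic passed to [cationic_atoms()].
#' @return one-row data.frame: `pose_id`, `ligand_id`, `ionic_to_anchor`,
#'   `min_distance`, `contributing_atom` (index or NA).
#' @export
ionic_contact <- function(pose, anchor_residue,
                          criterion = ionic_criterion(),
                          heuristic = FALSE) {
  resname <- unique(anchor_residue$resname)
  cname <- carboxyl_carbon_name(resname)
  crow <- anchor_residue[anchor_residue$name == cname, , drop = FALSE]
  if (nrow(crow) != 1L)
    stop("anchor residue ", resname, " lacks its carboxyl carbon ", cname)
  cxyz <- c(crow$x, crow$y, crow$z)
  cat_idx <- cationic_atoms(pose, heuristic = heuristic)
  if (!length(cat_idx)) {
    return(data.frame(pose_id = pose$pose_id, ligand_id = pose$ligand_id,
                      ionic_to_anchor = FALSE, min_distance = Inf,
                      contributing_atom = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  a <- pose$atoms[cat_idx, , drop = FALSE]
  d <- sqrt((a$x - cxyz[1])^2 + (a$y - cxyz[2])^2 + (a$z - cxyz[3])^2)
  k <- which.min(d)
  hit <- if (criterion$inclusive) d[k] <= criterion$max_distance
         else d[k] < criterion$max_distance
  data.frame(pose_id = pose$pose_id, ligand_id = pose$ligand_id,
             ionic_to_anchor = hit, min_distance = d[k],
             contributing_atom = cat_idx[k], stringsAsFactors = FALSE)
}

#' Ionic-contact records for every pose of a set
#'
#' @param pset a [pose_set()].
#' @param anchor_residue,criterion,heuristic as in [ionic_contact()].
#' @return data.frame with one row per pose plus `model_id`, `run_id`.
#' @export
ionic_contacts <- function(pset, anchor_residue,
                           criterion = ionic_criterion(),
                           heuristic = FALSE) {
  recs <- lapply(pset$poses, ionic_contact, anchor_residue = anchor_residue,
                 criterion = criterion, heuristic = heuristic)
  out <- do.call(rbind, recs)
  out$model_id <- pset$model_id
  out$run_id <- pset$run_id
  out
}

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Extended geometric interaction fingerprint of a pose
#'
#' Reports, per binding-site residue, simple geometric interaction events:
#' hydrogen bond (ligand N/O to residue side-chain N/O heavy-atom distance
#' <= `hbond_max`), pi-cation (cationic ligand atom to aromatic ring
#' centroid <= `pi_cation_max`; aromatic residues only), and hydrophobic
#' contact (ligand carbon to side-chain carbon <= `hydrophobic_max`).
#' The thresholds are package conventions, configurable and excluded from
#' the headline charged-interaction score.
#'
#' @param pose a [ligand_pose()].
#' @param model a `receptor_model`.
#' @param site a [binding_site_spec()].
#' @param bwmap a `bw_map` resolving the site labels.
#' @param hbond_max,pi_cation_max,hydrophobic_max cutoffs in Angstrom.
#' @return data.frame with columns `type`, `bw_label`, `distance`
#'   (0 rows when nothing is in range).
#' @export
extended_fingerprint <- function(pose, model, site, bwmap,
                                 hbond_max = 3.5, pi_cation_max = 6.0,
                                 hydrophobic_max = 4.5) {
  la <- pose$atoms
  lig_polar <- la[la$element %in% c("N", "O"), , drop = FALSE]
  lig_carbon <- la[la$element == "C", , drop = FALSE]
  cat_idx <- cationic_atoms(pose)
  lig_cat <- la[cat_idx, , drop = FALSE]
  rows <- list()
  mindist <- function(A, B) {
    if (!nrow(A) || !nrow(B)) return(Inf)
    dx <- outer(A$x, B$x, `-`); dy <- outer(A$y, B$y, `-`)
    dz <- outer(A$z, B$z, `-`)
    min(sqrt(dx^2 + dy^2 + dz^2))
  }
  for (lab in site$site_residues) {
    res <- resolve_bw(model, bwmap, lab)
    side <- res[!(res$name %in% BACKBONE_NAMES) & res$element != "H", ,
                drop = FALSE]
    rpolar <- side[side$element %in% c("N", "O"), , drop = FALSE]
    d <- mindist(lig_polar, rpolar)
    if (d <= hbond_max)
      rows[[length(rows) + 1L]] <- data.frame(type = "hbond",
                                              bw_label = lab, distance = d)
    ring <- AROMATIC_RING_ATOMS[[unique(res$resname)]]
    if (!is.null(ring) && nrow(lig_cat)) {
      ra <- res[res$name %in% ring, , drop = FALSE]
      if (nrow(ra) >= 3) {
        cen <- colMeans(cbind(ra$x, ra$y, ra$z))
        d <- min(sqrt((lig_cat$x - cen[1])^2 + (lig_cat$y - cen[2])^2 +
                        (lig_cat$z - cen[3])^2))
        if (d <= pi_cation_max)
          rows[[length(rows) + 1L]] <- data.frame(type = "pi_cation",
                                                  bw_label = lab,
                                                  distance = d)
      }
    }
    rcarbon <- side[side$element == "C", , drop = FALSE]
    d <- mindist(lig_carbon, rcarbon)
    if (d <= hydrophobic_max)
      rows[[length(rows) + 1L]] <- data.frame(type = "hydrophobic",
                                              bw_label = lab, distance = d)
  }
  if (!length(rows))
    return(data.frame(type = character(0), bw_label = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
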