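# Backbone heavy-atom names (OXT covers C-terminal carboxylate).
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Construct a receptor model
#'
#' A receptor model is one member of a homology-model ensemble: an ordered
#' atom table plus a topology key used to guarantee that atomwise comparisons
#' across an ensemble pair up identical atoms.
#'
#' @param model_id character scalar identifying the model.
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z` (coordinates in Angstrom,
#'   author numbering, 1-based).
#' @return An object of class `receptor_model`: a list with `model_id`,
#'   `atoms` (with an `is_heavy` column added) and `topology_key`.
#' @export
receptor_model <- function(model_id, atoms) {
  required <- c("serial", "name", "element", "resname", "resno", "chain",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in model ", model_id)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  rownames(atoms) <- NULL
  structure(
    list(model_id = as.character(model_id),
         atoms = atoms,
         topology_key = topology_key_of(atoms)),
    class = "receptor_model")
}

topology_key_of <- function(atoms) {
  paste(atoms$resno, atoms$resname, atoms$name, sep = ":", collapse = "|")
}

#' @export
print.receptor_model <- function(x, ...) {
  nres <- length(unique(paste(x$atoms$chain, x$atoms$resno)))
  cat("Receptor model '", x$model_id, "': ", nrow(x$atoms), " atoms (",
      sum(x$atoms$is_heavy), " heavy), ", nres, " residues\n", sep = "")
  invisible(x)
}

#' Coordinates of a receptor model as a matrix
#' @param model a `receptor_model`.
#' @param idx optional integer index of atoms to extract.
#' @return numeric matrix with 3 columns (x, y, z).
#' @export
coords <- function(model, idx = NULL) {
  a <- model$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

`coords<-` <- function(model, value) {
  model$atoms$x <- value[, 1]
  model$atoms$y <- value[, 2]
  model$atoms$z <- value[, 3]
  model
}

infer_element <- function(name) {
  # Strip digits and primes, then take the leading letter; handles names
  # like "1HB2", "CA", "OD1".  Two-letter elements do not occur in standard
  # amino-acid ATOM records, so a single letter is sufficient here.
  core <- sub("^[0-9']+", "", name)
  toupper(substr(core, 1L, 1L))
}

#' Read receptor model(s) from a PDB file
#'
#' Wraps [bio3d::read.pdb()].  Elements come from PDB columns 77-78 and are
#' inferred from the atom name when absent.  Alternate locations are reduced
#' to one atom per (chain, residue, name): highest occupancy wins, ties go to
#' the lexically smallest altloc code (so 'A' beats 'B').  Hydrogens are kept
#' but flagged; all geometric analyses in this package use heavy atoms only.
#'
#' @param path PDB file.
#' @param model_id id for the (first) model; defaults to the file base name.
#'   Multi-MODEL files get `_m<k>` suffixes.
#' @param multi if `TRUE` and the file holds several MODEL blocks, return a
#'   list of `receptor_model`s (they share one topology key by construction).
#' @return A `receptor_model`, or a list of them for multi-MODEL input with
#'   `multi = TRUE`.
#' @export
read_pdb <- function(path, model_id = NULL, multi = TRUE) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: ", path)
  keep <- a$type %in% c("ATOM", "HETATM")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("empty structure: ", path)

  # altloc policy: highest occupancy, ties -> smallest altloc code
  alt <- ifelse(is.na(a$alt), "", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  sel_rows <- sort(ord[!duplicated(key[ord])])  # dedup, keep file order
  a <- a[sel_rows, , drop = FALSE]

  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- infer_element(a$elety[bad])
  atoms <- data.frame(serial = a$eleno, name = a$elety,
                      element = toupper(trimws(elem)),
                      resname = a$resid, resno = a$resno,
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  base_id <- if (is.null(model_id))
    sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE) else model_id

  n_model <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (n_model > 1L && multi) {
    # rebuild per-MODEL coordinate sets from the bio3d xyz matrix, using the
    # same atom filtering as above
    xyz_idx <- which(keep)[sel_rows]
    out <- vector("list", n_model)
    for (k in seq_len(n_model)) {
      ak <- atoms
      m <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
      ak$x <- m[xyz_idx, 1]; ak$y <- m[xyz_idx, 2]; ak$z <- m[xyz_idx, 3]
      out[[k]] <- receptor_model(sprintf("%s_m%d", base_id, k), ak)
    }
    return(out)
  }
  receptor_model(base_id, atoms)
}

#' Write a receptor model to a PDB file
#'
#' Wraps [bio3d::write.pdb()]; coordinates are written with 3 decimals so a
#' read/write round trip preserves them to 0.001 Angstrom.
#'
#' @param model a `receptor_model`.
#' @param path output file.
#' @param bfactor optional numeric vector (one per atom) written into the
#'   B-factor column, e.g. per-atom displacement for visualization.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path, bfactor = NULL) {
  a <- model$atoms
  b <- if (is.null(bfactor)) rep(0, nrow(a)) else {
    stopifnot(length(bfactor) == nrow(a))
    bfactor
  }
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords(model))),
    resno = a$resno, resid = a$resname, eleno = a$serial, elety = a$name,
    chain = a$chain, o = rep(1, nrow(a)), b = b, elesy = a$element))
  invisible(path)
}

#' Read a Ballesteros-Weinstein residue map
#'
#' The map is user-supplied configuration (never computed from alignment):
#' a TSV with columns `bw_label`, `chain`, `resnum`, `resname` linking
#' generic class-A GPCR labels such as "3.32" to author residue numbers.
#'
#' @param path TSV file.
#' @return data.frame of class `bw_map`.
#' @export
read_bwmap <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  bw_map(m)
}

#' @rdname read_bwmap
#' @param entries data.frame with columns `bw_label`, `chain`, `resnum`,
#'   `resname`.
#' @export
bw_map <- function(entries) {
  need <- c("bw_label", "chain", "resnum", "resname")
  missing <- setdiff(need, names(entries))
  if (length(missing))
    stop("BW map lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(entries$bw_label))
    stop("duplicate bw_label in BW map")
  entries$resnum <- as.integer(entries$resnum)
  class(entries) <- c("bw_map", "data.frame")
  entries
}

#' Resolve a Ballesteros-Weinstein label to the atoms of its residue
#'
#' @param model a `receptor_model`.
#' @param bwmap a `bw_map`.
#' @param bw_label label such as "3.32".
#' @return data.frame of the residue's atoms (rows of `model$atoms`).
#' @export
resolve_bw <- function(model, bwmap, bw_label) {
  i <- match(bw_label, bwmap$bw_label)
  if (is.na(i)) stop("bw_label '", bw_label, "' not in map")
  e <- bwmap[i, ]
  sel <- model$atoms$resno == e$resnum & model$atoms$chain == e$chain
  res <- model$atoms[sel, , drop = FALSE]
  if (nrow(res) == 0L)
    stop("residue ", e$chain, e$resnum, " (", bw_label,
         ") absent from model ", model$model_id)
  found <- unique(res$resname)
  if (!identical(found, e$resname))
    stop("BW map expects ", e$resname, " at ", e$chain, e$resnum, " (",
         bw_label, ") but model has ", paste(found, collapse = "/"))
  res
}

#' Select heavy-atom subsets of a model
#'
#' Backbone = heavy atoms named N, CA, C, O (plus OXT); side chain = the
#' remaining heavy atoms; the two partition the heavy-atom set.
#'
#' @param model a `receptor_model`.
#' @param subset one of "all_heavy", "backbone", "sidechain".
#' @return integer vector of row indices into `model$atoms`.
#' @export
atom_subset <- function(model, subset = c("all_heavy", "backbone", "sidechain")) {
  subset <- match.arg(subset)
  a <- model$atoms
  heavy <- which(a$is_heavy)
  switch(subset,
         all_heavy = heavy,
         backbone = heavy[a$name[heavy] %in% BACKBONE_NAMES],
         sidechain = heavy[!(a$name[heavy] %in% BACKBONE_NAMES)])
}

#' Binding-site specification in Ballesteros-Weinstein labels
#'
#' Defaults mirror the aminergic-GPCR orthosteric pocket: a carboxylate
#' anchor at 3.32 plus the residues commonly used to define the docking site.
#' Position 7.39 is deliberately taken from the supplied site list / map
#' rather than hard-coded to one amino acid, since its identity differs
#' between receptor and numbering conventions.
#'
#' @param anchor BW label of the anchor carboxylate (ASP or GLU).
#' @param auxiliary_acidic optional second acidic position (default "5.46").
#' @param site_residues labels defining the binding site.
#' @return list of class `binding_site_spec`.
#' @export
binding_site_spec <- function(anchor = "3.32", auxiliary_acidic = "5.46",
                              site_residues = c("3.32", "3.33", "4.56",
                                                "5.46", "6.48", "6.51",
                                                "7.39")) {
  if (!(anchor %in% site_residues))
    stop("anchor ", anchor, " must be one of the site residues")
  structure(list(anchor = anchor, auxiliary_acidic = auxiliary_acidic,
                 site_residues = site_residues),
            class = "binding_site_spec")
}

#' Read a binding-site specification from a YAML file
#' @param path YAML file with keys `anchor`, `auxiliary_acidic`,
#'   `site_residues`.
#' @return `binding_site_spec`.
#' @export
read_site_spec <- function(path) {
  y <- yaml::read_yaml(path)
  binding_site_spec(
    anchor = y$anchor %||% "3.32",
    auxiliary_acidic = y$auxiliary_acidic %||% "5.46",
    site_residues = unlist(y$site_residues) %||%
      c("3.32", "3.33", "4.56", "5.46", "6.48", "6.51", "7.39"))
}

#' Write a binding-site specification to YAML
#' @param spec a `binding_site_spec`.
#' @param path output file.
#' @export
write_site_spec <- function(spec, path) {
  yaml::write_yaml(list(anchor = spec$anchor,
                        auxiliary_acidic = spec$auxiliary_acidic,
                        site_residues = as.list(spec$site_residues)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
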