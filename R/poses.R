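#' Construct a ligand pose
#'
#' One docked conformation of a ligand: atoms with coordinates, element and
#' integer formal charge, plus an optional bond table (needed only by the
#' protonatable-amine heuristic of [cationic_atoms()]).
#'
#' @param pose_id,ligand_id identifiers.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `formal_charge`.
#' @param bonds optional data.frame with columns `from`, `to`, `order`
#'   (1-based atom indices).
#' @return object of class `ligand_pose`.
#' @export
ligand_pose <- function(pose_id, ligand_id, atoms, bonds = NULL) {
  need <- c("element", "x", "y", "z", "formal_charge")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    stop("pose atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("pose '", pose_id, "' has no atoms")
  fc <- atoms$formal_charge
  if (any(fc != round(fc))) stop("formal charges must be integers")
  atoms$formal_charge <- as.integer(fc)
  rownames(atoms) <- NULL
  structure(list(pose_id = as.character(pose_id),
                 ligand_id = as.character(ligand_id),
                 atoms = atoms, bonds = bonds),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("Ligand pose '", x$pose_id, "' (ligand ", x$ligand_id, "): ",
      nrow(x$atoms), " atoms, net formal charge ",
      sum(x$atoms$formal_charge), "\n", sep = "")
  invisible(x)
}

#' Construct a pose set
#'
#' All docked poses belonging to one (receptor model, docking run) pair.
#'
#' @param model_id,run_id identifiers of the receptor model and replicate run.
#' @param poses list of [ligand_pose()] objects with unique pose ids.
#' @return object of class `pose_set`.
#' @export
pose_set <- function(model_id, run_id, poses) {
  if (!length(poses)) stop("pose set must contain at least one pose")
  ids <- vapply(poses, function(p) p$pose_id, "")
  if (anyDuplicated(ids)) stop("duplicate pose_id in pose set")
  structure(list(model_id = as.character(model_id),
                 run_id = as.character(run_id), poses = poses),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("Pose set: model '", x$model_id, "', run '", x$run_id, "', ",
      length(x$poses), " poses\n", sep = "")
  invisible(x)
}

# fast data.frame constructor for trusted equal-length columns
new_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}

# V2000 legacy atom-block charge codes (field 5 of the atom line).
LEGACY_SDF_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                       `7` = -3L)

# Formal charges of one SDF record: "M  CHG" property lines override the
# legacy atom-block codes entirely (per the CTfile specification).
sdf_record_charges <- function(rec_lines, n_atoms) {
  fc <- integer(n_atoms)
  chg <- grep("^M  CHG", rec_lines, value = TRUE)
  if (length(chg)) {
    for (ln in chg) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      np <- f[1]
      for (j in seq_len(np)) fc[f[2 * j]] <- f[2 * j + 1]
    }
  } else {
    atom_lines <- rec_lines[5:(4 + n_atoms)]
    codes <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
    hit <- !is.na(codes) & codes > 0
    fc[hit] <- LEGACY_SDF_CHARGE[as.character(codes[hit])]
    fc[is.na(fc)] <- 0L
  }
  fc
}

read_poses_sdf <- function(path, model_id, run_id) {
  sdfs <- tryCatch(ChemmineR::read.SDFset(path),
                   error = function(e) stop("cannot parse SDF '", path, "': ",
                                            conditionMessage(e)))
  n <- length(ChemmineR::sdfid(sdfs))
  if (n == 0L) stop("no records in SDF file: ", path)
  raw <- readLines(path, warn = FALSE)
  ends <- grep("^\\${4}", raw)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) < n) ends <- c(ends, length(raw))
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    sdf <- sdfs@SDF[[i]]
    ab <- sdf@atomblock
    if (nrow(ab) == 0L) stop("record ", i, " in '", path, "' has no atoms")
    elem <- sub("_.*$", "", rownames(ab))
    xyz <- ab[, 1:3, drop = FALSE]
    if (all(xyz[, 3] == 0) && nrow(ab) > 1L &&
        grepl("2D", sdf@header[["Comment"]] %||% "", fixed = TRUE))
      stop("record ", i, " in '", path, "' has no 3D coordinates")
    rec <- raw[starts[i]:ends[min(i, length(ends))]]
    fc <- sdf_record_charges(rec, nrow(ab))
    db <- sdf@datablock
    title <- trimws(sdf@header[["Molecule_Name"]] %||% "")
    pose_id <- if ("pose_id" %in% names(db)) db[["pose_id"]]
               else if (nzchar(title)) title else sprintf("pose_%03d", i)
    ligand_id <- if ("ligand_id" %in% names(db)) db[["ligand_id"]]
                 else if (nzchar(title)) title else sprintf("ligand_%03d", i)
    bb <- sdf@bondblock
    bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3 &&
                 all(bb[, 1] >= 1))
      new_df(from = unname(bb[, 1]), to = unname(bb[, 2]),
             order = unname(bb[, 3])) else NULL
    # internal fast path; same shape ligand_pose() validates
    poses[[i]] <- structure(
      list(pose_id = as.character(pose_id),
           ligand_id = as.character(ligand_id),
           atoms = new_df(element = elem, x = unname(xyz[, 1]),
                          y = unname(xyz[, 2]), z = unname(xyz[, 3]),
                          formal_charge = fc),
           bonds = bonds),
      class = "ligand_pose")
  }
  ids <- vapply(poses, function(p) p$pose_id, "")
  if (anyDuplicated(ids))
    for (i in seq_along(poses))
      poses[[i]]$pose_id <- sprintf("%s_%03d", poses[[i]]$pose_id, i)
  pose_set(model_id, run_id, poses)
}

# SYBYL atom types that carry a formal positive charge by definition; MOL2
# stores only partial charges, so formal charge must come from the type.
MOL2_CATION_TYPES <- c("N.4", "C.cat")

read_poses_mol2 <- function(path, model_id, run_id) {
  mols <- tryCatch(bio3d::read.mol2(path),
                   error = function(e) stop("cannot parse MOL2 '", path,
                                            "': ", conditionMessage(e)))
  if (inherits(mols, "mol2")) mols <- list(mols)
  if (!length(mols)) stop("no records in MOL2 file: ", path)
  poses <- lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    a <- m$atom
    if (is.null(a) || nrow(a) == 0L)
      stop("record ", i, " in '", path, "' has no atoms")
    elem <- toupper(sub("\\..*$", "", a$elety))
    fc <- ifelse(a$elety %in% MOL2_CATION_TYPES, 1L, 0L)
    ligand_pose(sprintf("%s_%03d", m$name %||% "pose", i),
                m$name %||% sprintf("ligand_%03d", i),
                data.frame(element = elem, x = a$x, y = a$y, z = a$z,
                           formal_charge = fc, stringsAsFactors = FALSE))
  })
  pose_set(model_id, run_id, poses)
}

#' Read docked ligand poses from an SDF or MOL2 file
#'
#' SDF formal charges are taken from `M  CHG` property lines when present,
#' otherwise from the legacy atom-block charge codes, and preserved exactly.
#' MOL2 files carry only partial charges, so formal charges are derived from
#' SYBYL atom types (`N.4`, `C.cat` are +1).
#'
#' @param path file ending in `.sdf`/`.mol` or `.mol2`.
#' @param model_id,run_id identifiers attached to the resulting set.
#' @return a [pose_set()].
#' @export
read_poses <- function(path, model_id, run_id = "run1") {
  if (!file.exists(path)) stop("no such pose file: ", path)
  if (file.size(path) == 0L) stop("empty pose file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         sdf = , mol = read_poses_sdf(path, model_id, run_id),
         mol2 = read_poses_mol2(path, model_id, run_id),
         stop("unknown pose file extension '.", ext,
              "' (expected .sdf or .mol2): ", path))
}

#' Write a pose set as a multi-record V2000 SDF file
#'
#' Formal charges are written both as `M  CHG` lines and in the legacy
#' atom-block field; `ligand_id` / `pose_id` are stored as SDF data fields so
#' that a write/read round trip preserves identity and charges exactly.
#'
#' @param pset a [pose_set()].
#' @param path output file.
#' @export
write_poses_sdf <- function(pset, path) {
  fmt_atom <- function(a, legacy) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element, legacy)
  }
  inv_legacy <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L,
                  `-3` = 7L)
  out <- vector("list", length(pset$poses))
  for (i in seq_along(pset$poses)) {
    p <- pset$poses[[i]]
    a <- p$atoms
    legacy <- inv_legacy[as.character(a$formal_charge)]
    legacy[is.na(legacy)] <- 0L
    nb <- if (is.null(p$bonds)) 0L else nrow(p$bonds)
    lines <- c(p$pose_id, "  modelrank", "3D",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nb),
               fmt_atom(a, legacy))
    if (nb > 0)
      lines <- c(lines, sprintf("%3d%3d%3d  0", p$bonds$from, p$bonds$to,
                                p$bonds$order))
    chg <- which(a$formal_charge != 0L)
    if (length(chg)) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        lines <- c(lines, paste0(
          sprintf("M  CHG%3d", length(grp)),
          paste(sprintf("%4d%4d", grp, a$formal_charge[grp]),
                collapse = "")))
      }
    }
    lines <- c(lines, "M  END",
               ">  <ligand_id>", p$ligand_id, "",
               ">  <pose_id>", p$pose_id, "",
               "$$$$")
    out[[i]] <- lines
  }
  writeLines(unlist(out), path)
  invisible(path)
}
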