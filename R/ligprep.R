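#' Default curation thresholds for ChEMBL-style bioactivity tables
#'
#' Molecular weight at most 500 Da, confidence score exactly 9, binding or
#' functional activity types, exact relation "=", value at most 10 with unit
#' nM, and unambiguous stereochemistry.  Both value boundaries are
#' inclusive.
#'
#' @return named list of thresholds consumed by [curate()].
#' @export
curation_thresholds <- function() {
  list(mw = 500, confidence = 9L,
       types = c("Ki", "Kd", "IC50", "EC50"),
       relation = "=", value = 10, unit = "nM")
}

CURATION_STAGES <- c("mw", "confidence", "type", "relation", "value",
                     "unit", "stereo")

# common ChEMBL-export spellings of the canonical column names
DEFAULT_COLUMN_ALIASES <- c(
  molecule_chembl_id = "ligand_id", chembl_id = "ligand_id",
  canonical_smiles = "smiles",
  full_mwt = "mw", molecular_weight = "mw", mw_freebase = "mw",
  confidence_score = "confidence",
  standard_type = "std_type", standard_relation = "std_relation",
  standard_value = "std_value", standard_units = "std_unit",
  standard_unit = "std_unit", document_year = "year")

#' Normalize bioactivity column names to the canonical schema
#'
#' Renames ChEMBL-export style columns (e.g. `standard_type`,
#' `molecule_chembl_id`, `full_mwt`) to the canonical names [curate()]
#' expects; a user mapping (named vector: `c(input_name = "canonical")`)
#' takes precedence over the built-in aliases.
#'
#' @param records data.frame.
#' @param mapping optional named character vector of extra renames.
#' @return the data.frame with renamed columns.
#' @export
normalize_activity_columns <- function(records, mapping = NULL) {
  aliases <- DEFAULT_COLUMN_ALIASES
  if (!is.null(mapping)) aliases[names(mapping)] <- mapping
  hit <- names(records) %in% names(aliases) &
    !(unname(aliases[names(records)]) %in% names(records))
  names(records)[hit] <- unname(aliases[names(records)[hit]])
  records
}

stage_pass <- function(records, stage, th) {
  p <- switch(stage,
              mw = records$mw <= th$mw,
              confidence = records$confidence == th$confidence,
              type = records$std_type %in% th$types,
              relation = records$std_relation == th$relation,
              value = records$std_value <= th$value,
              unit = records$std_unit == th$unit,
              stereo = records$stereo_clear)
  # records with NA in a filtered column cannot be verified -> fail there
  p & !is.na(p)
}

#' Curate a bioactivity table
#'
#' Applies the filter stages in order (molecular weight, confidence score,
#' activity type, relation, activity value, unit, stereo clarity); every
#' dropped record is attributed to the first stage it fails, and the report
#' carries per-stage in/dropped/out counts.
#'
#' @param records data.frame with columns `ligand_id`, `mw`, `confidence`,
#'   `std_type`, `std_relation`, `std_value`, `std_unit`, `stereo_clear`
#'   (logical; see Details).
#' @param thresholds list as from [curation_thresholds()].
#' @param stages stage order (changing it changes per-stage drop counts but
#'   never the kept set).
#' @return list of class `curation_report`: `kept` (data.frame),
#'   `stage_counts` (data.frame `stage`, `n_in`, `n_dropped`, `n_out`),
#'   `dropped` (data.frame `ligand_id`, `stage`).
#' @details Stereo ambiguity is a precomputed boolean here: with raw SMILES,
#'   unassigned-stereocenter detection belongs to the cheminformatics layer
#'   and its verdict is cached into `stereo_clear`, which keeps the pipeline
#'   testable without chemistry.
#' @export
curate <- function(records, thresholds = curation_thresholds(),
                   stages = CURATION_STAGES) {
  need <- c("ligand_id", "mw", "confidence", "std_type", "std_relation",
            "std_value", "std_unit", "stereo_clear")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("activity table lacks column(s): ", paste(missing, collapse = ", "))
  if (!setequal(stages, CURATION_STAGES))
    stop("stages must be a permutation of: ",
         paste(CURATION_STAGES, collapse = ", "))
  kept <- records
  counts <- data.frame(stage = stages, n_in = NA_integer_,
                       n_dropped = NA_integer_, n_out = NA_integer_,
                       stringsAsFactors = FALSE)
  dropped <- list()
  for (i in seq_along(stages)) {
    st <- stages[i]
    pass <- stage_pass(kept, st, thresholds)
    counts$n_in[i] <- nrow(kept)
    counts$n_dropped[i] <- sum(!pass)
    counts$n_out[i] <- sum(pass)
    if (any(!pass))
      dropped[[st]] <- data.frame(ligand_id = kept$ligand_id[!pass],
                                  stage = st, stringsAsFactors = FALSE)
    kept <- kept[pass, , drop = FALSE]
  }
  rownames(kept) <- NULL
  structure(list(kept = kept, stage_counts = counts,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(ligand_id = character(0),
                                           stage = character(0))),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation:", x$stage_counts$n_in[1], "records in,",
      nrow(x$kept), "kept\n")
  print.data.frame(x$stage_counts)
  invisible(x)
}

BINDING_TYPES <- c("Ki", "Kd")

#' Deduplicate bioactivity records per ligand
#'
#' When a ligand has several measurements: binding data (Ki, Kd) beats
#' functional data (IC50, EC50); within the same class the most recent year
#' wins; remaining ties go to the lowest activity value, then stable input
#' order.
#'
#' @param records curated data.frame with `ligand_id`, `std_type`, `year`,
#'   `std_value`.
#' @return data.frame with one row per ligand_id, in first-appearance order.
#' @export
deduplicate <- function(records) {
  if (!nrow(records)) return(records)
  is_binding <- records$std_type %in% BINDING_TYPES
  ord <- order(!is_binding, -records$year, records$std_value,
               seq_len(nrow(records)))
  best <- ord[!duplicated(records$ligand_id[ord])]
  out <- records[sort(best), , drop = FALSE]   # stable input order
  rownames(out) <- NULL
  out
}

#' Tanimoto similarity of two fingerprint sets
#'
#' `|A intersect B| / |A union B|` on bit/feature sets from one fingerprint
#' scheme.  Two empty fingerprints are defined as similarity 1 (and noted
#' via a message), since indistinguishable objects should not count as
#' maximally diverse.
#'
#' @param fp_a,fp_b fingerprints as vectors of set members (any atomic
#'   type), or logical vectors of equal length (bit vectors).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (is.logical(fp_a) && is.logical(fp_b)) {
    stopifnot(length(fp_a) == length(fp_b))
    fp_a <- which(fp_a); fp_b <- which(fp_b)
  }
  u <- length(union(fp_a, fp_b))
  if (u == 0L) {
    message("tanimoto: both fingerprints empty; defining similarity as 1")
    return(1)
  }
  length(intersect(fp_a, fp_b)) / u
}

#' MaxMin diversity picking
#'
#' Greedy diversity selection on fingerprint distance (1 - Tanimoto): the
#' seed determines the first pick; each subsequent pick maximizes the
#' minimum distance to the already-picked set (ties broken by lowest index,
#' so the result is deterministic for a fixed seed).
#'
#' @param fingerprints list of fingerprint sets (see [tanimoto()]).
#' @param n number of items to pick (`n <= length(fingerprints)`).
#' @param seed integer seed for the first pick.
#' @return integer vector of picked indices, in pick order.
#' @export
maxmin_pick <- function(fingerprints, n, seed = 42L) {
  m <- length(fingerprints)
  if (n > m) stop("cannot pick ", n, " items from ", m)
  if (n <= 0L) return(integer(0))
  first <- local_seed(seed, sample.int(m, 1L))
  picked <- first
  # min distance of every candidate to the picked set, updated incrementally
  mind <- vapply(fingerprints, function(f)
    1 - tanimoto(f, fingerprints[[first]]), 0)
  while (length(picked) < n) {
    mind[picked] <- -Inf
    nxt <- which.max(mind)        # which.max takes the first (lowest index)
    picked <- c(picked, nxt)
    dn <- vapply(fingerprints, function(f)
      1 - tanimoto(f, fingerprints[[nxt]]), 0)
    mind <- pmin(mind, dn)
  }
  picked
}

#' Cheng-Prusoff conversion of competition IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` for a competition binding assay with
#' radioligand concentration `L` and radioligand dissociation constant `Kd`
#' (any consistent concentration unit).
#'
#' @param ic50 measured IC50 (> 0).
#' @param radioligand_conc radioligand concentration `L` (>= 0).
#' @param radioligand_kd radioligand `Kd` (> 0).
#' @return Ki in the unit of `ic50`.
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, radioligand_kd) {
  if (any(ic50 <= 0) || any(radioligand_conc < 0) ||
      any(radioligand_kd <= 0))
    stop("ic50 and Kd must be positive, radioligand concentration non-negative")
  ic50 / (1 + radioligand_conc / radioligand_kd)
}

#' Convert a molar Ki to pKi
#' @param ki_molar Ki in mol/L (> 0).
#' @return pKi = -log10(Ki).
#' @export
to_pki <- function(ki_molar) {
  if (any(ki_molar <= 0)) stop("Ki must be positive")
  -log10(ki_molar)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
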