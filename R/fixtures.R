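SIDECHAIN_ATOMS <- list(
  GLY = character(0), ALA = "CB",
  VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  PRO = c("CB", "CG", "CD"),
  ASP = c("CB", "CG", "OD1", "OD2"), GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
          "CH2"))

# seven short helix segments; site residues sit at their canonical
# Ballesteros-Weinstein positions (3.32 D, 3.33 Y, 4.56 Y, 5.46 E, 6.48 W,
# 6.51 Y, 7.39 F) with H3R-like author numbering (D114, E206, ...)
TEMPLATE_HELICES <- list(
  list(seq = c("LEU", "ALA", "PHE", "VAL"), resno0 = 40L, bw0 = "1.39"),
  list(seq = c("ALA", "LEU", "TYR", "ALA"), resno0 = 80L, bw0 = "2.50"),
  list(seq = c("VAL", "ASP", "TYR", "LEU"), resno0 = 113L, bw0 = "3.31"),
  list(seq = c("ALA", "TYR", "LEU", "VAL"), resno0 = 165L, bw0 = "4.55"),
  list(seq = c("LEU", "GLU", "ALA", "TYR"), resno0 = 205L, bw0 = "5.45"),
  list(seq = c("TRP", "ALA", "LEU", "TYR"), resno0 = 371L, bw0 = "6.48"),
  list(seq = c("PHE", "VAL", "ALA", "LEU"), resno0 = 398L, bw0 = "7.39"))

#' Synthetic seven-helix receptor template
#'
#' A small hand-built helix-bundle scaffold emulating the orthosteric pocket
#' of an aminergic GPCR: seven four-residue helix segments arranged on a
#' circle, with the binding-site residues (anchor aspartate at 3.32, a
#' glutamate at 5.46, aromatics at 3.33/4.56/6.48/6.51/7.39 and a leucine at
#' 7.42) pointing into the pocket.  Geometry is schematic - atom names,
#' subsets and distances behave like a protein's, chemistry is not
#' force-field realistic.
#'
#' @return list with `model` (a `receptor_model`), `bwmap` (a `bw_map`) and
#'   `site` (a [binding_site_spec()]).
#' @export
fixture_template <- function() {
  rows <- list(); bw_entries <- list()
  serial <- 0L
  add_atom <- function(name, elem, resname, resno, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = elem, resname = resname,
      resno = resno, chain = "A", x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  Rcirc <- 11; rhel <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  for (h in seq_along(TEMPLATE_HELICES)) {
    hel <- TEMPLATE_HELICES[[h]]
    th <- 2 * pi * (h - 1) / 7
    axis <- c(Rcirc * cos(th), Rcirc * sin(th))
    nres <- length(hel$seq)
    ca <- t(vapply(seq_len(nres) - 1L, function(i) {
      phi <- th + pi / 3 + i * turn
      c(axis[1] + rhel * cos(phi), axis[2] + rhel * sin(phi), 1.5 + rise * i)
    }, numeric(3)))
    bw_major <- as.integer(sub("\\..*", "", hel$bw0))
    bw_minor <- as.integer(sub(".*\\.", "", hel$bw0))
    for (i in seq_len(nres)) {
      resname <- hel$seq[i]
      resno <- hel$resno0 + i - 1L
      bw_entries[[length(bw_entries) + 1L]] <- data.frame(
        bw_label = sprintf("%d.%d", bw_major, bw_minor + i - 1L),
        chain = "A", resnum = resno, resname = resname,
        stringsAsFactors = FALSE)
      prev_dir <- if (i > 1) ca[i - 1, ] - ca[i, ] else c(0, 0, -1)
      next_dir <- if (i < nres) ca[i + 1, ] - ca[i, ] else -prev_dir
      prev_dir <- prev_dir / sqrt(sum(prev_dir^2))
      next_dir <- next_dir / sqrt(sum(next_dir^2))
      add_atom("N", "N", resname, resno, ca[i, ] + 1.45 * prev_dir)
      add_atom("CA", "C", resname, resno, ca[i, ])
      cpos <- ca[i, ] + 1.52 * next_dir
      add_atom("C", "C", resname, resno, cpos)
      oup <- c(next_dir[2], -next_dir[1], 0.4)
      add_atom("O", "O", resname, resno, cpos + 1.23 * oup / sqrt(sum(oup^2)))
      # side chain marches from CA toward the pocket axis (z-axis) in a
      # zigzag so no three atoms are collinear
      inward <- c(-ca[i, 1], -ca[i, 2], 0)
      inward <- inward / sqrt(sum(inward^2))
      perp <- c(-inward[2], inward[1], 0)
      sc <- SIDECHAIN_ATOMS[[resname]]
      for (j in seq_along(sc)) {
        pos <- ca[i, ] + (0.8 + 1.25 * j) * inward +
          0.55 * (-1)^j * perp + c(0, 0, 0.22 * j)
        add_atom(sc[j], substr(sc[j], 1, 1), resname, resno, pos)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  list(model = receptor_model("template", atoms),
       bwmap = bw_map(do.call(rbind, bw_entries)),
       site = binding_site_spec())
}

#' Fixture-generation configuration
#'
#' Defaults emulate the study conditions of a 1000-model homology ensemble
#' docked twice with 9 ligands x 10 poses: per-atom noise of 0.4 Angstrom
#' RMS on backbone and 1.6 Angstrom RMS on side chains, a planted
#' charged-interaction fraction per model (top model 75/90, a quarter of the
#' ensemble at or below 0.1 including a few exact zeros), and planted
#' discriminating side-chain displacements in the low-scoring models
#' (4.7 Angstrom at the 5.46 carboxyl oxygen, 2.1 Angstrom at the 7.42
#' distal carbon).
#'
#' @param n_models,n_ligands,poses_per_ligand,n_runs ensemble dimensions.
#' @param sigma_backbone,sigma_sidechain per-atom RMS displacement of the
#'   Gaussian coordinate noise, in Angstrom (per-coordinate sd is
#'   sigma/sqrt(3)).
#' @param planted_scores optional numeric vector (length `n_models`,
#'   fractions in \[0,1\]) or matrix (`n_models x n_runs`); fractions not
#'   representable as k/(total poses) are rounded to the nearest k and the
#'   truth table records the actual value.  Default: a seeded distribution
#'   with the shape described above.
#' @param planted_shifts data.frame with columns `bw_label`, `atom`,
#'   `delta` applied to low-scoring models; `NULL` for none.
#' @param low_score_threshold models with planted aggregate score <= this
#'   receive the shifts (default 0.1).
#' @param interacting_range,noninteracting_range distance windows (Angstrom,
#'   cation to anchor carboxyl carbon) for planted interacting and
#'   non-interacting poses; the gap around the 6 Angstrom boundary gives the
#'   construction a safety margin of at least 0.5 Angstrom.
#' @param seed integer master seed; every derived random draw is a pure
#'   function of (seed, model index, run index), so generation is
#'   reproducible and chunkable.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_models = 1000L, n_ligands = 9L,
                           poses_per_ligand = 10L, n_runs = 2L,
                           sigma_backbone = 0.4, sigma_sidechain = 1.6,
                           planted_scores = NULL,
                           planted_shifts = data.frame(
                             bw_label = c("5.46", "7.42"),
                             atom = c("OE2", "CD2"),
                             delta = c(4.7, 2.1),
                             stringsAsFactors = FALSE),
                           low_score_threshold = 0.1,
                           interacting_range = c(4.0, 5.5),
                           noninteracting_range = c(7.0, 12.0),
                           seed = 1L) {
  stopifnot(sigma_backbone >= 0, sigma_sidechain >= 0, n_models >= 1,
            n_runs >= 1)
  if (!is.null(planted_shifts) && any(planted_shifts$delta < 0))
    stop("planted shift deltas must be >= 0")
  structure(list(n_models = as.integer(n_models),
                 n_ligands = as.integer(n_ligands),
                 poses_per_ligand = as.integer(poses_per_ligand),
                 n_runs = as.integer(n_runs),
                 sigma_backbone = sigma_backbone,
                 sigma_sidechain = sigma_sidechain,
                 planted_scores = planted_scores,
                 planted_shifts = planted_shifts,
                 low_score_threshold = low_score_threshold,
                 interacting_range = interacting_range,
                 noninteracting_range = noninteracting_range,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

derived_seed <- function(seed, ...) {
  k <- c(...)
  as.integer((as.numeric(seed) * 7919 + sum(k * 131^(seq_along(k) - 1))) %%
               2147483629)
}

# default planted per-model interacting counts k (out of n_poses):
# one top model at 75/90-equivalent, ~0.7% exact zeros, a quarter of the
# ensemble at or below score 0.1, the rest spread over the mid range
default_planted_k <- function(n_models, n_poses, seed) {
  n_zero <- max(1L, round(0.007 * n_models))
  n_low <- max(0L, round(0.25 * n_models) - n_zero - 0L)
  n_top <- 1L
  n_mid <- n_models - n_zero - n_low - n_top
  if (n_mid < 0) stop("n_models too small for the default score profile")
  k_low_max <- floor(0.1 * n_poses)
  k_top <- max(2L, round(75 / 90 * n_poses))
  mid_range <- seq.int(min(k_low_max + 1L, k_top - 1L), k_top - 1L)
  local_seed(derived_seed(seed, 1L), {
    k_low <- if (n_low > 0L && k_low_max >= 1L)
      sample.int(k_low_max, n_low, replace = TRUE) else rep(0L, n_low)
    k <- c(rep(0L, n_zero), k_low,
           sample(mid_range, n_mid, replace = TRUE), k_top)
    sample(k)   # shuffle which model gets which score
  })
}

model_id_fmt <- function(n_models) {
  paste0("model_%0", max(4L, nchar(n_models)), "d")
}

#' Generate a synthetic receptor-model ensemble
#'
#' Copies the [fixture_template()] `n_models` times, adds isotropic Gaussian
#' coordinate noise (backbone and side-chain scales separately), and applies
#' the planted side-chain shifts to the low-scoring models (shift direction:
#' radially out of the pocket, the same fixed direction in every shifted
#' model).  Deterministic under the config seed; model `i` depends only on
#' (seed, i).
#'
#' @param config a [fixture_config()].
#' @return list with `models` (named list of `receptor_model`s), `bwmap`,
#'   `site`, `truth` (list with per-model planted counts/scores, expected
#'   ranking, shifted atoms and low-score ids).
#' @export
make_receptor_ensemble <- function(config) {
  tpl <- fixture_template()
  n_poses <- config$n_ligands * config$poses_per_ligand
  k_tab <- planted_k_matrix(config, n_poses)
  ids <- sprintf(model_id_fmt(config$n_models), seq_len(config$n_models))
  agg <- rowMeans(k_tab) / n_poses
  low <- agg <= config$low_score_threshold

  shifts <- config$planted_shifts
  shift_idx <- integer(0); shift_vec <- list()
  if (!is.null(shifts) && nrow(shifts)) {
    for (s in seq_len(nrow(shifts))) {
      res <- resolve_bw(tpl$model, tpl$bwmap, shifts$bw_label[s])
      row <- res[res$name == shifts$atom[s], , drop = FALSE]
      if (nrow(row) != 1L)
        stop("planted shift atom ", shifts$atom[s], " not found at ",
             shifts$bw_label[s])
      i <- which(tpl$model$atoms$serial == row$serial)
      out_dir <- c(row$x, row$y, 0)
      out_dir <- out_dir / sqrt(sum(out_dir^2))  # radially out of the pocket
      shift_idx[s] <- i
      shift_vec[[s]] <- out_dir * shifts$delta[s]
    }
  }

  base <- coords(tpl$model)
  bb <- atom_subset(tpl$model, "backbone")
  sc <- atom_subset(tpl$model, "sidechain")
  sd_atom <- numeric(nrow(base))
  sd_atom[bb] <- config$sigma_backbone / sqrt(3)
  sd_atom[sc] <- config$sigma_sidechain / sqrt(3)

  models <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    xyz <- base
    if (length(shift_idx) && low[m])
      for (s in seq_along(shift_idx))
        xyz[shift_idx[s], ] <- xyz[shift_idx[s], ] + shift_vec[[s]]
    noise <- local_seed(derived_seed(config$seed, 2L, m),
                        matrix(stats::rnorm(length(xyz), sd = sd_atom),
                               ncol = 3))
    mod <- tpl$model
    coords(mod) <- xyz + noise
    mod$model_id <- ids[m]
    models[[m]] <- mod
  }
  names(models) <- ids

  truth_scores <- data.frame(
    model_id = rep(ids, config$n_runs),
    run_id = rep(sprintf("run%d", seq_len(config$n_runs)), each = config$n_models),
    k = as.vector(k_tab), n = n_poses,
    score = as.vector(k_tab) / n_poses, stringsAsFactors = FALSE)
  expected_rank <- rank_models(
    data.frame(model_id = truth_scores$model_id,
               run_id = truth_scores$run_id,
               score = truth_scores$score, stringsAsFactors = FALSE))
  list(models = models, bwmap = tpl$bwmap, site = tpl$site,
       truth = list(scores = truth_scores,
                    aggregate = stats::setNames(agg, ids),
                    expected_order = expected_rank$model_id,
                    low_score_models = ids[low],
                    shifts = shifts,
                    shifted_atom_serial =
                      tpl$model$atoms$serial[shift_idx]))
}

planted_k_matrix <- function(config, n_poses) {
  ps <- config$planted_scores
  if (is.null(ps)) {
    k <- default_planted_k(config$n_models, n_poses, config$seed)
    return(matrix(k, nrow = config$n_models, ncol = config$n_runs))
  }
  if (is.matrix(ps)) {
    stopifnot(nrow(ps) == config$n_models, ncol(ps) == config$n_runs)
    return(round(ps * n_poses))
  }
  stopifnot(length(ps) == config$n_models)
  matrix(round(ps * n_poses), nrow = config$n_models, ncol = config$n_runs)
}

# one synthetic pose set for (model index m, run index r); a pure function
# of (config$seed, m, r) given the model coordinates
make_pose_set_one <- function(config, model, bwmap, m, r) {
  n_poses <- config$n_ligands * config$poses_per_ligand
  anchor <- resolve_bw(model, bwmap, "3.32")
  cg <- anchor[anchor$name == "CG", , drop = FALSE]
  cxyz <- c(cg$x, cg$y, cg$z)
  k <- attr(model, "planted_k")  # set by caller when known
  local_seed(derived_seed(config$seed, 3L, m, r), {
    interacting <- logical(n_poses)
    if (k > 0) interacting[sample.int(n_poses, k)] <- TRUE
    d <- ifelse(interacting,
                stats::runif(n_poses, config$interacting_range[1],
                             config$interacting_range[2]),
                stats::runif(n_poses, config$noninteracting_range[1],
                             config$noninteracting_range[2]))
    # random directions on the sphere
    u <- matrix(stats::rnorm(3 * n_poses), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    poses <- vector("list", n_poses)
    for (p in seq_len(n_poses)) {
      lig <- (p - 1L) %/% config$poses_per_ligand + 1L
      cation <- cxyz + d[p] * u[p, ]
      tail1 <- cation + d[p] * u[p, ] * (1.5 / d[p])
      tail2 <- cation + d[p] * u[p, ] * (2.9 / d[p])
      atoms <- data.frame(
        element = c("N", "C", "C"),
        x = c(cation[1], tail1[1], tail2[1]),
        y = c(cation[2], tail1[2], tail2[2]),
        z = c(cation[3], tail1[3], tail2[3]),
        formal_charge = c(1L, 0L, 0L), stringsAsFactors = FALSE)
      poses[[p]] <- ligand_pose(
        sprintf("lig%02d_p%02d", lig,
                (p - 1L) %% config$poses_per_ligand + 1L),
        sprintf("lig%02d", lig), atoms,
        bonds = data.frame(from = c(1L, 2L), to = c(2L, 3L),
                           order = c(1L, 1L)))
    }
    pose_set(model$model_id, sprintf("run%d", r), poses)
  })
}

#' Generate synthetic pose sets with planted interaction fractions
#'
#' For every (model, run) pair, places `n_ligands * poses_per_ligand` small
#' cationic ligand fragments so that exactly the planted number of poses has
#' its charged nitrogen within the interacting distance window of the
#' anchor carboxyl carbon of that very model (and the rest well outside), so
#' scoring recovers the planted fraction exactly.
#'
#' @param config a [fixture_config()].
#' @param ensemble result of [make_receptor_ensemble()] (or a compatible
#'   list with `models`, `bwmap`, `truth`).
#' @param model_idx optional subset of model indices to generate (chunked
#'   generation yields identical sets).
#' @return list of [pose_set()]s (runs nested within models).
#' @export
make_pose_sets <- function(config, ensemble, model_idx = NULL) {
  idx <- model_idx %||% seq_along(ensemble$models)
  truth <- ensemble$truth$scores
  out <- vector("list", length(idx) * config$n_runs)
  j <- 0L
  for (m in idx) {
    model <- ensemble$models[[m]]
    for (r in seq_len(config$n_runs)) {
      k <- truth$k[truth$model_id == model$model_id &
                     truth$run_id == sprintf("run%d", r)]
      attr(model, "planted_k") <- k
      j <- j + 1L
      out[[j]] <- make_pose_set_one(config, model, ensemble$bwmap, m, r)
    }
  }
  out
}

#' Generate a synthetic bioactivity table with known filter survivors
#'
#' Builds `n` records that pass every curation stage, then mutates disjoint
#' subsets so that each profiled record fails exactly its assigned stage;
#' the expected kept count is `n - sum(fail_profile)`.
#'
#' @param n number of records.
#' @param fail_profile named integer vector/list over the stage names
#'   (`mw`, `confidence`, `type`, `relation`, `value`, `unit`, `stereo`).
#' @param seed integer seed.
#' @return list with `records` (data.frame), `expected_kept`,
#'   `fail_profile`.
#' @export
make_activity_table <- function(n, fail_profile = list(), seed = 1L) {
  fail_profile <- unlist(fail_profile)
  if (length(fail_profile) &&
      !all(names(fail_profile) %in% CURATION_STAGES))
    stop("unknown stage in fail_profile: ",
         paste(setdiff(names(fail_profile), CURATION_STAGES),
               collapse = ", "))
  if (sum(fail_profile) > n)
    stop("fail_profile assigns more failures (", sum(fail_profile),
         ") than records (", n, ")")
  local_seed(derived_seed(seed, 4L), {
    rec <- data.frame(
      ligand_id = sprintf("L%05d", seq_len(n)),
      smiles = vapply(sample(1:6, n, TRUE),
                      function(k) paste(rep("C", k), collapse = ""), ""),
      mw = round(stats::runif(n, 150, 500), 2),
      confidence = 9L,
      std_type = sample(c("Ki", "Kd", "IC50", "EC50"), n, TRUE),
      std_relation = "=",
      std_value = round(stats::runif(n, 0.1, 10), 3),
      std_unit = "nM",
      year = sample(1995:2018, n, TRUE),
      stereo_clear = TRUE, stringsAsFactors = FALSE)
    pool <- sample.int(n)   # disjoint failure assignment
    taken <- 0L
    for (st in names(fail_profile)) {
      cnt <- fail_profile[[st]]
      if (cnt == 0) next
      i <- pool[(taken + 1L):(taken + cnt)]
      taken <- taken + cnt
      rec[i, ] <- within(rec[i, , drop = FALSE], {
        if (st == "mw") mw <- round(stats::runif(cnt, 501, 900), 2)
        if (st == "confidence") confidence <- sample(4:8, cnt, TRUE)
        if (st == "type") std_type <- "Inhibition"
        if (st == "relation") std_relation <- ">"
        if (st == "value") std_value <- round(stats::runif(cnt, 10.5, 500), 2)
        if (st == "unit") std_unit <- "uM"
        if (st == "stereo") stereo_clear <- FALSE
      })
    }
    list(records = rec, expected_kept = n - sum(fail_profile),
         fail_profile = as.list(fail_profile))
  })
}

#' Generate duplicate-measurement groups for deduplication tests
#'
#' Random groups of 2-4 records per ligand with mixed binding/functional
#' types, years and values; the preferred survivor is decided by the stated
#' preference order and can be recomputed independently by brute force.
#'
#' @param n_groups number of ligands with duplicates.
#' @param seed integer seed.
#' @return data.frame of activity records (several rows per ligand_id).
#' @export
make_duplicate_records <- function(n_groups, seed = 1L) {
  local_seed(derived_seed(seed, 5L), {
    rows <- lapply(seq_len(n_groups), function(g) {
      k <- sample(2:4, 1)
      data.frame(ligand_id = sprintf("DUP%04d", g),
                 mw = round(stats::runif(1, 150, 500), 2),
                 confidence = 9L,
                 std_type = sample(c("Ki", "Kd", "IC50", "EC50"), k, TRUE),
                 std_relation = "=",
                 std_value = round(stats::runif(k, 0.1, 10), 3),
                 std_unit = "nM",
                 year = sample(1995:2018, k, TRUE),
                 stereo_clear = TRUE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[sample.int(nrow(out)), , drop = FALSE]   # shuffle row order
  })
}

#' Write a complete fixture directory
#'
#' Materializes the synthetic study on disk: one PDB per model under
#' `models/`, one SDF per (model, run) under `poses/` named
#' `<model_id>__<run_id>.sdf`, `manifest.tsv`, `bwmap.tsv`, `site.yaml`,
#' an `activity.csv` table with its curation truth, and `truth.json` with
#' all planted ground truth.  Generation is streamed model by model, so
#' memory stays flat for large ensembles.
#'
#' @param dir output directory (created).
#' @param config a [fixture_config()].
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, config = fixture_config()) {
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "poses"), showWarnings = FALSE)
  ens <- make_receptor_ensemble(config)
  utils::write.table(ens$bwmap, file.path(dir, "bwmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_site_spec(ens$site, file.path(dir, "site.yaml"))
  manifest <- list()
  for (m in seq_along(ens$models)) {
    model <- ens$models[[m]]
    write_pdb(model, file.path(dir, "models", paste0(model$model_id, ".pdb")))
    sets <- make_pose_sets(config, ens, model_idx = m)
    for (ps in sets) {
      fn <- sprintf("%s__%s.sdf", ps$model_id, ps$run_id)
      write_poses_sdf(ps, file.path(dir, "poses", fn))
      manifest[[length(manifest) + 1L]] <- data.frame(
        model_id = ps$model_id, run_id = ps$run_id,
        model_path = file.path("models", paste0(ps$model_id, ".pdb")),
        pose_path = file.path("poses", fn), stringsAsFactors = FALSE)
    }
    ens$models[m] <- list(NULL)   # free as we go
  }
  utils::write.table(do.call(rbind, manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  act <- make_activity_table(
    600L, fail_profile = list(mw = 40L, confidence = 20L, type = 25L,
                              relation = 15L, value = 20L, unit = 15L,
                              stereo = 15L),
    seed = config$seed)
  utils::write.csv(act$records, file.path(dir, "activity.csv"),
                   row.names = FALSE)
  truth <- list(config = config[setdiff(names(config), "planted_scores")],
                scores = ens$truth$scores,
                expected_order = ens$truth$expected_order,
                low_score_models = ens$truth$low_score_models,
                shifts = ens$truth$shifts,
                activity_expected_kept = act$expected_kept,
                activity_fail_profile = act$fail_profile)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
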