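# Small in-code fixtures and independent oracles shared across test files.

# A single aspartate residue (8 heavy atoms) with its carboxyl carbon (CG)
# at a chosen position.
asp_residue_atoms <- function(cg = c(0, 0, 0), resno = 114L) {
  base <- rbind(N = c(-2.5, 1.2, 0), CA = c(-1.8, 0, 0), C = c(-2.4, -1.3, 0),
                O = c(-3.6, -1.4, 0.3), CB = c(-0.9, 0.2, 0.8),
                CG = c(0, 0, 0), OD1 = c(0.4, 1.1, 0.4),
                OD2 = c(0.6, -1.0, -0.4))
  base <- sweep(base, 2, -cg)  # translate so CG sits at `cg`
  data.frame(serial = seq_len(8), name = rownames(base),
             element = substr(rownames(base), 1, 1), resname = "ASP",
             resno = resno, chain = "A",
             x = base[, 1], y = base[, 2], z = base[, 3],
             stringsAsFactors = FALSE)
}

asp_model <- function(cg = c(0, 0, 0), resno = 114L, model_id = "asp") {
  receptor_model(model_id, asp_residue_atoms(cg, resno))
}

asp_bwmap <- function(resno = 114L) {
  bw_map(data.frame(bw_label = "3.32", chain = "A", resnum = resno,
                    resname = "ASP", stringsAsFactors = FALSE))
}

# a pose with cationic atoms at given positions (plus a neutral carbon)
cation_pose <- function(positions, charges = rep(1L, nrow(positions)),
                        pose_id = "p1", ligand_id = "lig1") {
  force(charges)
  positions <- rbind(positions, c(50, 50, 50))   # far-away neutral atom
  n <- nrow(positions)
  ligand_pose(pose_id, ligand_id, data.frame(
    element = c(rep("N", n - 1L), "C"),
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    formal_charge = c(as.integer(charges), 0L), stringsAsFactors = FALSE),
    bonds = data.frame(from = seq_len(n - 1L), to = rep(n, n - 1L),
                       order = rep(1L, n - 1L)))
}

# independent oracle: all-pairs distance scan between every cationic atom
# and the carboxyl carbon, then threshold
brute_force_ionic <- function(pose, anchor_atoms, max_distance = 6.0) {
  cname <- if (unique(anchor_atoms$resname) == "ASP") "CG" else "CD"
  cc <- anchor_atoms[anchor_atoms$name == cname, ]
  idx <- which(pose$atoms$formal_charge >= 1L)
  if (!length(idx)) return(list(hit = FALSE, min_d = Inf))
  best <- Inf
  for (i in idx) {
    a <- pose$atoms[i, ]
    d <- sqrt((a$x - cc$x)^2 + (a$y - cc$y)^2 + (a$z - cc$z)^2)
    if (d < best) best <- d
  }
  list(hit = best <= max_distance, min_d = best)
}

# independent oracle for deduplication: explicit pairwise dominance
dedup_winner_bruteforce <- function(group) {
  beats <- function(i, j) {
    bi <- group$std_type[i] %in% c("Ki", "Kd")
    bj <- group$std_type[j] %in% c("Ki", "Kd")
    if (bi != bj) return(bi)
    if (group$year[i] != group$year[j]) return(group$year[i] > group$year[j])
    if (group$std_value[i] != group$std_value[j])
      return(group$std_value[i] < group$std_value[j])
    i < j   # stable input order
  }
  w <- 1L
  for (i in seq_len(nrow(group))[-1]) if (beats(i, w)) w <- i
  w
}

# uniformly-ish random rotation matrix (QR of Gaussian, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform_model <- function(model, R, t) {
  coordsm <- as.matrix(model$atoms[, c("x", "y", "z")])
  newxyz <- sweep(coordsm %*% t(R), 2, t, `+`)
  a <- model$atoms
  a$x <- newxyz[, 1]; a$y <- newxyz[, 2]; a$z <- newxyz[, 3]
  receptor_model(model$model_id, a)
}

# small two-model helper: template plus per-subset Gaussian noise
noisy_template_models <- function(n, sigma_bb, sigma_sc, seed,
                                  shift_atom = NULL, shift_vec = NULL) {
  tpl <- fixture_template()$model
  bb <- atom_subset(tpl, "backbone"); sc <- atom_subset(tpl, "sidechain")
  sdv <- numeric(nrow(tpl$atoms))
  sdv[bb] <- sigma_bb / sqrt(3); sdv[sc] <- sigma_sc / sqrt(3)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- tpl$atoms
    noise <- matrix(rnorm(3 * nrow(a), sd = sdv), ncol = 3)
    a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
    if (!is.null(shift_atom)) {
      a$x[shift_atom] <- a$x[shift_atom] + shift_vec[1]
      a$y[shift_atom] <- a$y[shift_atom] + shift_vec[2]
      a$z[shift_atom] <- a$z[shift_atom] + shift_vec[3]
    }
    receptor_model(sprintf("m%03d", i), a)
  })
}
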