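#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between paired coordinate sets, via SVD of the covariance matrix with the
#' usual determinant correction that excludes reflections.  The fitted
#' mapping is `x -> R %*% (x - centroid_mobile) + centroid_reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows
#'   (n >= 3, not all collinear).
#' @return object of class `superposition`: list with `rotation` (3 x 3,
#'   det = +1), `translation` (the mapping above folded into `R x + t` form)
#'   and `rmsd_after` in Angstrom.
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.numeric(mobile) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinate matrices must be n x 3")
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("coordinate sets differ in length")
  if (n < 3) stop("need at least 3 paired points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  if (qr(X)$rank < 2 || qr(Y)$rank < 2)
    stop("degenerate (collinear) coordinates: rotation not determined")
  C <- crossprod(X, Y)                       # 3 x 3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # y ~ R x (centered)
  fitted <- X %*% t(R)
  rmsd_after <- sqrt(mean(rowSums((Y - fitted)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd_after = rmsd_after),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition: rmsd_after =", format(x$rmsd_after, digits = 6),
      "Angstrom\n")
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a `superposition` from [kabsch_fit()].
#' @param xyz n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

stop_if_topology_mismatch <- function(a, b) {
  if (!identical(a$topology_key, b$topology_key))
    stop("models '", a$model_id, "' and '", b$model_id,
         "' differ in topology; atomwise comparison undefined")
}

rmsd_of <- function(A, B, idx) {
  if (!length(idx)) return(NA_real_)
  sqrt(mean(rowSums((A[idx, , drop = FALSE] - B[idx, , drop = FALSE])^2)))
}

#' RMSD between two models with backbone/side-chain decomposition
#'
#' Computes heavy-atom RMSD on all three subsets (all heavy, backbone, side
#' chain) from a single superposition, so the partition identity
#' `n_all * all^2 = n_bb * bb^2 + n_sc * sc^2` holds exactly.
#'
#' @param model_a,model_b `receptor_model`s sharing one topology.
#' @param superpose fit `model_a` onto `model_b` before measuring?
#' @param fit_subset atom subset used for the fit (default backbone heavy
#'   atoms, the convention used throughout this package).
#' @return object of class `rmsd_summary`: list with `all_heavy`,
#'   `backbone`, `sidechain` (Angstrom) and `n_atoms` per subset.
#' @export
rmsd <- function(model_a, model_b, superpose = TRUE,
                 fit_subset = "backbone") {
  stop_if_topology_mismatch(model_a, model_b)
  A <- coords(model_a); B <- coords(model_b)
  idx <- list(all_heavy = atom_subset(model_a, "all_heavy"),
              backbone = atom_subset(model_a, "backbone"),
              sidechain = atom_subset(model_a, "sidechain"))
  if (superpose) {
    fi <- atom_subset(model_a, fit_subset)
    sup <- kabsch_fit(A[fi, , drop = FALSE], B[fi, , drop = FALSE])
    A <- apply_superposition(sup, A)
  }
  structure(list(all_heavy = rmsd_of(A, B, idx$all_heavy),
                 backbone = rmsd_of(A, B, idx$backbone),
                 sidechain = rmsd_of(A, B, idx$sidechain),
                 n_atoms = vapply(idx, length, 0L)),
            class = "rmsd_summary")
}

#' @export
print.rmsd_summary <- function(x, ...) {
  cat(sprintf(
    "RMSD (Angstrom): all heavy %.3f (n=%d), backbone %.3f (n=%d), sidechain %.3f (n=%d)\n",
    x$all_heavy, x$n_atoms[["all_heavy"]], x$backbone,
    x$n_atoms[["backbone"]], x$sidechain, x$n_atoms[["sidechain"]]))
  invisible(x)
}

#' Superpose an ensemble onto a common reference
#'
#' Reference "mean": fit every model onto the first model (backbone heavy
#' atoms), average coordinates, then refit every model onto that average
#' once more and re-average.  One refit round makes the reference
#' deterministic and essentially converged for compact ensembles.
#'
#' @param models list of `receptor_model`s with equal topology.
#' @param reference "mean" or "first".
#' @param fit_subset subset used for fitting (default backbone).
#' @return list with `models` (superposed copies) and `reference`
#'   (a `receptor_model`).
#' @export
superpose_ensemble <- function(models, reference = c("mean", "first"),
                               fit_subset = "backbone") {
  reference <- match.arg(reference)
  if (!length(models)) stop("empty ensemble")
  for (m in models) stop_if_topology_mismatch(models[[1]], m)
  fi <- atom_subset(models[[1]], fit_subset)
  fit_all <- function(ref_xyz) {
    lapply(models, function(m) {
      X <- coords(m)
      sup <- kabsch_fit(X[fi, , drop = FALSE],
                        ref_xyz[fi, , drop = FALSE])
      coords(m) <- apply_superposition(sup, X)
      m
    })
  }
  ref_xyz <- coords(models[[1]])
  fitted <- fit_all(ref_xyz)
  if (reference == "mean") {
    avg <- function(ms) Reduce(`+`, lapply(ms, coords)) / length(ms)
    fitted <- fit_all(avg(fitted))   # one refit round onto the average
    ref_xyz <- avg(fitted)
  }
  ref <- models[[1]]
  coords(ref) <- ref_xyz
  ref$model_id <- if (reference == "mean") "ensemble_mean"
                  else models[[1]]$model_id
  ref <- receptor_model(ref$model_id, ref$atoms)
  list(models = fitted, reference = ref)
}

#' Coordinate-wise mean structure of superposed models
#'
#' Plain unweighted per-atom arithmetic mean; the models are assumed to be
#' already superposed onto a common frame (see [superpose_ensemble()]).
#'
#' @param models non-empty list of `receptor_model`s with equal topology.
#' @return a `receptor_model` with model_id "mean".
#' @export
mean_structure <- function(models) {
  if (!length(models)) stop("empty ensemble")
  for (m in models) stop_if_topology_mismatch(models[[1]], m)
  out <- models[[1]]
  coords(out) <- Reduce(`+`, lapply(models, coords)) / length(models)
  receptor_model("mean", out$atoms)
}

#' Ensemble RMSD with backbone/side-chain decomposition
#'
#' Superposes every model onto the reference (backbone heavy-atom fit) and
#' reports per-model RMSD summaries plus their arithmetic means, the way
#' ensemble flexibility of homology-model sets is usually quantified.
#' Optionally also reports the average over all model pairs.
#'
#' @param models list of >= 2 `receptor_model`s with equal topology.
#' @param reference "mean" (iteratively fitted ensemble average; headline
#'   numbers) or "first".
#' @param include_pairwise also compute the all-pairs average (quadratic in
#'   ensemble size; off by default).
#' @return object of class `ensemble_rmsd`: list with `per_model`
#'   (data.frame), `average` (named numeric), `n_atoms`, `reference`, and
#'   optionally `pairwise_average`.
#' @export
ensemble_rmsd <- function(models, reference = c("mean", "first"),
                          include_pairwise = FALSE) {
  reference <- match.arg(reference)
  if (length(models) < 2L) stop("ensemble RMSD needs at least 2 models")
  sup <- superpose_ensemble(models, reference)
  per <- lapply(sup$models, function(m) rmsd(m, sup$reference,
                                             superpose = FALSE))
  per_model <- data.frame(
    model_id = vapply(models, function(m) m$model_id, ""),
    all_heavy = vapply(per, `[[`, 0, "all_heavy"),
    backbone = vapply(per, `[[`, 0, "backbone"),
    sidechain = vapply(per, `[[`, 0, "sidechain"),
    stringsAsFactors = FALSE)
  out <- list(per_model = per_model,
              average = c(all_heavy = mean(per_model$all_heavy),
                          backbone = mean(per_model$backbone),
                          sidechain = mean(per_model$sidechain)),
              n_atoms = per[[1]]$n_atoms,
              reference = sup$reference)
  if (include_pairwise) {
    n <- length(sup$models)
    acc <- c(all_heavy = 0, backbone = 0, sidechain = 0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      # models already share a frame, but each pair gets its own fit so the
      # pairwise numbers are frame-independent
      r <- rmsd(sup$models[[i]], sup$models[[j]], superpose = TRUE)
      acc <- acc + c(r$all_heavy, r$backbone, r$sidechain)
    }
    out$pairwise_average <- acc / (n * (n - 1L) / 2L)
  }
  class(out) <- "ensemble_rmsd"
  out
}

#' @export
print.ensemble_rmsd <- function(x, ...) {
  cat(sprintf(
    "Ensemble of %d models, average RMSD to reference (Angstrom):\n  all heavy %.2f | backbone %.2f | sidechain %.2f\n",
    nrow(x$per_model), x$average[["all_heavy"]], x$average[["backbone"]],
    x$average[["sidechain"]]))
  if (!is.null(x$pairwise_average))
    cat(sprintf("  pairwise average: all heavy %.2f | backbone %.2f | sidechain %.2f\n",
                x$pairwise_average[["all_heavy"]],
                x$pairwise_average[["backbone"]],
                x$pairwise_average[["sidechain"]]))
  invisible(x)
}
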