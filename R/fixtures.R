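# Synthetic protein-ligand fixtures with a known, AEV-linear ground truth,
# so every downstream module is testable without external structures. The
# geometry emulates a buried small molecule: a compact ligand cluster
# surrounded by a shell of 1-3-atom "residues" at binding-site distances.

#' Configuration of the synthetic-complex generator
#'
#' Defaults sketch a small binding site: 4-8 ligand atoms inside a 2.5 A
#' ball, 12-24 protein atoms grouped in residues whose centres sit 3-6 A
#' from the origin (so a 3.5 A selection keeps some and drops others), a
#' 1.5 A minimum interatomic distance (covalent-bond scale), and a 3-species
#' (C, N, O) heavy-atom palette.
#'
#' @param n_ligand_atoms integer range (min, max).
#' @param n_protein_atoms integer range (min, max).
#' @param species_pool element labels drawn from uniformly.
#' @param ligand_radius Angstrom radius of the ligand cluster.
#' @param shell Angstrom range (min, max) of residue-centre distances.
#' @param min_dist minimum pairwise distance, Angstrom (> 0).
#' @param seed integer seed.
#' @param noise_sd Gaussian noise added to ground-truth pK (0 = noiseless).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_ligand_atoms = c(4L, 8L),
                             n_protein_atoms = c(12L, 24L),
                             species_pool = c("C", "N", "O"),
                             ligand_radius = 2.5,
                             shell = c(3.0, 6.0),
                             min_dist = 1.5,
                             seed = 1L,
                             noise_sd = 0) {
  stopifnot(min_dist > 0, length(n_ligand_atoms) == 2,
            length(n_protein_atoms) == 2, noise_sd >= 0)
  structure(list(n_ligand_atoms = as.integer(n_ligand_atoms),
                 n_protein_atoms = as.integer(n_protein_atoms),
                 species_pool = species_pool,
                 ligand_radius = ligand_radius, shell = shell,
                 min_dist = min_dist, seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "synthetic_config")
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# place a point at `radius(+-spread)` from `center` respecting min_dist to
# `existing`; 1000 retries before giving up
.place_atom <- function(center, radius, spread, existing, min_dist) {
  for (try in 1:1000) {
    p <- center + .rand_unit() * stats::runif(1, max(0, radius - spread),
                                              radius + spread)
    if (is.null(existing) ||
        min(sqrt(colSums((t(existing) - p)^2))) >= min_dist)
      return(p)
  }
  stop("could not satisfy min_dist within retry budget")
}

#' Generate one synthetic protein-ligand complex
#'
#' Deterministic given `cfg$seed`. Ligand atoms fill a central cluster;
#' protein atoms are grouped into residues of 1-3 atoms scattered on a
#' surrounding shell. All pairwise distances respect `cfg$min_dist`.
#'
#' @param cfg a [synthetic_config()].
#' @param id identifier for the complex.
#' @return a [pl_complex()] (without affinity; see [true_affinity()]).
#' @export
make_complex <- function(cfg, id = "synth") {
  stopifnot(inherits(cfg, "synthetic_config"))
  rint <- function(rg) if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1)
  withr::with_seed(cfg$seed, {
    n_lig <- rint(cfg$n_ligand_atoms)
    n_prot <- rint(cfg$n_protein_atoms)
    xyz <- NULL
    for (a in seq_len(n_lig)) {
      p <- .place_atom(c(0, 0, 0), cfg$ligand_radius / 2,
                       cfg$ligand_radius / 2, xyz, cfg$min_dist)
      xyz <- rbind(xyz, p)
    }
    lig <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      element = sample(cfg$species_pool, n_lig, replace = TRUE))
    prot <- NULL
    res_id <- 0L
    placed <- 0L
    rows <- list()
    while (placed < n_prot) {
      res_id <- res_id + 1L
      center <- .rand_unit() * stats::runif(1, cfg$shell[1], cfg$shell[2])
      n_in_res <- min(sample(1:3, 1), n_prot - placed)
      for (a in seq_len(n_in_res)) {
        p <- .place_atom(center, 0.9, 0.9, xyz, cfg$min_dist)
        xyz <- rbind(xyz, p)
        rows[[length(rows) + 1L]] <- data.frame(
          element = sample(cfg$species_pool, 1), x = p[1], y = p[2], z = p[3],
          residue_id = sprintf("A|%d| |RES", res_id), record = "ATOM")
        placed <- placed + 1L
      }
    }
    prot <- do.call(rbind, rows)
    pl_complex(protein_atoms = prot,
               ligand_atoms = lig[, c("x", "y", "z", "element")],
               id = id)
  })
}

#' Ground-truth affinity functional
#'
#' A deterministic additive functional of the AEVs: atom `i` contributes
#' `w[species(i)] * phi(G_i)` where `phi` is one fixed random linear map
#' shared by all species and `w` holds per-species scalar weights;
#' contributions are summed. The functional is representable by the model
#' family by construction, so parameter recovery is well-posed. An affine
#' calibration maps the raw values onto a realistic affinity scale
#' (mean ~6.5 pK, sd ~1.8 pK, the spread of curated affinity databases);
#' being affine, it keeps the truth inside the representable family. The
#' functional inherits the AEVs' rigid-transform invariance, so recovery
#' tests cannot be passed by coordinate memorization.
#'
#' @param params the [aev_params()] the truth is defined over.
#' @param d binding-site selection distance used when evaluating complexes.
#' @param map [species_map()] used when evaluating complexes.
#' @param seed integer seed fixing the weights.
#' @return an object of class `truth_spec` with unit calibration; see
#'   [calibrate_truth()].
#' @export
truth_spec <- function(params, d = 3.5, map = species_map(), seed = 1L) {
  stopifnot(inherits(params, "aev_params"))
  L <- aev_length(params)
  ns <- length(params$species)
  withr::with_seed(seed, {
    phi <- stats::rnorm(L, sd = 1 / sqrt(L))
    w <- stats::rnorm(ns)
  })
  structure(list(params = params, d = d, map = map, phi = phi, w = w,
                 scale = 1, shift = 0, seed = as.integer(seed)),
            class = "truth_spec")
}

#' Evaluate the ground-truth affinity of a system
#'
#' @param system an [atomic_system()] (already selected/mapped).
#' @param truth a [truth_spec()].
#' @return pK value.
#' @export
true_affinity <- function(system, truth) {
  stopifnot(inherits(system, "atomic_system"), inherits(truth, "truth_spec"))
  aevs <- compute_aevs(system, truth$params)
  sp <- attr(aevs, "species_index")
  raw <- sum(truth$w[sp] * as.vector(unclass(aevs) %*% truth$phi))
  truth$scale * raw + truth$shift
}

#' Calibrate the truth functional onto an affinity scale
#'
#' Sets the affine calibration so a reference collection of systems has the
#' requested mean and standard deviation of pK.
#'
#' @param truth a [truth_spec()].
#' @param systems list of [atomic_system()] objects.
#' @param target_mean,target_sd requested moments, pK units.
#' @return the calibrated `truth_spec`.
#' @export
calibrate_truth <- function(truth, systems, target_mean = 6.5,
                            target_sd = 1.8) {
  raw <- vapply(systems, function(s) true_affinity(s, truth), 0)
  if (stats::sd(raw) == 0) stop("degenerate truth: constant over reference set")
  truth$scale <- target_sd / stats::sd(raw)
  truth$shift <- target_mean - truth$scale * mean(raw)
  truth
}

#' Generate a labelled synthetic dataset
#'
#' `n` complexes with per-complex seeds derived from `cfg$seed`, a truth
#' functional calibrated on the generated collection, ground-truth pK labels
#' (plus optional Gaussian noise) and optional synthetic baseline docking
#' scores for delta-learning (baseline = noisy affinity mapped back to
#' kcal/mol).
#'
#' @param cfg a [synthetic_config()].
#' @param n number of complexes.
#' @param params an [aev_params()] (also defines the truth).
#' @param d selection distance, Angstrom.
#' @param map a [species_map()].
#' @param baseline generate `baseline_score` columns?
#' @return list with `complexes`, `systems`, `truth`, and data.frame
#'   `labels` (id, pk_exp, baseline_score).
#' @export
make_dataset <- function(cfg, n, params, d = 3.5, map = species_map(),
                         baseline = FALSE) {
  cxs <- lapply(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed * 10000L + i
    make_complex(cfg_i, id = sprintf("synth%04d", i))
  })
  systems <- lapply(cxs, select_binding_site, d = d, map = map)
  truth <- truth_spec(params, d = d, map = map, seed = cfg$seed)
  truth <- calibrate_truth(truth, systems)
  pk <- vapply(systems, function(s) true_affinity(s, truth), 0)
  withr::with_seed(cfg$seed + 7L, {
    if (cfg$noise_sd > 0) pk <- pk + stats::rnorm(n, sd = cfg$noise_sd)
    bs <- if (baseline) {
      # crude baseline: truth corrupted by 1-pK noise, in kcal/mol
      con <- physical_constants()
      -(pk + stats::rnorm(n, sd = 1)) * con$R * con$T * log(10)
    } else rep(NA_real_, n)
  })
  for (i in seq_len(n)) {
    cxs[[i]]$pk_exp <- pk[i]
    cxs[[i]]$baseline_score <- bs[i]
  }
  list(complexes = cxs, systems = systems, truth = truth,
       labels = data.frame(id = vapply(cxs, function(c) c$id, ""),
                           pk_exp = pk, baseline_score = bs))
}

# --- pose decoys ------------------------------------------------------------

#' Root-mean-square deviation between two poses
#'
#' `sqrt(mean(|a_i - b_i|^2))` over matched atoms; computed in place with no
#' re-superposition, as decoy-pose evaluation requires.
#'
#' @param a,b N x 3 coordinate matrices with identical atom order.
#' @return RMSD, Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3)
    stop("pose coordinate matrices must share an N x 3 shape")
  sqrt(mean(rowSums((a - b)^2)))
}

.rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate rigid decoy poses at requested RMSDs
#'
#' Each decoy is a rigid perturbation of the ligand: a random rotation about
#' the ligand centroid scaled (by bisection) to contribute at most ~70% of
#' the target RMSD, plus a random translation sized so the total in-place
#' RMSD hits the target (rotation and translation RMSD contributions add in
#' quadrature about the centroid). Achieved RMSDs land within 10% of each
#' target.
#'
#' @param complex a [pl_complex()].
#' @param rmsd_targets vector of target RMSDs, Angstrom (>= 0).
#' @param seed integer seed.
#' @return list of decoys, each `list(ligand_atoms, rmsd)`; `rmsd` is the
#'   achieved in-place RMSD.
#' @export
make_decoys <- function(complex, rmsd_targets, seed = 1L) {
  stopifnot(inherits(complex, "pl_complex"), all(rmsd_targets >= 0))
  ref <- as.matrix(complex$ligand_atoms[, c("x", "y", "z")])
  centroid <- colMeans(ref)
  centered <- sweep(ref, 2, centroid)
  withr::with_seed(seed, lapply(rmsd_targets, function(target) {
    if (target == 0) {
      new_xyz <- ref
    } else {
      axis <- .rand_unit()
      rot_budget <- 0.7 * target
      lo <- 0
      hi <- pi
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        R <- .rotation_matrix(axis, mid)
        r_rot <- sqrt(mean(rowSums((centered %*% t(R) - centered)^2)))
        if (r_rot > rot_budget) hi <- mid else lo <- mid
      }
      R <- .rotation_matrix(axis, lo)
      rotated <- centered %*% t(R)
      r_rot <- sqrt(mean(rowSums((rotated - centered)^2)))
      t_mag <- sqrt(max(0, target^2 - r_rot^2))
      new_xyz <- sweep(rotated, 2, centroid + .rand_unit() * t_mag, "+")
    }
    achieved <- pose_rmsd(new_xyz, ref)
    if (target > 0 && abs(achieved - target) / target > 0.10)
      stop("decoy RMSD ", round(achieved, 3), " missed target ", target)
    lig <- complex$ligand_atoms
    lig[, c("x", "y", "z")] <- new_xyz
    list(ligand_atoms = lig, rmsd = achieved)
  }))
}

# --- serialization ----------------------------------------------------------

#' Write a complex as PDB (protein) and SDF (ligand) files
#'
#' Minimal valid files that [load_complex()] round-trips: fixed-column PDB
#' ATOM records with the element field, and a V2000 SDF atom block.
#'
#' @param complex a [pl_complex()].
#' @param protein_path,ligand_path output paths (`.pdb` and `.sdf`).
#' @return invisibly, a list of the two paths.
#' @export
write_complex <- function(complex, protein_path, ligand_path) {
  prot <- complex$protein_atoms
  res_key <- match(prot$residue_id, unique(prot$residue_id))
  plines <- vapply(seq_len(nrow(prot)), function(i) {
    el <- toupper(prot$element[i])
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(paste0(el, i %% 100), 1, 4), "", "RES", "A",
            res_key[i], "", prot$x[i], prot$y[i], prot$z[i], 1, 0,
            substr(el, 1, 2))
  }, "")
  writeLines(c(plines, "END"), protein_path)
  lig <- complex$ligand_atoms
  n <- nrow(lig)
  llines <- c(complex$id, "  aevbind synthetic", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
              vapply(seq_len(n), function(i)
                sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        lig$x[i], lig$y[i], lig$z[i], lig$element[i]), ""),
              "M  END", "$$$$")
  writeLines(llines, ligand_path)
  invisible(list(protein_path = protein_path, ligand_path = ligand_path))
}

#' Write a synthetic dataset to disk with a manifest
#'
#' Serializes every complex to PDB/SDF under `dir` and writes
#' `manifest.csv` with columns id, protein_path, ligand_path, pk_exp,
#' baseline_score (paths relative to the manifest).
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$complexes, function(cx) {
    pp <- paste0(cx$id, "_protein.pdb")
    lp <- paste0(cx$id, "_ligand.sdf")
    write_complex(cx, file.path(dir, pp), file.path(dir, lp))
    data.frame(id = cx$id, protein_path = pp, ligand_path = lp,
               pk_exp = cx$pk_exp, baseline_score = cx$baseline_score)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Build a synthetic screening benchmark
#'
#' For each target, a pool of candidate systems labelled by ground truth:
#' actives are pool members whose true affinity (against that target's truth
#' functional) falls in the top `active_fraction`; the best binder is the
#' pool maximum. Scores are left for the caller's model to fill in.
#'
#' @param cfg a [synthetic_config()].
#' @param n_targets number of targets.
#' @param pool_size candidates per target.
#' @param active_fraction fraction labelled as true binders.
#' @param params an [aev_params()].
#' @param d,map selection policy.
#' @return list per target: `list(target_id, systems, true_pk,
#'   is_true_binder, is_best_binder)`.
#' @export
make_screening_pool <- function(cfg, n_targets, pool_size,
                                active_fraction = 0.1, params,
                                d = 3.5, map = species_map()) {
  lapply(seq_len(n_targets), function(t) {
    cfg_t <- cfg
    cfg_t$seed <- cfg$seed + 1000L * t
    ds <- make_dataset(cfg_t, pool_size, params, d = d, map = map)
    pk <- ds$labels$pk_exp
    cut <- stats::quantile(pk, 1 - active_fraction)
    list(target_id = sprintf("target%02d", t), systems = ds$systems,
         true_pk = pk, is_true_binder = pk >= cut,
         is_best_binder = seq_along(pk) == which.max(pk))
  })
}
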