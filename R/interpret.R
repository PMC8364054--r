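# Gradient- and contribution-based interpretation. The prediction is a sum
# of per-atom network outputs over symmetry functions of distances and
# angles, so d(pK)/d(coords) is assembled analytically: reverse-mode
# gradients of each atomic network w.r.t. its AEV row, chained through the
# closed-form derivatives of the radial and angular terms.

# gradient of sum_m w_m * G^R_m terms contributed by atom i's neighbours,
# plus the angular analogue; accumulates into an N x 3 matrix.
# gbar: N x L matrix of d(output)/d(AEV entry).
.aev_coord_grad <- function(coords, spec_idx, params, gbar) {
  n <- nrow(coords)
  ns <- length(params$species)
  nm_r <- length(params$radial_shifts)
  nrad <- ns * nm_r
  th <- params$theta_shifts
  rs <- params$angular_radial_shifts
  nth <- length(th)
  nrs <- length(rs)
  nm_a <- nth * nrs
  zeta <- params$zeta
  ptab <- .pair_table(ns)
  dm <- as.matrix(stats::dist(coords))
  if (n > 1 && min(dm[upper.tri(dm)]) == 0)
    stop("coincident atoms: gradient undefined")
  # theta_s-major-then-Rs expansion used by the featurizer columns
  th_m <- rep(th, each = nrs)
  rs_m <- rep(rs, times = nth)
  cos_th <- cos(th_m)
  sin_th <- sin(th_m)
  grad <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    di <- dm[i, ]
    # radial chain rule
    nb <- which(di <= params$Rc_radial & seq_len(n) != i)
    if (length(nb) > 0L) {
      dj <- di[nb]
      E <- exp(-params$eta_R * (outer(dj, params$radial_shifts, "-"))^2)
      fc <- cutoff_fn(dj, params$Rc_radial)
      fcd <- .cutoff_fn_d(dj, params$Rc_radial)
      dT <- E * (-2 * params$eta_R * outer(dj, params$radial_shifts, "-") * fc + fcd)
      w <- t(vapply(spec_idx[nb], function(a)
        gbar[i, (a - 1L) * nm_r + seq_len(nm_r)], numeric(nm_r)))
      coef <- rowSums(w * dT)                       # d(out)/d(dj)
      u <- (coords[nb, , drop = FALSE] -
              matrix(coords[i, ], length(nb), 3, byrow = TRUE)) / dj
      contrib <- coef * u
      grad[nb, ] <- grad[nb, ] + contrib
      grad[i, ] <- grad[i, ] - colSums(contrib)
    }
    # angular chain rule
    nba <- which(di <= params$Rc_angular & seq_len(n) != i)
    if (length(nba) >= 2L) {
      pr <- utils::combn(nba, 2L)
      j <- pr[1L, ]
      k <- pr[2L, ]
      P <- length(j)
      vj <- coords[j, , drop = FALSE] - matrix(coords[i, ], P, 3, byrow = TRUE)
      vk <- coords[k, , drop = FALSE] - matrix(coords[i, ], P, 3, byrow = TRUE)
      dj <- di[j]
      dk <- di[k]
      cosq <- pmin(1, pmax(-1, rowSums(vj * vk) / (dj * dk)))
      sinq <- sqrt(pmax(0, 1 - cosq^2))
      if (any(sin_th != 0) && any(sinq < 1e-12))
        stop("collinear neighbour pair: angular gradient undefined for ",
             "theta shifts with sin(theta_s) != 0")
      davg <- (dj + dk) / 2
      fcj <- cutoff_fn(dj, params$Rc_angular)
      fck <- cutoff_fn(dk, params$Rc_angular)
      fcdj <- .cutoff_fn_d(dj, params$Rc_angular)
      fcdk <- .cutoff_fn_d(dk, params$Rc_angular)
      # P x nm_a pieces
      cos_shift <- outer(cosq, cos_th) + outer(sinq, sin_th)  # cos(theta - theta_s)
      Apow <- (1 + cos_shift)^(zeta - 1)
      E <- exp(-params$eta_A * (outer(davg, rs_m, "-"))^2)
      pref <- 2^(1 - zeta)
      # q = d cos(theta - theta_s) / d cos(theta)
      q <- matrix(cos_th, P, nm_a, byrow = TRUE)
      if (any(sin_th != 0))
        q <- q + outer(cosq / pmax(sinq, 1e-300), sin_th) * -1
      dT_dc <- pref * zeta * Apow * q * E * (fcj * fck)
      A <- Apow * (1 + cos_shift)
      dEdd <- -params$eta_A * (outer(davg, rs_m, "-")) * E
      dT_ddj <- pref * A * (dEdd * (fcj * fck) + E * (fcdj * fck))
      dT_ddk <- pref * A * (dEdd * (fcj * fck) + E * (fcj * fcdk))
      # gather gbar weights for each pair's species-pair block
      pidx <- ptab[cbind(spec_idx[j], spec_idx[k])]
      w <- t(vapply(pidx, function(p)
        gbar[i, nrad + (p - 1L) * nm_a + seq_len(nm_a)], numeric(nm_a)))
      cC <- rowSums(w * dT_dc)
      cJ <- rowSums(w * dT_ddj)
      cK <- rowSums(w * dT_ddk)
      uj <- vj / dj
      uk <- vk / dk
      dc_dj <- vk / (dj * dk) - cosq * vj / dj^2
      dc_dk <- vj / (dj * dk) - cosq * vk / dk^2
      gj <- cJ * uj + cC * dc_dj
      gk <- cK * uk + cC * dc_dk
      # scatter-add kept as an explicit loop: pairs repeat atoms
      for (p in seq_len(P)) {
        grad[j[p], ] <- grad[j[p], ] + gj[p, ]
        grad[k[p], ] <- grad[k[p], ] + gk[p, ]
        grad[i, ] <- grad[i, ] - gj[p, ] - gk[p, ]
      }
    }
  }
  grad
}

#' Gradient of the predicted affinity w.r.t. atomic coordinates
#'
#' End-to-end analytic differentiation: reverse-mode through the atomic
#' networks, closed-form chain rule through the symmetry functions. The
#' result (pK/Angstrom) indicates where the model "wants" atoms to move to
#' improve the predicted affinity; its per-atom sum vanishes under global
#' translation because the features are translation invariant.
#'
#' @param model an `aev_model` (a single ensemble member for ensembles).
#' @param system an [atomic_system()].
#' @return N x 3 matrix of gradients, pK/Angstrom.
#' @export
coordinate_gradients <- function(model, system) {
  stopifnot(inherits(model, "aev_model"), inherits(system, "atomic_system"))
  aevs <- compute_aevs(system, model$params)
  gbar <- .input_gradient(model, aevs, attr(aevs, "species_index"))
  .aev_coord_grad(system$coords, attr(aevs, "species_index"), model$params,
                  gbar)
}

#' Per-atom contributions to the predicted affinity
#'
#' One forward pass; the contributions sum exactly to the prediction.
#'
#' @param model an `aev_model` or `aev_ensemble`.
#' @param system an [atomic_system()].
#' @return numeric vector, pK units, one entry per atom.
#' @export
atomic_contributions <- function(model, system) {
  predict_system(model, system)$atomic_contributions
}

#' Full attribution of a prediction
#'
#' @param model an `aev_model`.
#' @param system an [atomic_system()].
#' @return list of class `attribution_result` with `grad` (N x 3,
#'   pK/Angstrom), `grad_norm` (per-atom magnitude), `contributions`
#'   (per-atom pK) and `pk`.
#' @export
attribute_prediction <- function(model, system) {
  pred <- predict_system(model, system)
  g <- coordinate_gradients(model, system)
  structure(list(grad = g, grad_norm = sqrt(rowSums(g^2)),
                 contributions = pred$atomic_contributions, pk = pred$pk),
            class = "attribution_result")
}

#' Write per-atom values into the B-factor column of a PDB file
#'
#' Visualization-oriented export: ligand atoms become HETATM records,
#' binding-site atoms ATOM records, with `values` (e.g. contributions or
#' gradient norms) in the B-factor field.
#'
#' @param system an [atomic_system()].
#' @param values numeric per-atom values.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_pdb_bfactors <- function(system, values, path) {
  stopifnot(inherits(system, "atomic_system"),
            length(values) == nrow(system$coords))
  lines <- vapply(seq_len(nrow(system$coords)), function(i) {
    rec <- if (system$ligand_mask[i]) "HETATM" else "ATOM  "
    res <- if (system$ligand_mask[i]) "LIG" else "ENV"
    el <- toupper(system$elements[i])
    sprintf("%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, i, substr(paste0(el, i), 1, 4), "", res, "A",
            if (system$ligand_mask[i]) 1L else i, "",
            system$coords[i, 1], system$coords[i, 2], system$coords[i, 3],
            1.00, values[i], substr(el, 1, 2))
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Experimental: gradient-ascent pose refinement
#'
#' Moves ligand atoms along the affinity gradient with a per-step
#' displacement cap. Exposed for exploration only; no convergence claims.
#'
#' @param model an `aev_model`.
#' @param system an [atomic_system()].
#' @param steps iterations.
#' @param step_size gradient multiplier, Angstrom per (pK/Angstrom).
#' @param max_step per-atom displacement cap per iteration, Angstrom.
#' @return list with the refined `system` and the `pk` trajectory.
#' @export
optimize_pose <- function(model, system, steps = 20, step_size = 0.01,
                          max_step = 0.1) {
  traj <- numeric(steps + 1)
  traj[1] <- predict_system(model, system)$pk
  for (s in seq_len(steps)) {
    g <- coordinate_gradients(model, system)
    g[!system$ligand_mask, ] <- 0
    disp <- step_size * g
    nrm <- sqrt(rowSums(disp^2))
    too_big <- nrm > max_step
    disp[too_big, ] <- disp[too_big, ] * (max_step / nrm[too_big])
    system$coords <- system$coords + disp
    traj[s + 1] <- predict_system(model, system)$pk
  }
  list(system = system, pk = traj)
}
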