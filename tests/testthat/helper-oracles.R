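# Shared fixtures and independent oracles.
#
# oracle_aev() re-derives every AEV entry with naive loops straight from the
# printed radial/angular formulas; it shares no code with compute_aevs() and
# is the reference the vectorized featurizer is checked against.

oracle_aev <- function(sys, p) {
  n <- nrow(sys$coords)
  sp <- match(sys$elements, p$species)
  ns <- length(p$species)
  nmr <- length(p$radial_shifts)
  th <- p$theta_shifts
  rs <- p$angular_radial_shifts
  nma <- length(th) * length(rs)
  # lexicographic unordered species-pair index
  pair_idx <- function(a, b) {
    lo <- min(a, b)
    hi <- max(a, b)
    sum(ns - seq_len(lo - 1) + 1) + (hi - lo + 1)
  }
  fc <- function(r, Rc) if (r <= Rc) 0.5 * (cos(pi * r / Rc) + 1) else 0
  out <- matrix(0, n, aev_length(p))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (j != i) {
      rij <- sqrt(sum((sys$coords[j, ] - sys$coords[i, ])^2))
      for (m in seq_len(nmr)) {
        col <- (sp[j] - 1) * nmr + m
        out[i, col] <- out[i, col] +
          exp(-p$eta_R * (rij - p$radial_shifts[m])^2) * fc(rij, p$Rc_radial)
      }
    }
    for (j in seq_len(n)) for (k in seq_len(n))
      if (j < k && j != i && k != i) {
        vj <- sys$coords[j, ] - sys$coords[i, ]
        vk <- sys$coords[k, ] - sys$coords[i, ]
        rij <- sqrt(sum(vj^2))
        rik <- sqrt(sum(vk^2))
        theta <- acos(max(-1, min(1, sum(vj * vk) / (rij * rik))))
        m <- 0
        for (t in th) for (r in rs) {
          m <- m + 1
          col <- ns * nmr + (pair_idx(sp[j], sp[k]) - 1) * nma + m
          out[i, col] <- out[i, col] +
            2^(1 - p$zeta) * (1 + cos(theta - t))^p$zeta *
            exp(-p$eta_A * ((rij + rik) / 2 - r)^2) *
            fc(rij, p$Rc_angular) * fc(rik, p$Rc_angular)
        }
      }
  }
  out
}

# random atomic system; coordinates spread over `spread` Angstrom
random_system <- function(n, species = c("C", "N", "O"), seed = 1,
                          spread = 5) {
  withr::with_seed(seed, atomic_system(
    elements = sample(species, n, replace = TRUE),
    coords = matrix(stats::runif(n * 3, 0, spread), n, 3),
    ligand_mask = c(TRUE, rep(FALSE, n - 1))))
}

rand_rotation <- function(seed) {
  withr::with_seed(seed, {
    axis <- stats::rnorm(3)
    angle <- stats::runif(1, 0, 2 * pi)
  })
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rigid_transform <- function(sys, R, t) {
  sys$coords <- sys$coords %*% t(R) +
    matrix(t, nrow(sys$coords), 3, byrow = TRUE)
  sys
}

# small shared parameter set (3 species keeps tests fast)
test_params <- function() aev_params(species = c("C", "N", "O"))

# tiny network spec for fast model tests
tiny_spec <- function(p, hidden = c(16, 8), dropout_p = 0.25)
  network_spec(aev_length(p), length(p$species), hidden_sizes = hidden,
               dropout_p = dropout_p)

# featurized records for a quick synthetic dataset
quick_records <- function(n, seed = 7, params = test_params()) {
  map <- species_map(canonical_species = params$species)
  cfg <- synthetic_config(seed = seed)
  ds <- make_dataset(cfg, n, params, d = 3.5, map = map)
  recs <- lapply(seq_along(ds$systems), function(i) {
    aevs <- compute_aevs(ds$systems[[i]], params)
    list(aevs = aevs, species = attr(aevs, "species_index"),
         y = ds$labels$pk_exp[i])
  })
  list(recs = recs, ds = ds, map = map)
}
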