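#' Symmetry-function hyperparameters for atomic environment vectors
#'
#' Bundles every hyperparameter of the radial and angular atom-centred
#' symmetry functions (ACSFs) together with the ordered species list, which
#' jointly fix the length and column layout of the atomic environment vector
#' (AEV). Defaults follow the ANI-1x parameter set for the radial part
#' (cutoff 5.2 A, 16 evenly spaced shifts starting at 0.9 A, eta_R = 16) and
#' the restricted Behler-Parrinello angular grid (theta shifts \{0, pi\},
#' single angular radial shift at 0 A, eta_A = 8, zeta = 32, cutoff 3.5 A).
#'
#' @param species character vector of species labels, ordered; the order
#'   fixes the AEV block layout and must match the networks trained on it.
#' @param Rc_radial radial cutoff, Angstrom.
#' @param eta_R width of the radial Gaussians, 1/A^2.
#' @param radial_shifts ordered vector of radial shifts R_s, Angstrom.
#' @param Rc_angular angular cutoff, Angstrom.
#' @param eta_A width of the angular-term distance Gaussian, 1/A^2.
#' @param angular_radial_shifts ordered vector of R_s values for the angular
#'   terms, Angstrom.
#' @param theta_shifts ordered vector of angular shifts theta_s, radians.
#' @param zeta sharpness exponent of the angular peaks (dimensionless).
#' @return an object of class `aev_params`.
#' @export
aev_params <- function(species,
                       Rc_radial = 5.2,
                       eta_R = 16,
                       radial_shifts = 0.9 + (0:15) * (5.2 - 0.9) / 16,
                       Rc_angular = 3.5,
                       eta_A = 8,
                       angular_radial_shifts = 0,
                       theta_shifts = c(0, pi),
                       zeta = 32) {
  species <- as.character(species)
  stopifnot(length(species) >= 1)
  if (anyDuplicated(species))
    stop("duplicated species labels: ", paste(unique(species[duplicated(species)]), collapse = ", "))
  if (!(Rc_radial > 0 && Rc_angular > 0)) stop("cutoffs must be positive")
  if (length(radial_shifts) < 1 || length(angular_radial_shifts) < 1 ||
      length(theta_shifts) < 1) stop("shift lists must be non-empty")
  if (!(zeta > 0)) stop("zeta must be positive")
  structure(
    list(species = species,
         Rc_radial = Rc_radial, eta_R = eta_R,
         radial_shifts = as.numeric(radial_shifts),
         Rc_angular = Rc_angular, eta_A = eta_A,
         angular_radial_shifts = as.numeric(angular_radial_shifts),
         theta_shifts = as.numeric(theta_shifts), zeta = zeta),
    class = "aev_params")
}

#' @export
print.aev_params <- function(x, ...) {
  cat("AEV parameters\n")
  cat("  species          :", paste(x$species, collapse = " "), "\n")
  cat("  radial  : Rc =", x$Rc_radial, "A, eta_R =", x$eta_R, ",",
      length(x$radial_shifts), "shifts\n")
  cat("  angular : Rc =", x$Rc_angular, "A, eta_A =", x$eta_A,
      ", zeta =", x$zeta, ",", length(x$theta_shifts), "theta shifts,",
      length(x$angular_radial_shifts), "radial shifts\n")
  cat("  AEV length       :", aev_length(x), "\n")
  invisible(x)
}

#' Length of the per-atom feature vector
#'
#' `n_s * |radial_shifts| + n_s (n_s + 1) / 2 * |theta_shifts| *
#' |angular_radial_shifts|` where `n_s` is the number of species: one radial
#' block per species and one angular block per unordered species pair.
#'
#' @param params an [aev_params()] object.
#' @return integer feature-vector length.
#' @export
aev_length <- function(params) {
  stopifnot(inherits(params, "aev_params"))
  ns <- length(params$species)
  ns * length(params$radial_shifts) +
    ns * (ns + 1L) / 2L * length(params$theta_shifts) *
      length(params$angular_radial_shifts)
}

#' Smooth cosine cutoff function
#'
#' `0.5 * (cos(pi * Rij / Rc) + 1)` for `Rij <= Rc`, 0 beyond; continuous at
#' the cutoff and valued in \[0, 1\]. Ensures locality of every symmetry
#' function.
#'
#' @param Rij distance(s), Angstrom; must be non-negative.
#' @param Rc cutoff radius, Angstrom.
#' @return dimensionless value(s) in \[0, 1\].
#' @export
cutoff_fn <- function(Rij, Rc) {
  stopifnot(Rc > 0)
  if (any(Rij < 0)) stop("negative interatomic distance")
  ifelse(Rij <= Rc, 0.5 * (cos(pi * Rij / Rc) + 1), 0)
}

# derivative of the cutoff w.r.t. distance (0 beyond the cutoff)
.cutoff_fn_d <- function(Rij, Rc) {
  ifelse(Rij <= Rc, -0.5 * pi / Rc * sin(pi * Rij / Rc), 0)
}

# lookup table: unordered species pair (a, b) -> block index, lexicographic
# over a <= b
.pair_table <- function(ns) {
  m <- matrix(0L, ns, ns)
  k <- 0L
  for (a in seq_len(ns)) for (b in a:ns) {
    k <- k + 1L
    m[a, b] <- k
    m[b, a] <- k
  }
  m
}

# map element labels to species indices, erroring on unknowns
.species_index <- function(elements, species) {
  idx <- match(elements, species)
  if (anyNA(idx))
    stop("species not in parameter set: ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  idx
}

#' Radial symmetry-function terms for one atom
#'
#' Entry (alpha, m) is `sum_{j != i, j in alpha} exp(-eta_R (Rij - Rs_m)^2) *
#' fc(Rij)` with the radial cutoff. Blocks are species-major, shifts within.
#'
#' @param system an [atomic_system()].
#' @param i atom index (1-based).
#' @param params an [aev_params()] object.
#' @return numeric vector of length `|species| * |radial_shifts|`.
#' @export
radial_terms <- function(system, i, params) {
  stopifnot(inherits(system, "atomic_system"), inherits(params, "aev_params"))
  n <- nrow(system$coords)
  stopifnot(i >= 1, i <= n)
  spec_idx <- .species_index(system$elements, params$species)
  d <- sqrt(colSums((t(system$coords) - system$coords[i, ])^2))
  .radial_row(d, spec_idx, i, params)
}

.radial_row <- function(d, spec_idx, i, params) {
  ns <- length(params$species)
  shifts <- params$radial_shifts
  nm <- length(shifts)
  out <- numeric(ns * nm)
  nb <- which(d <= params$Rc_radial & seq_along(d) != i)
  if (length(nb) == 0L) return(out)
  dj <- d[nb]
  # |nb| x nm matrix of Gaussian * cutoff terms
  terms <- exp(-params$eta_R * (outer(dj, shifts, "-"))^2) *
    cutoff_fn(dj, params$Rc_radial)
  grp <- spec_idx[nb]
  for (a in unique(grp)) {
    cols <- (a - 1L) * nm + seq_len(nm)
    out[cols] <- colSums(terms[grp == a, , drop = FALSE])
  }
  out
}

#' Angular symmetry-function terms for one atom
#'
#' Entry (\{alpha, beta\}, theta_s, Rs) is `2^(1-zeta) * sum_{(j,k)} (1 +
#' cos(theta_ijk - theta_s))^zeta * exp(-eta_A ((Rij + Rik)/2 - Rs)^2) *
#' fc(Rij) fc(Rik)` with the angular cutoff, where `theta_ijk` is the angle
#' at vertex `i` and the sum runs over unordered neighbour pairs, each
#' counted once. Blocks are ordered lexicographically over species pairs
#' (alpha <= beta); within a block theta_s varies slowest, then Rs.
#'
#' @inheritParams radial_terms
#' @return numeric vector of length
#'   `|species pairs| * |theta_shifts| * |angular_radial_shifts|`.
#' @export
angular_terms <- function(system, i, params) {
  stopifnot(inherits(system, "atomic_system"), inherits(params, "aev_params"))
  n <- nrow(system$coords)
  stopifnot(i >= 1, i <= n)
  spec_idx <- .species_index(system$elements, params$species)
  d <- sqrt(colSums((t(system$coords) - system$coords[i, ])^2))
  if (any(d[-i] == 0))
    stop("coincident atoms: angle at atom ", i, " undefined")
  .angular_row(system$coords, d, spec_idx, i, params, .pair_table(length(params$species)))
}

.angular_row <- function(coords, d, spec_idx, i, params, ptab) {
  ns <- length(params$species)
  th <- params$theta_shifts
  rs <- params$angular_radial_shifts
  nth <- length(th)
  nrs <- length(rs)
  nm <- nth * nrs
  npair <- ns * (ns + 1L) / 2L
  out <- numeric(npair * nm)
  nb <- which(d <= params$Rc_angular & seq_along(d) != i)
  if (length(nb) < 2L) return(out)
  pr <- utils::combn(nb, 2L)
  j <- pr[1L, ]
  k <- pr[2L, ]
  vj <- coords[j, , drop = FALSE] - matrix(coords[i, ], length(j), 3, byrow = TRUE)
  vk <- coords[k, , drop = FALSE] - matrix(coords[i, ], length(k), 3, byrow = TRUE)
  dj <- d[j]
  dk <- d[k]
  cosq <- pmin(1, pmax(-1, rowSums(vj * vk) / (dj * dk)))
  theta <- acos(cosq)
  davg <- (dj + dk) / 2
  fcf <- cutoff_fn(dj, params$Rc_angular) * cutoff_fn(dk, params$Rc_angular)
  # theta_s-major then Rs within a species-pair block
  ang <- (1 + cos(outer(theta, th, "-")))^params$zeta          # P x nth
  rad <- exp(-params$eta_A * (outer(davg, rs, "-"))^2)          # P x nrs
  terms <- 2^(1 - params$zeta) *
    ang[, rep(seq_len(nth), each = nrs), drop = FALSE] *
    rad[, rep(seq_len(nrs), times = nth), drop = FALSE] * fcf   # P x nm
  grp <- ptab[cbind(spec_idx[j], spec_idx[k])]
  for (p in unique(grp)) {
    cols <- (p - 1L) * nm + seq_len(nm)
    out[cols] <- colSums(terms[grp == p, , drop = FALSE])
  }
  out
}

#' Compute atomic environment vectors for every atom of a system
#'
#' Row `i` of the result is the concatenation of the radial blocks (one per
#' species) followed by the angular blocks (one per unordered species pair)
#' for atom `i`. The result depends only on interatomic distances, included
#' angles and species, and is therefore invariant under rigid transforms,
#' reflections and same-species permutations.
#'
#' @param system an [atomic_system()].
#' @param params an [aev_params()] object; every element of the system must
#'   appear in `params$species`.
#' @return an `aev_matrix`: numeric N x L matrix with attributes
#'   `species_index` (per-row species index into `params$species`) and
#'   `params`.
#' @export
compute_aevs <- function(system, params) {
  stopifnot(inherits(system, "atomic_system"), inherits(params, "aev_params"))
  coords <- system$coords
  n <- nrow(coords)
  spec_idx <- .species_index(system$elements, params$species)
  dm <- as.matrix(stats::dist(coords))
  if (n > 1 && min(dm[upper.tri(dm)]) == 0)
    stop("coincident atoms in system: angular terms undefined")
  ptab <- .pair_table(length(params$species))
  L <- aev_length(params)
  nrad <- length(params$species) * length(params$radial_shifts)
  out <- matrix(0, n, L)
  for (i in seq_len(n)) {
    out[i, seq_len(nrad)] <- .radial_row(dm[i, ], spec_idx, i, params)
    out[i, (nrad + 1L):L] <- .angular_row(coords, dm[i, ], spec_idx, i, params, ptab)
  }
  structure(out, species_index = spec_idx, params = params,
            class = c("aev_matrix", "matrix", "array"))
}

#' Column labels for the AEV layout
#'
#' Human-readable labels documenting the frozen block order, e.g.
#' `"R|C|Rs=0.9"` or `"A|C-O|th=0|Rs=0"`.
#'
#' @param params an [aev_params()] object.
#' @return character vector of length [aev_length()].
#' @export
aev_layout <- function(params) {
  stopifnot(inherits(params, "aev_params"))
  sp <- params$species
  rad <- as.vector(t(outer(sp, params$radial_shifts,
                           function(a, r) sprintf("R|%s|Rs=%g", a, r))))
  ang <- character(0)
  for (a in seq_along(sp)) for (b in a:length(sp))
    for (t in params$theta_shifts) for (r in params$angular_radial_shifts)
      ang <- c(ang, sprintf("A|%s-%s|th=%g|Rs=%g", sp[a], sp[b], t, r))
  c(rad, ang)
}

#' Serialize AEV parameters to JSON
#'
#' The layout (species order, shifts, exponents) determines the meaning of
#' every trained weight, so parameters are stored alongside checkpoints.
#'
#' @param params an [aev_params()] object.
#' @param path file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_aev_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "aev_params"))
  js <- jsonlite::toJSON(unclass(params), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read AEV parameters from JSON
#' @param path file written by [write_aev_params()].
#' @return an [aev_params()] object.
#' @export
read_aev_params <- function(path) {
  x <- jsonlite::fromJSON(path)
  aev_params(species = x$species, Rc_radial = x$Rc_radial, eta_R = x$eta_R,
             radial_shifts = x$radial_shifts, Rc_angular = x$Rc_angular,
             eta_A = x$eta_A, angular_radial_shifts = x$angular_radial_shifts,
             theta_shifts = x$theta_shifts, zeta = x$zeta)
}
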