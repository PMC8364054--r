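# Structure input and binding-site assembly.
#
# Parsing deliberately trusts explicit element fields only: the PDB element
# column (77-78), the SDF V2000 atom-block element, the MOL2 SYBYL atom type.
# Atom-name heuristics are never used; connectivity and bond orders are
# ignored because the model needs only elements and coordinates.

# elements with their own atomic network when present in the canonical list
.ORGANIC_ELEMENTS <- c("H", "C", "O", "N", "S", "P", "F", "Cl", "Br", "I")

#' Canonical species mapping policy
#'
#' Defines the canonical species list (which fixes the number of atomic
#' networks and the AEV block order), how metal centres are treated, and
#' whether hydrogens are kept. Any element outside the ten organic elements
#' H, C, O, N, S, P, F, Cl, Br, I is a metal for policy purposes; metals are
#' either discarded or mapped onto a single dummy species `"X"`.
#' Selenium-containing structures are rejected outright.
#'
#' @param canonical_species ordered species labels; defines the feature
#'   layout. Defaults to the ten organic elements (plus `"X"` when
#'   `metal_policy = "map_to_dummy"`).
#' @param metal_policy `"discard"` or `"map_to_dummy"`.
#' @param keep_hydrogens keep hydrogen atoms? When `FALSE` hydrogens are
#'   stripped from both protein and ligand before the distance selection.
#' @param dummy_label label used for mapped metals.
#' @return an object of class `species_map`.
#' @export
species_map <- function(canonical_species = NULL,
                        metal_policy = c("discard", "map_to_dummy"),
                        keep_hydrogens = TRUE,
                        dummy_label = "X") {
  metal_policy <- match.arg(metal_policy)
  if (is.null(canonical_species)) {
    canonical_species <- .ORGANIC_ELEMENTS
    if (!keep_hydrogens) canonical_species <- setdiff(canonical_species, "H")
    if (metal_policy == "map_to_dummy")
      canonical_species <- c(canonical_species, dummy_label)
  }
  canonical_species <- as.character(canonical_species)
  if (anyDuplicated(canonical_species)) stop("duplicate canonical species")
  has_dummy <- dummy_label %in% canonical_species
  if (metal_policy == "map_to_dummy" && !has_dummy)
    stop("metal_policy 'map_to_dummy' requires the dummy label '",
         dummy_label, "' in canonical_species")
  if (metal_policy == "discard" && has_dummy)
    stop("dummy label present but metal_policy is 'discard'")
  structure(list(canonical_species = canonical_species,
                 dummy_label = dummy_label,
                 metal_policy = metal_policy,
                 keep_hydrogens = keep_hydrogens),
            class = "species_map")
}

#' Atomic system: the featurization input
#'
#' Elements (already mapped through a [species_map()]), Cartesian coordinates
#' in Angstrom and a per-atom ligand flag.
#'
#' @param elements character vector of species labels, length N.
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param ligand_mask logical vector, length N; at least one `TRUE`.
#' @return an object of class `atomic_system`.
#' @export
atomic_system <- function(elements, coords, ligand_mask) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must be N x 3")
  n <- nrow(coords)
  if (length(elements) != n || length(ligand_mask) != n)
    stop("elements, coords and ligand_mask must agree in length")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (any(!nzchar(elements))) stop("empty element symbol")
  if (!any(ligand_mask)) stop("system must contain at least one ligand atom")
  structure(list(elements = as.character(elements), coords = coords,
                 ligand_mask = as.logical(ligand_mask)),
            class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  cat("atomic_system:", nrow(x$coords), "atoms (",
      sum(x$ligand_mask), "ligand /", sum(!x$ligand_mask), "environment )\n")
  cat("  species:", paste(sort(unique(x$elements)), collapse = " "), "\n")
  invisible(x)
}

.normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
}

.WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "TIP4", "SPC")

# parse ATOM/HETATM records of a PDB file into a data.frame
.read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  el <- .normalize_element(substring(lines, 77, 78))
  if (any(!nzchar(el)))
    stop("missing element column (77-78) in ", path,
         " for ", sum(!nzchar(el)), " atom record(s); file rejected")
  resname <- trimws(substring(lines, 18, 20))
  data.frame(
    record = trimws(substring(lines, 1, 6)),
    name = trimws(substring(lines, 13, 16)),
    resname = resname,
    chain = substring(lines, 22, 22),
    resseq = trimws(substring(lines, 23, 26)),
    icode = substring(lines, 27, 27),
    x = as.numeric(substring(lines, 31, 38)),
    y = as.numeric(substring(lines, 39, 46)),
    z = as.numeric(substring(lines, 47, 54)),
    element = el,
    stringsAsFactors = FALSE)
}

# SDF / MOL V2000 atom block
.read_sdf_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("truncated SDF file: ", path)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substring(counts, 1, 3)))
  if (is.na(natoms)) stop("unparseable SDF counts line in ", path)
  if (natoms < 1L) stop("empty ligand in ", path)
  block <- lines[5:(4 + natoms)]
  x <- suppressWarnings(as.numeric(substring(block, 1, 10)))
  y <- suppressWarnings(as.numeric(substring(block, 11, 20)))
  z <- suppressWarnings(as.numeric(substring(block, 21, 30)))
  el <- .normalize_element(substring(block, 32, 34))
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(el)))
    stop("unparseable atom block (element field required) in ", path)
  data.frame(x = x, y = y, z = z, element = el, stringsAsFactors = FALSE)
}

# MOL2: element taken from the SYBYL atom type before any dot
.read_mol2_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^@<TRIPOS>ATOM", lines)
  if (length(start) == 0L) stop("no @<TRIPOS>ATOM section in ", path)
  start <- start[1] + 1L
  ends <- grep("^@<TRIPOS>", lines)
  end <- ends[ends >= start]
  end <- if (length(end)) end[1] - 1L else length(lines)
  block <- lines[start:end]
  block <- block[nzchar(trimws(block))]
  if (length(block) == 0L) stop("empty ligand in ", path)
  fields <- strsplit(trimws(block), "\\s+")
  bad <- vapply(fields, length, 1L) < 6L
  if (any(bad)) stop("unparseable MOL2 atom line(s) in ", path)
  el <- .normalize_element(vapply(fields, function(f) sub("\\..*$", "", f[6]), ""))
  data.frame(
    x = as.numeric(vapply(fields, `[`, "", 3L)),
    y = as.numeric(vapply(fields, `[`, "", 4L)),
    z = as.numeric(vapply(fields, `[`, "", 5L)),
    element = el, stringsAsFactors = FALSE)
}

#' Protein-ligand complex
#'
#' Container pairing protein atoms (with residue keys) and ligand atoms,
#' plus optional experimental affinity (pK units) and a baseline docking
#' score (kcal/mol) for delta-learning.
#'
#' @param protein_atoms data.frame with columns `element, x, y, z,
#'   residue_id` (and optionally `record`).
#' @param ligand_atoms data.frame with columns `element, x, y, z`.
#' @param id opaque identifier.
#' @param pk_exp experimental affinity, pK units, or `NA`.
#' @param baseline_score docking score, kcal/mol, or `NA`.
#' @return an object of class `pl_complex`.
#' @export
pl_complex <- function(protein_atoms, ligand_atoms, id = "complex",
                       pk_exp = NA_real_, baseline_score = NA_real_) {
  if (nrow(ligand_atoms) == 0L) stop("ligand must contain at least one atom")
  structure(list(protein_atoms = protein_atoms, ligand_atoms = ligand_atoms,
                 id = id, pk_exp = pk_exp, baseline_score = baseline_score),
            class = "pl_complex")
}

#' @export
print.pl_complex <- function(x, ...) {
  cat("pl_complex", x$id, ":", nrow(x$protein_atoms), "protein atoms,",
      nrow(x$ligand_atoms), "ligand atoms")
  if (!is.na(x$pk_exp)) cat(", pK =", x$pk_exp)
  cat("\n")
  invisible(x)
}

#' Load a protein-ligand complex from structure files
#'
#' Reads the protein from PDB (element column required) and the ligand from
#' SDF, MOL2 or PDB, removing all water molecules from the protein. Files
#' without explicit element information are rejected rather than guessed at.
#'
#' @param protein_path PDB file.
#' @param ligand_path SDF (`.sdf`/`.mol`), MOL2 (`.mol2`) or PDB file.
#' @param id identifier; defaults to the ligand file stem.
#' @param pk_exp optional experimental affinity, pK units.
#' @param baseline_score optional docking score, kcal/mol.
#' @return a [pl_complex()].
#' @export
load_complex <- function(protein_path, ligand_path, id = NULL,
                         pk_exp = NA_real_, baseline_score = NA_real_) {
  prot <- .read_pdb_atoms(protein_path)
  n_water <- sum(prot$resname %in% .WATER_RESNAMES)
  prot <- prot[!prot$resname %in% .WATER_RESNAMES, , drop = FALSE]
  if (n_water > 0)
    message("removed ", n_water, " water atom(s) from ", basename(protein_path))
  prot$residue_id <- paste(prot$chain, prot$resseq, prot$icode, prot$resname,
                           sep = "|")
  ext <- tolower(tools::file_ext(ligand_path))
  lig <- switch(ext,
                sdf = , mol = .read_sdf_atoms(ligand_path),
                mol2 = .read_mol2_atoms(ligand_path),
                pdb = {
                  df <- .read_pdb_atoms(ligand_path)
                  df <- df[!df$resname %in% .WATER_RESNAMES, , drop = FALSE]
                  df[, c("x", "y", "z", "element")]
                },
                stop("unsupported ligand format: ", ligand_path))
  if (nrow(lig) == 0L) stop("empty ligand in ", ligand_path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(ligand_path))
  pl_complex(protein_atoms = prot[, c("element", "x", "y", "z",
                                      "residue_id", "record")],
             ligand_atoms = lig[, c("x", "y", "z", "element")],
             id = id, pk_exp = pk_exp, baseline_score = baseline_score)
}

.is_metal <- function(element) !(element %in% .ORGANIC_ELEMENTS)

#' Assemble the binding-site atomic system
#'
#' Keeps every ligand atom and every protein residue having at least one
#' atom within Euclidean distance `d` of any ligand atom. Hydrogens are
#' stripped (from both sides, before the distance test) when the species map
#' says so; metal centres — any element outside the ten organic elements —
#' are discarded or mapped to the dummy species per policy, each metal
#' treated as its own residue for the distance test. `d = 0` yields a
#' ligand-only system. Retention is residue-atomic: a residue survives or
#' vanishes as a whole.
#'
#' @param complex a [pl_complex()].
#' @param d selection distance, Angstrom, `>= 0`.
#' @param map a [species_map()].
#' @return an [atomic_system()] with elements mapped through the species map.
#' @export
select_binding_site <- function(complex, d = 3.5, map = species_map()) {
  stopifnot(inherits(complex, "pl_complex"), inherits(map, "species_map"),
            d >= 0)
  prot <- complex$protein_atoms
  lig <- complex$ligand_atoms
  if (any(c(prot$element, lig$element) == "Se"))
    stop("selenium-containing complex rejected: ", complex$id)
  if (!map$keep_hydrogens) {
    prot <- prot[prot$element != "H", , drop = FALSE]
    lig <- lig[lig$element != "H", , drop = FALSE]
    if (nrow(lig) == 0L) stop("ligand has no heavy atoms: ", complex$id)
  }
  metal <- .is_metal(prot$element)
  if (map$metal_policy == "discard") {
    prot <- prot[!metal, , drop = FALSE]
  } else {
    prot$element[metal] <- map$dummy_label
    # a metal centre is its own residue for selection purposes
    prot$residue_id[metal] <- paste0("METAL|", seq_len(sum(metal)))
  }
  lig_metal <- .is_metal(lig$element)
  if (any(lig_metal)) {
    if (map$metal_policy == "discard") {
      lig <- lig[!lig_metal, , drop = FALSE]
      if (nrow(lig) == 0L) stop("ligand entirely metallic: ", complex$id)
    } else lig$element[lig_metal] <- map$dummy_label
  }
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  keep_res <- character(0)
  if (nrow(prot) > 0 && d > 0) {
    prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
    # min distance of each protein atom to the ligand
    d2 <- apply(prot_xyz, 1, function(p)
      min(colSums((t(lig_xyz) - p)^2)))
    mind <- tapply(sqrt(d2), prot$residue_id, min)
    keep_res <- names(mind)[mind <= d]
  }
  prot <- prot[prot$residue_id %in% keep_res, , drop = FALSE]
  elements <- c(lig$element, prot$element)
  unknown <- setdiff(unique(elements), map$canonical_species)
  if (length(unknown))
    stop("element(s) outside the canonical species list: ",
         paste(unknown, collapse = ", "))
  coords <- rbind(lig_xyz, if (nrow(prot)) as.matrix(prot[, c("x", "y", "z")]))
  atomic_system(elements = elements, coords = coords,
                ligand_mask = c(rep(TRUE, nrow(lig)), rep(FALSE, nrow(prot))))
}

#' Reproducible train/validation split
#'
#' Removes `exclude_ids`, then splits the remaining ids at `ratio` (train
#' fraction) under `seed`. The two partitions are disjoint and their union is
#' `ids` minus `exclude_ids`.
#'
#' @param ids character vector of unique identifiers.
#' @param ratio train fraction, in (0, 1); default 0.9.
#' @param exclude_ids ids removed before splitting (e.g. benchmark overlap).
#' @param seed integer seed.
#' @return list with components `train` and `val`.
#' @export
split_dataset <- function(ids, ratio = 0.9, exclude_ids = character(0),
                          seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  if (anyDuplicated(ids)) stop("ids must be unique")
  ids <- setdiff(ids, exclude_ids)
  n <- length(ids)
  if (n < 2L) stop("fewer than 2 ids remain after exclusion")
  perm <- withr::with_seed(seed, sample(ids))
  n_train <- min(max(round(ratio * n), 1L), n - 1L)
  list(train = perm[seq_len(n_train)], val = perm[(n_train + 1L):n])
}

#' Read a dataset manifest
#'
#' CSV with columns `id, protein_path, ligand_path, pk_exp, baseline_score`
#' (the last two optional). Relative paths are resolved against the manifest
#' directory.
#'
#' @param path manifest CSV.
#' @return data.frame with resolved paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "protein_path", "ligand_path")
  if (!all(req %in% names(m)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(m$id)) stop("duplicate ids in manifest")
  if (!"pk_exp" %in% names(m)) m$pk_exp <- NA_real_
  if (!"baseline_score" %in% names(m)) m$baseline_score <- NA_real_
  base <- dirname(path)
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$protein_path <- fix(m$protein_path)
  m$ligand_path <- fix(m$ligand_path)
  m
}

#' Load every complex of a manifest
#' @param manifest data.frame from [read_manifest()].
#' @return named list of [pl_complex()] objects.
#' @export
load_manifest_complexes <- function(manifest) {
  out <- lapply(seq_len(nrow(manifest)), function(i)
    load_complex(manifest$protein_path[i], manifest$ligand_path[i],
                 id = manifest$id[i], pk_exp = manifest$pk_exp[i],
                 baseline_score = manifest$baseline_score[i]))
  names(out) <- manifest$id
  out
}
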