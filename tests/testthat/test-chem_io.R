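make_test_complex <- function() {
  # two residues: one within 3.5 A of the ligand, one farther; plus a Zn
  prot <- data.frame(
    element = c("C", "N", "C", "O", "Zn"),
    x = c(3.0, 3.4, 5.0, 5.6, 2.5),
    y = c(0, 1.0, 0, 1.0, 2.5),
    z = 0,
    residue_id = c("A|1| |ALA", "A|1| |ALA", "A|2| |GLY", "A|2| |GLY",
                   "B|1| |ZN"),
    record = c(rep("ATOM", 4), "HETATM"))
  lig <- data.frame(x = c(0, 1.2), y = 0, z = 0, element = c("C", "O"))
  pl_complex(prot, lig, id = "tst")
}

test_that("fixture-written files round-trip through load_complex", {
  cfg <- synthetic_config(seed = 42L)
  cx <- make_complex(cfg, id = "rt")
  pp <- withr::local_tempfile(fileext = ".pdb")
  lp <- withr::local_tempfile(fileext = ".sdf")
  write_complex(cx, pp, lp)
  back <- load_complex(pp, lp)
  expect_s3_class(back, "pl_complex")
  expect_identical(nrow(back$protein_atoms), nrow(cx$protein_atoms))
  expect_identical(nrow(back$ligand_atoms), nrow(cx$ligand_atoms))
  expect_identical(back$ligand_atoms$element, cx$ligand_atoms$element)
  # PDB stores 3 decimals; SDF 4
  expect_equal(as.matrix(back$protein_atoms[, c("x", "y", "z")]),
               as.matrix(cx$protein_atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$ligand_atoms$x, cx$ligand_atoms$x, tolerance = 1e-3)
})

test_that("water molecules never survive loading", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A   2       1.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  O   WAT A   3       2.000   0.000   0.000  1.00  0.00           O",
    "END"), pdb)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("lig", "", "",
               "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    1.5000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "M  END", "$$$$"), sdf)
  cx <- suppressMessages(load_complex(pdb, sdf))
  expect_identical(nrow(cx$protein_atoms), 1L)
  expect_false(any(grepl("HOH|WAT", cx$protein_atoms$residue_id)))
})

test_that("PDB files without an element column are rejected by name", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
               "END"), pdb)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("lig", "", "",
               "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    1.5000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "M  END", "$$$$"), sdf)
  expect_error(load_complex(pdb, sdf), "element column.*\\.pdb")
})

test_that("binding-site selection honours the distance threshold residue-wise", {
  cx <- make_test_complex()
  map <- species_map(metal_policy = "discard")
  # residue 1 closest approach: atom (3.0,0,0) to ligand (1.2,0,0) = 1.8 A
  # residue 2 closest approach: (5.0,0,0) -> 3.8 A
  sys <- select_binding_site(cx, d = 2.0, map = map)
  expect_identical(sum(!sys$ligand_mask), 2L)
  sys <- select_binding_site(cx, d = 3.9, map = map)
  expect_identical(sum(!sys$ligand_mask), 4L)
  # threshold boundary: a residue at exactly d is kept
  sys <- select_binding_site(cx, d = 1.8, map = map)
  expect_identical(sum(!sys$ligand_mask), 2L)
  sys <- select_binding_site(cx, d = 1.79, map = map)
  expect_identical(sum(!sys$ligand_mask), 0L)
})

test_that("d = 0 yields exactly the ligand", {
  cx <- make_test_complex()
  sys <- select_binding_site(cx, d = 0, map = species_map())
  expect_identical(sys$elements, c("C", "O"))
  expect_true(all(sys$ligand_mask))
})

test_that("metal policy discards or maps to the dummy species", {
  cx <- make_test_complex()
  sys <- select_binding_site(cx, d = 5,
                             map = species_map(metal_policy = "discard"))
  expect_false("Zn" %in% sys$elements)
  expect_false("X" %in% sys$elements)
  sys <- select_binding_site(cx, d = 5,
                             map = species_map(metal_policy = "map_to_dummy"))
  expect_true("X" %in% sys$elements)
  expect_false("Zn" %in% sys$elements)
  # selenium is rejected outright
  cx$protein_atoms$element[1] <- "Se"
  expect_error(select_binding_site(cx, d = 5), "selenium|Se")
})

test_that("hydrogen policy strips both sides before the distance test", {
  prot <- data.frame(element = c("H", "C"), x = c(2.0, 6.0), y = 0, z = 0,
                     residue_id = c("A|1| |ALA", "A|1| |ALA"),
                     record = "ATOM")
  lig <- data.frame(x = c(0, 0.9), y = 0, z = 0, element = c("C", "H"))
  cx <- pl_complex(prot, lig, id = "h")
  sys_h <- select_binding_site(cx, d = 2.5, map = species_map())
  expect_identical(sort(sys_h$elements), c("C", "C", "H", "H"))
  # without hydrogens the residue's only close atom is gone -> residue drops
  sys_noh <- select_binding_site(cx, d = 2.5,
                                 map = species_map(keep_hydrogens = FALSE))
  expect_identical(sys_noh$elements, "C")
})

test_that("selection monotonicity and residue atomicity hold on random
           complexes", {
  for (seed in 1:5) {
    cx <- make_complex(synthetic_config(seed = seed), id = "m")
    map <- species_map(canonical_species = c("C", "N", "O"))
    sizes <- vapply(c(0, 2, 3.5, 5, 10), function(d)
      nrow(select_binding_site(cx, d = d, map = map)$coords), 0L)
    expect_true(all(diff(sizes) >= 0))
    # residue atomicity: retained protein atom count is a sum over residues
    sys <- select_binding_site(cx, d = 3.5, map = map)
    res_sizes <- table(cx$protein_atoms$residue_id)
    n_prot <- sum(!sys$ligand_mask)
    ok <- any(vapply(0:length(res_sizes), function(k) {
      combos <- utils::combn(length(res_sizes), k)
      any(apply(matrix(combos, nrow = max(k, 1)), 2, function(j)
        sum(res_sizes[j]) == n_prot))
    }, TRUE))
    expect_true(ok)
  }
})

test_that("split_dataset partitions deterministically and respects exclusion", {
  ids <- sprintf("id%03d", 1:100)
  sp <- split_dataset(ids, ratio = 0.9, seed = 4L)
  expect_identical(length(sp$train), 90L)
  expect_identical(length(sp$val), 10L)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)
  excl <- ids[1:10]
  sp2 <- split_dataset(ids, ratio = 0.9, exclude_ids = excl, seed = 4L)
  expect_identical(length(sp2$train), 81L)
  expect_identical(length(sp2$val), 9L)
  expect_length(intersect(c(sp2$train, sp2$val), excl), 0)
  sp3 <- split_dataset(ids, ratio = 0.9, exclude_ids = excl, seed = 4L)
  expect_identical(sp2, sp3)
  sp4 <- split_dataset(ids, ratio = 0.9, exclude_ids = excl, seed = 5L)
  expect_false(identical(sp2$train, sp4$train))
  expect_error(split_dataset(ids[1:2], exclude_ids = ids[1]), "fewer than 2")
})

test_that("manifest round-trip resolves relative paths", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(synthetic_config(seed = 3L), 3,
                     aev_params(species = c("C", "N", "O")),
                     map = species_map(canonical_species = c("C", "N", "O")))
  manifest <- write_dataset(ds, dir)
  m <- read_manifest(manifest)
  expect_identical(nrow(m), 3L)
  cxs <- load_manifest_complexes(m)
  expect_length(cxs, 3)
  expect_identical(names(cxs), m$id)
  expect_equal(cxs[[1]]$pk_exp, ds$labels$pk_exp[1], tolerance = 1e-6)
})
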