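test_that("scaling formulas match their closed forms", {
  expect_identical(scale_atomic_mass(10.812), 0)
  expect_identical(scale_vdw_radius(1.5), 0)
  expect_identical(scale_covalent_radius(0.64), 0)
  expect_equal(scale_atomic_mass(126.904), 1, tolerance = 1e-6)
  expect_lt(abs(scale_atomic_mass(12.011) - 0.0103280), 1e-6)
  expect_equal(scale_vdw_radius(2.1), 1, tolerance = 1e-6)
  expect_equal(scale_vdw_radius(1.2), -0.5, tolerance = 1e-6)
  expect_equal(scale_covalent_radius(1.40), 1, tolerance = 1e-6)
  expect_equal(scale_covalent_radius(0.76), 0.1578947, tolerance = 1e-6)
  # independent direct evaluation on random inputs
  set.seed(42)
  x <- runif(20, 0.1, 300)
  expect_equal(scale_atomic_mass(x), (x - 10.812) / 116.092,
               tolerance = 1e-12)
  expect_equal(scale_vdw_radius(x), (x - 1.5) / 0.6, tolerance = 1e-12)
  expect_equal(scale_covalent_radius(x), (x - 0.64) / 0.76,
               tolerance = 1e-12)
  expect_error(scale_atomic_mass(0), "positive")
  expect_error(scale_vdw_radius(-1), "positive")
  expect_error(scale_covalent_radius(0), "positive")
})

test_that("atom features match hand counts on small molecules", {
  etoh <- parse_smiles("CCO")
  af <- atom_features(etoh)
  expect_equal(ncol(af), 14L)
  expect_equal(names(af), feature_names("atomic"))
  o <- atom_features(etoh, 3L)
  expect_equal(o$num_hydrogens, 1)
  expect_equal(o$hydroxyl_group, 1)
  expect_equal(o$atomic_number, 8)
  expect_equal(af$hydroxyl_group, c(0, 0, 1))
  ch4 <- atom_features(parse_smiles("C"), 1L)
  expect_equal(ch4$atom_degree, 0)
  expect_equal(ch4$num_hydrogens, 4)
  expect_equal(ch4$atom_formal_charge, 0)
  expect_equal(ch4$electronegativity, 2.55)
  expect_equal(ch4$has_electronegativity, 1)
  expect_error(atom_features(etoh, 4L), "out of range")
})

test_that("molecular descriptors match hand counts", {
  benz <- molecular_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(ncol(benz), 15L)
  expect_equal(names(benz), feature_names("molecular"))
  expect_equal(benz$has_ring, 1)
  expect_equal(benz$num_rings, 1)
  expect_equal(benz$is_aromatic, 1)
  expect_equal(benz$num_atoms, 6)
  expect_equal(benz$fraction_sp2, 1)
  ch4 <- molecular_descriptors(parse_smiles("C"))
  expect_equal(ch4$has_ring, 0)
  expect_equal(ch4$num_rings, 0)
  expect_equal(ch4$num_rotatable_bonds, 0)
  expect_equal(ch4$num_atoms, 1)
  expect_equal(ch4$min_degree, 0)
  etoh <- molecular_descriptors(parse_smiles("CCO"))
  expect_gte(etoh$num_hbond_donors, 1)
  expect_gte(etoh$hba, 1)
})

test_that("homonuclear heavy-atom molecules average to the element's
           electronegativity", {
  expect_identical(molecular_descriptors(
    parse_smiles("CCCC"))$general_electronegativity, 2.55)
  expect_identical(molecular_descriptors(
    parse_smiles("c1ccccc1"))$general_electronegativity, 2.55)
})

test_that("geometry descriptors behave on degenerate and extended shapes", {
  w <- geometry_descriptors(parse_smiles("O", gen3d = TRUE, seed = 3))
  expect_equal(ncol(w), 6L)
  expect_identical(w$width, 0)
  expect_identical(w$length, 0)
  expect_identical(w$height, 0)
  expect_identical(w$orientation_angle, 0)
  expect_gt(w$volume, 0)
  oct <- geometry_descriptors(parse_smiles("CCCCCCCC", gen3d = TRUE,
                                           seed = 3))
  expect_gt(oct$length, oct$width)
  expect_gt(oct$length, oct$height)
  expect_gte(oct$width, oct$height)
  expect_true(oct$orientation_angle >= 0 && oct$orientation_angle <= pi)
})

test_that("geometry requires a conformer and reports failures as typed", {
  expect_error(geometry_descriptors(parse_smiles("CCO")),
               class = "molgat_geometry_failure")
  broken <- parse_smiles("CCO", gen3d = TRUE)
  broken$geometry <- NULL
  broken$geometry_error <- "conformer embedding failed"
  expect_error(geometry_descriptors(broken),
               class = "molgat_geometry_failure")
  expect_error(node_feature_matrix(broken), "geometry")
})

test_that("node feature matrix is N x 35 with constant global block", {
  mol <- parse_smiles("CCO", gen3d = TRUE, seed = 5)
  m <- node_feature_matrix(mol)
  expect_equal(dim(m), c(3L, 35L))
  expect_equal(colnames(m), feature_names())
  expect_equal(length(feature_names("atomic")), 14L)
  expect_equal(length(feature_names("molecular")), 15L)
  expect_equal(length(feature_names("geometry")), 6L)
  glob <- m[, 15:35]
  for (j in seq_len(ncol(glob))) {
    expect_equal(glob[, j], rep(glob[1, j], 3), tolerance = 0,
                 ignore_attr = TRUE)
  }
})

test_that("featurization is deterministic for a fixed seed", {
  m1 <- node_feature_matrix(parse_smiles("CC(C)O", gen3d = TRUE, seed = 9))
  m2 <- node_feature_matrix(parse_smiles("CC(C)O", gen3d = TRUE, seed = 9))
  expect_identical(m1, m2)
})

test_that("featurize_graphs drops bad rows with a report", {
  data <- tibble::tibble(smiles = c("CCO", "not_a_smiles", "CC"),
                         target = c(1, 2, 3))
  expect_warning(out <- featurize_graphs(data, seed = 2), "dropped")
  expect_equal(nrow(out), 2L)
  expect_equal(out$smiles, c("CCO", "CC"))
  dropped <- attr(out, "dropped")
  expect_equal(dropped$row, 2L)
  expect_equal(dropped$reason, "parse_failure")
})
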