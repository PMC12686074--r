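test_that("minimal PDB fixtures parse into tidy atom tables", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 1, 1.5, 0, 0),
    pdb_line(3, "C", "GLY", "A", 1, 2.2, 1.2, 0),
    "END"
  ), pdb)
  m <- read_structure(pdb)
  expect_equal(m$n_models, 1)
  a <- m$atoms
  expect_equal(nrow(a), 3)
  expect_equal(unique(a$chain), "A")
  expect_equal(unique(a$resno), 1)
  expect_equal(a$x, c(0, 1.5, 2.2))
})

test_that("mmCIF and PDB of the same toy structure give identical coordinates", {
  model <- simulate_structure(n_res = 3, gap = 6)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(model, pdb)
  m_pdb <- read_structure(pdb)
  cif <- withr::local_tempfile(fileext = ".cif")
  a <- model$atoms
  lines <- c(
    "data_synthetic", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            a$eleno, a$element, a$elety, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
  )
  writeLines(lines, cif)
  m_cif <- read_structure(cif)
  expect_equal(m_cif$atoms[, c("x", "y", "z")], m_pdb$atoms[, c("x", "y", "z")],
               tolerance = 1e-3)
  expect_equal(m_cif$atoms$resno, m_pdb$atoms$resno)
})

test_that("multi-model files become coordinate ensembles", {
  base <- simulate_structure(n_res = 4, gap = 8)
  ens <- simulate_ensemble(base, jitter_sd = 0.2, n_frames = 5, seed = 2)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(ens, pdb)
  back <- read_structure(pdb)
  expect_equal(back$n_models, 5)
  expect_equal(nrow(back$atoms), 5 * nrow(base$atoms))
})

test_that("superposition is exact under rigid transforms and identity", {
  m <- simulate_structure(n_res = 8, gap = 5)
  s0 <- superpose_structures(m, m)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$n_pruned, 0)

  rot <- random_rotation(3)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% rot
  m2$atoms$x <- xyz[, 1] + 11; m2$atoms$y <- xyz[, 2] - 4; m2$atoms$z <- xyz[, 3] + 2
  s <- superpose_structures(m, m2)
  expect_lt(s$rmsd, 1e-6)

  # property: random rigid transforms over several seeds
  for (sd_ in 1:5) {
    r <- random_rotation(sd_)
    m3 <- m
    xyz3 <- sweep(as.matrix(m$atoms[, c("x", "y", "z")]) %*% r, 2,
                  rnorm(3, 0, 20), "+")
    m3$atoms$x <- xyz3[, 1]; m3$atoms$y <- xyz3[, 2]; m3$atoms$z <- xyz3[, 3]
    expect_lt(superpose_structures(m, m3, atoms = "heavy")$rmsd, 1e-6)
  }
})

test_that("superposition rmsd agrees with the bio3d reference fit", {
  m <- simulate_structure(n_res = 9, gap = 5)
  set.seed(4)
  m2 <- m
  n <- nrow(m$atoms)
  m2$atoms$x <- m$atoms$x + rnorm(n, 0, 0.4)
  m2$atoms$y <- m$atoms$y + rnorm(n, 0, 0.4)
  m2$atoms$z <- m$atoms$z + rnorm(n, 0, 0.4)
  got <- superpose_structures(m, m2, atoms = "heavy")$rmsd
  # independent oracle: bio3d rigid-body fit on the same paired coordinates
  fixed <- as.vector(t(as.matrix(m$atoms[, c("x", "y", "z")])))
  mobile <- as.vector(t(as.matrix(m2$atoms[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed, mobile))
  want <- sqrt(mean(colSums(matrix((fixed - fitted)^2, nrow = 3))))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("superposition rmsd of noisy copies matches the closed-form value", {
  m <- simulate_structure(n_res = 20, gap = 6)   # 200 heavy atoms
  sigma <- 0.15
  set.seed(10)
  rmsds <- replicate(50, {
    m2 <- m
    n <- nrow(m$atoms)
    m2$atoms$x <- m$atoms$x + rnorm(n, 0, sigma)
    m2$atoms$y <- m$atoms$y + rnorm(n, 0, sigma)
    m2$atoms$z <- m$atoms$z + rnorm(n, 0, sigma)
    superpose_structures(m, m2, atoms = "heavy")$rmsd
  })
  # E[rmsd] ~ sigma * sqrt(3) for iid Gaussian noise on many atoms
  expect_equal(mean(rmsds), sigma * sqrt(3), tolerance = 0.05)
})

test_that("pruning removes displaced outlier atoms before the final fit", {
  m <- simulate_structure(n_res = 12, gap = 6)
  m2 <- m
  ca_rows <- which(m2$atoms$elety == "CA")
  shift <- head(ca_rows, 3)
  m2$atoms$x[shift] <- m2$atoms$x[shift] + 8   # 3 displaced CA atoms
  s_raw <- superpose_structures(m, m2, atoms = "CA")
  s_pruned <- superpose_structures(m, m2, atoms = "CA", prune_cutoff = 2)
  expect_equal(s_pruned$n_pruned, 3)
  expect_equal(s_pruned$n_atoms_used + s_pruned$n_pruned, s_raw$n_atoms_used)
  expect_lt(s_pruned$rmsd, 1e-6)
  expect_gt(s_raw$rmsd, 1)
})

test_that("interface residues match the brute-force scan and respect the gap", {
  near <- simulate_structure(n_res = 6, gap = 4)
  far <- simulate_structure(n_res = 6, gap = 20)
  ra <- 1:6; rb <- 101:106
  got <- interface_residues(near, ra, rb, cutoff = 5)
  expect_gt(nrow(got), 0)
  expect_equal(nrow(interface_residues(far, ra, rb, cutoff = 5)), 0)

  # O(n^2) oracle over heavy atoms
  h <- near$atoms[near$atoms$element != "H", ]
  oracle <- list()
  for (i in ra) for (j in rb) {
    ai <- h[h$resno == i, c("x", "y", "z")]
    aj <- h[h$resno == j, c("x", "y", "z")]
    dmin <- min(sqrt(outer(rowSums(ai^2), rowSums(aj^2), "+") -
                       2 * as.matrix(ai) %*% t(as.matrix(aj))))
    if (dmin <= 5) oracle[[paste(i, j)]] <- dmin
  }
  expect_setequal(paste(got$res_a, got$res_b), names(oracle))
  expect_equal(got$min_dist[order(paste(got$res_a, got$res_b))],
               unname(unlist(oracle))[order(names(oracle))], tolerance = 1e-9)

  # symmetry in the two ranges
  swapped <- interface_residues(near, rb, ra, cutoff = 5)
  expect_setequal(paste(got$res_a, got$res_b), paste(swapped$res_b, swapped$res_a))
  expect_error(interface_residues(near, 1:6, 6:10), "overlap")
})

test_that("residue contacts flag hydrogen-bond-capable N/O pairs only", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.2, 0, 0),
    pdb_line(3, "O", "SER", "A", 2, 0, 2.9, 0),     # N-O at 2.9 A
    pdb_line(4, "CB", "SER", "A", 2, 1.2, 2.9, 0),  # C-C at 2.9 A from CA
    pdb_line(5, "CG", "LEU", "A", 3, 30, 0, 0),     # far away
    "END"
  ), pdb)
  m <- read_structure(pdb)
  rep1 <- residue_contacts(m, 1)
  expect_equal(rep1$resno, 2)
  expect_true(rep1$hbond_capable)
  # focal residue 2 seen from a carbon-only perspective is a plain contact
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CG", "LEU", "A", 2, 0, 2.9, 0),
    "END"
  ), pdb2)
  m2 <- read_structure(pdb2)
  rep2 <- residue_contacts(m2, 1)
  expect_equal(rep2$resno, 2)
  expect_false(rep2$hbond_capable)
  expect_error(residue_contacts(m2, 99), "not found")
  # sorted ascending by distance
  expect_true(!is.unsorted(rep1$min_dist))
})

test_that("pocket distances follow the centroid geometry", {
  # ligand centroid exactly at the origin; CA-only residue at (3,4,0)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "GLY", "A", 1, 3, 4, 0),
    pdb_line(2, "C1", "ADP", "L", 900, 0.5, 0, 0, record = "HETATM", element = "C"),
    pdb_line(3, "C2", "ADP", "L", 900, -0.5, 0, 0, record = "HETATM", element = "C"),
    "END"
  ), pdb)
  m <- read_structure(pdb)
  pocket <- pocket_center(m, ligand = "ADP")
  expect_equal(pocket$center, c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(distance_to_pocket(m, 1, pocket), 5)   # Pythagoras
  expect_error(pocket_center(m, ligand = "ATP"), "No defining atoms")

  # side-chain centroid oracle on the synthetic two-domain model
  model <- simulate_structure(n_res = 4, gap = 6, ligand_center = c(1, 2, 3))
  pk <- pocket_center(model, ligand = "LIG")
  expect_equal(pk$center, c(1, 2, 3), ignore_attr = TRUE)
  a2 <- model$atoms[model$atoms$resno == 2 & !model$atoms$het, ]
  side <- a2[!a2$elety %in% c("N", "CA", "C", "O", "OXT"), ]
  oracle <- sqrt(sum((colMeans(side[, c("x", "y", "z")]) - c(1, 2, 3))^2))
  expect_equal(distance_to_pocket(model, 2, pk), oracle, tolerance = 1e-12)
})

test_that("RMSF is zero for static ensembles and d for +/-d alternation", {
  base <- simulate_structure(n_res = 5, gap = 8)
  static <- simulate_ensemble(base, jitter_sd = 0, n_frames = 4, seed = 1)
  prof <- ensemble_rmsf(static)
  expect_true(all(prof$rmsf == 0))

  # residue displaced +/- d along x in alternating frames -> RMSF = d
  d <- 0.7
  ens <- static
  ca_res3 <- which(ens$atoms$elety == "CA" & ens$atoms$resno == 3)
  ens$atoms$x[ca_res3] <- ens$atoms$x[ca_res3] + c(d, -d, d, -d)
  prof2 <- ensemble_rmsf(ens)
  expect_equal(prof2$rmsf[prof2$resno == 3 & prof2$chain == "A"], d,
               tolerance = 1e-12)
  expect_equal(sum(prof2$rmsf > 1e-12), 1)
})

test_that("RMSF of a jittered ensemble converges to sigma * sqrt(3)", {
  base <- simulate_structure(n_res = 10, gap = 8)
  sigma <- 0.3
  ens <- simulate_ensemble(base, jitter_sd = sigma, n_frames = 500, seed = 5)
  prof <- ensemble_rmsf(ens)
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.05)
  # the per-frame-superposition variant stays in the same range
  prof_fit <- ensemble_rmsf(ens, fit = TRUE)
  expect_equal(mean(prof_fit$rmsf), sigma * sqrt(3), tolerance = 0.07)
  expect_error(ensemble_rmsf(base), "at least 2")
})
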