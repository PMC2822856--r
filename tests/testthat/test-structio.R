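# Structure parsing, centroid reduction, superposition and RMSF.

test_that("PDB parsing retains standard residues and applies filters", {
  s <- read_structure(toy_two_residue_pdb())
  expect_s3_class(s, "mhc_structure")
  expect_equal(nrow(unique(s$atom[c("chain", "resno")])), 2L)
  expect_equal(structure_chains(s), "A")
  expect_equal(chain_sequence(s, "A"), "AG")

  # hetero groups, waters and hydrogens are dropped
  txt <- paste(c(toy_two_residue_pdb(),
                 pdb_line(20, "O", "HOH", "A", 90, 0, 0, 9),
                 pdb_line(21, "HB1", "ALA", "A", 1, 1.2, -1.4, 1.2,
                          element = "H")), collapse = "\n")
  s2 <- read_structure(txt)
  expect_equal(nrow(s2$atom), nrow(s$atom))

  expect_error(read_structure("REMARK nothing here"), "no ATOM records")
  expect_error(read_structure(pdb_line(1, "O", "HOH", "A", 1, 0, 0, 0)),
               "retained")
  expect_error(read_structure(paste("ATOM      1  CA  ALA A   1   bad",
                                    sep = "")), "malformed")
})

test_that("altloc duplicates resolve to the highest-occupancy copy", {
  txt <- paste(c(
    pdb_line(1, "N",  "ALA", "A", 1, 0.0, 1.4, 0.0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.2, 0.6, 0.0, occ = 0.6, alt = "A"),
    pdb_line(3, "CA", "ALA", "A", 1, 9.9, 9.9, 9.9, occ = 0.4, alt = "B"),
    pdb_line(4, "C",  "ALA", "A", 1, 2.4, 1.4, 0.0),
    pdb_line(5, "O",  "ALA", "A", 1, 2.5, 2.6, 0.0),
    "END"), collapse = "\n")
  s <- read_structure(txt)
  ca <- s$atom[s$atom$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(unlist(ca[c("x", "y", "z")], use.names = FALSE),
               c(1.2, 0.6, 0.0))

  # equal occupancy: altloc A wins
  txt2 <- sub("  0.60", "  0.40", txt, fixed = TRUE)
  ca2 <- read_structure(txt2)$atom
  ca2 <- ca2[ca2$elety == "CA", ]
  expect_equal(ca2$x, 1.2)
})

test_that("multi-model files load as trajectory frames on request", {
  frames <- lapply(c(0, 1, 2), function(dz) {
    backbone_lines(3, shift = c(0, 0, dz))
  })
  txt <- multi_model_pdb(frames)
  s1 <- read_structure(txt)
  expect_equal(s1$nframes, 1L)
  st <- read_structure(txt, trajectory = TRUE)
  expect_equal(st$nframes, 3L)
  expect_equal(frame_z <- matrix(st$xyz[, 3], nrow = 3)[, 1], c(0, 1, 2))
})

test_that("centroid schemes follow their definitions", {
  s <- read_structure(toy_two_residue_pdb())
  ca <- reduce_structure(s, "CA")
  expect_equal(attr(ca, "scheme"), "CA")
  expect_equal(c(ca$x[1], ca$y[1], ca$z[1]), c(1.2, 0.6, 0.0))

  # alanine under CM: centroid is its single heavy side-chain atom (CB)
  cm <- reduce_structure(s, "CM")
  expect_equal(c(cm$x[1], cm$y[1], cm$z[1]), c(1.2, -0.5, 1.2))

  # CM centroid of a two-atom side chain is their midpoint
  txt <- paste(c(
    pdb_line(1, "N",  "SER", "A", 1, -1.2, 0.86, 0),
    pdb_line(2, "CA", "SER", "A", 1, 0, 0, 0),
    pdb_line(3, "C",  "SER", "A", 1, 1.31, 0.78, 0),
    pdb_line(4, "O",  "SER", "A", 1, 1.25, 2.01, 0),
    pdb_line(5, "CB", "SER", "A", 1, 0, 0, 0),
    pdb_line(6, "OG", "SER", "A", 1, 2, 0, 0),
    "END"), collapse = "\n")
  cm2 <- reduce_structure(read_structure(txt), "CM")
  expect_equal(c(cm2$x, cm2$y, cm2$z), c(1, 0, 0))

  # reduction is invariant to atom record order
  lines <- strsplit(toy_two_residue_pdb(), "\n")[[1]]
  shuffled <- paste(c(sample(lines[1:9]), "END"), collapse = "\n")
  cm3 <- reduce_structure(read_structure(shuffled), "CM")
  expect_equal(cm3$x, cm$x)
  expect_equal(cm3$z, cm$z)

  # a missing backbone atom is an error naming the residue (glycine needs
  # N, CA and C to build its virtual C-beta)
  broken <- paste(lines[-6], collapse = "\n")
  expect_error(reduce_structure(read_structure(broken), "CB"),
               "missing backbone atom N in residue GLY")
})

test_that("glycine gets a virtual C-beta at the construction bond length", {
  s <- read_structure(toy_two_residue_pdb())
  cb <- reduce_structure(s, "CB")
  gly <- cb[cb$resid == "GLY", ]
  ca_xyz <- s$atom[s$atom$resno == 2 & s$atom$elety == "CA", c("x", "y", "z")]
  d <- sqrt(sum((unlist(gly[c("x", "y", "z")]) - unlist(ca_xyz))^2))
  expect_equal(d, 1.522, tolerance = 1e-9)
  # equal angles to the N and C directions
  n_xyz <- unlist(s$atom[s$atom$resno == 2 & s$atom$elety == "N",
                         c("x", "y", "z")])
  c_xyz <- unlist(s$atom[s$atom$resno == 2 & s$atom$elety == "C",
                         c("x", "y", "z")])
  v <- unlist(gly[c("x", "y", "z")]) - unlist(ca_xyz)
  u1 <- n_xyz - unlist(ca_xyz); u2 <- c_xyz - unlist(ca_xyz)
  a1 <- acos(sum(v * u1) / sqrt(sum(v^2) * sum(u1^2)))
  a2 <- acos(sum(v * u2) / sqrt(sum(v^2) * sum(u2^2)))
  expect_equal(a1, a2, tolerance = 1e-6)
  # glycine under CM also falls back to the virtual C-beta, silently
  expect_silent(cm <- reduce_structure(s, "CM"))
  expect_equal(unlist(cm[cm$resid == "GLY", c("x", "y", "z")],
                      use.names = FALSE),
               unlist(gly[c("x", "y", "z")], use.names = FALSE))
})

test_that("superposition is exact for rigid transforms and matches a grid oracle", {
  set.seed(1)
  a <- matrix(rnorm(30), ncol = 3)
  fit <- superpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  # 90-degree rotation about z plus translation: rmsd stays 0
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  b <- a %*% t(Rz) + matrix(rep(c(5, -2, 1), each = 10), ncol = 3)
  fit2 <- superpose(a, b)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  expect_equal(a %*% fit2$rotation +
                 matrix(fit2$translation, 10, 3, byrow = TRUE), b,
               tolerance = 1e-9)

  # mirror-image-like triangles superpose exactly (proper rotation exists)
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(superpose(A, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))$rmsd,
               0, tolerance = 1e-9)
  # genuinely incongruent sets: compare with a brute-force rotation search
  B <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
  expect_gt(superpose(A, B)$rmsd, 0.1)
  expect_equal(superpose(A, B)$rmsd, superpose_rmsd_oracle(A, B),
               tolerance = 1e-5)
  set.seed(7)
  A2 <- matrix(rnorm(15), ncol = 3)
  B2 <- A2 + matrix(rnorm(15, 0, 0.4), ncol = 3)
  expect_equal(superpose(A2, B2)$rmsd, superpose_rmsd_oracle(A2, B2),
               tolerance = 1e-5)
  # symmetry of the minimised rmsd
  expect_equal(superpose(A, B)$rmsd, superpose(B, A)$rmsd, tolerance = 1e-9)

  expect_error(superpose(A[1:2, ], B[1:2, ]), "at least 3")
  expect_error(superpose(A, B[1:2, ]), "equal size")
})

test_that("trajectory RMSD tracks frame displacement", {
  ref <- read_structure(multi_model_pdb(list(backbone_lines(4))))
  frames <- list(backbone_lines(4),
                 backbone_lines(4, shift = c(0, 0, 1)))
  traj <- read_structure(multi_model_pdb(frames), trajectory = TRUE)
  out <- trajectory_rmsd(ref, traj)
  expect_equal(out$rmsd[1], 0, tolerance = 1e-9)
  # a rigid shift is removed by superposition
  expect_equal(out$rmsd[2], 0, tolerance = 1e-9)

  # genuine internal deformation is not removable
  bent <- backbone_lines(4, jitter = function(s) {
    if (s > 8) c(0, 0, 2) else c(0, 0, 0)
  })
  traj2 <- read_structure(multi_model_pdb(list(backbone_lines(4), bent)),
                          trajectory = TRUE)
  expect_gt(trajectory_rmsd(ref, traj2)$rmsd[2], 0.3)
})

test_that("backbone RMSF has the documented closed forms", {
  # identical frames: zero fluctuation
  traj <- read_structure(multi_model_pdb(list(backbone_lines(3),
                                              backbone_lines(3))),
                         trajectory = TRUE)
  expect_equal(backbone_rmsf(traj)$rmsf, rep(0, 3))
  expect_error(backbone_rmsf(read_structure(
    multi_model_pdb(list(backbone_lines(3))))), "at least two frames")

  # one atom alternating by 2 A: its fluctuation is 1 A (half-range),
  # residue value averages over its four backbone atoms
  move_first <- function(dx) backbone_lines(1, jitter = function(s) {
    if (s == 1) c(dx, 0, 0) else c(0, 0, 0)
  })
  traj2 <- read_structure(multi_model_pdb(list(move_first(0), move_first(2))),
                          trajectory = TRUE)
  expect_equal(backbone_rmsf(traj2)$rmsf, 1 / 4)

  # isotropic Gaussian jitter sigma: per-atom RMSF -> sigma * sqrt(3)
  set.seed(42)
  sigma <- 0.5
  nf <- 200
  frames <- lapply(seq_len(nf), function(f) {
    backbone_lines(15, jitter = function(s) rnorm(3, 0, sigma))
  })
  traj3 <- read_structure(multi_model_pdb(frames), trajectory = TRUE)
  mean_rmsf <- mean(backbone_rmsf(traj3)$rmsf)
  expect_equal(mean_rmsf, sigma * sqrt(3 * (nf - 1) / nf), tolerance = 0.05)

  # the pre-superposition requirement is real: adding a rigid offset to one
  # frame changes the RMSF
  traj4 <- read_structure(multi_model_pdb(list(
    backbone_lines(3), backbone_lines(3, shift = c(0, 0, 3)))),
    trajectory = TRUE)
  expect_gt(mean(backbone_rmsf(traj4)$rmsf), 1)
})
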