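# PDB parsing, selections, and the geometric primitives.

test_that("PDB reading: altloc resolution, HETATM retention, format errors", {
  lines <- c(
    "ATOM      1  N   SER A  10      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  OG ASER A  10      11.000  10.000  10.000  0.60  0.00           O",
    "ATOM      3  OG BSER A  10      12.000  10.000  10.000  0.40  0.00           O",
    "HETATM    4  O   HOH A 100      20.000  20.000  20.000  1.00  0.00           O",
    "END")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  m <- read_structure(tf)
  expect_equal(nrow(m$atoms), 3)            # one OG survives
  og <- m$atoms[m$atoms$atom == "OG", ]
  expect_equal(og$x, 11.0)                  # the occupancy-0.6 conformer
  expect_true("HETATM" %in% m$atoms$type)

  bad <- c("ATOM      1  N   SER A  10      10.0xx  10.000  10.000  1.00  0.00           N")
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, tf2)
  err <- tryCatch(read_structure(tf2), error = function(e) e)
  expect_s3_class(err, "format_error")
  expect_match(conditionMessage(err), "line 1")
})

test_that("altloc ties resolve to conformer A and write/read round-trips", {
  atoms <- rbind(
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "CA",
               x = 1, y = 0, z = 0, occ = 0.5, altloc = "B",
               stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "CA",
               x = 2, y = 0, z = 0, occ = 0.5, altloc = "A",
               stringsAsFactors = FALSE))
  m <- structure_model(atoms)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 2)                # tie -> altloc A

  tpl <- decoding_center_template("recognized")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tpl, tf)
  back <- read_structure(tf)
  expect_equal(model_coords(back), model_coords(tpl), tolerance = 1e-3)
  expect_identical(atom_ids(back), atom_ids(tpl))
})

test_that("selection grammar: wildcards, ranges, lists, insertion codes", {
  m <- synthetic_rf_complex("mtrf1", "recognized")
  expect_length(select_atoms(m, "A:1492:*"), 12)
  expect_length(select_atoms(m, "A:1492-1493:*"), 24)
  expect_gt(length(select_atoms(m, "R:286-301:*")), 60)
  expect_length(select_atoms(m, "R:115A:*"), 11)          # the RT-insert Arg
  expect_length(select_atoms(m, "R:115:*"), 0)            # icode matters
  expect_length(select_atoms(m, "A:1493:N1"), 1)
  expect_equal(length(select_atoms(m, "A:1492,1493:N*")),
               length(select_atoms(m, list(chain = "A",
                                           resno = c(1492, 1493),
                                           atom = c("N1", "N3", "N6", "N7",
                                                    "N9")))))
  expect_error(select_atoms(m, "A:1492"), class = "selection_error")
})

test_that("minimum distance over the cross product of two selections", {
  atoms <- rbind(
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "CA",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "B", resno = 1, resname = "GLY", atom = "CA",
               x = 3, y = 4, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "B", resno = 2, resname = "GLY", atom = "CA",
               x = 30, y = 4, z = 0, stringsAsFactors = FALSE))
  m <- structure_model(atoms)
  expect_equal(min_distance(m, "A:*:*", "A:*:*"), 0)
  expect_equal(min_distance(m, "A:*:*", "B:*:*"), 5)
  expect_equal(min_distance(m, "B:*:*", "A:*:*"), 5)
  expect_error(min_distance(m, "C:*:*", "A:*:*"), class = "selection_error")
})

test_that("hydrogen-bond window and donor/acceptor chemistry", {
  far <- structure_model(rbind(
    data.frame(chain = "A", resno = 1, resname = "SER", atom = "OG",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 5, resname = "GLY", atom = "O",
               x = 10, y = 0, z = 0, stringsAsFactors = FALSE)))
  expect_equal(nrow(detect_hbonds(far, "A:1:*", "A:5:*")), 0)

  near <- structure_model(rbind(
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "N",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 5, resname = "GLY", atom = "O",
               x = 2.9, y = 0, z = 0, stringsAsFactors = FALSE)))
  hb <- detect_hbonds(near, "A:1:*", "A:5:*")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, "A:1:N")
  expect_equal(hb$acceptor, "A:5:O")
  expect_true(is.na(hb$angle))

  # two carbons at bonding distance are not a hydrogen bond
  cc <- structure_model(rbind(
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "CA",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 5, resname = "GLY", atom = "CA",
               x = 2.9, y = 0, z = 0, stringsAsFactors = FALSE)))
  expect_equal(nrow(detect_hbonds(cc, "A:1:*", "A:5:*")), 0)
})

test_that("D-H...A angle is enforced only when hydrogens are present", {
  base <- function(hx, hy) structure_model(rbind(
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "N",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "H",
               x = hx, y = hy, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 5, resname = "GLY", atom = "O",
               x = 2.9, y = 0, z = 0, stringsAsFactors = FALSE)))
  # H pointing at the acceptor: near-linear, accepted
  lin <- detect_hbonds(base(1.0, 0), "A:1:*", "A:5:*")
  expect_equal(nrow(lin), 1)
  expect_equal(lin$angle, 180, tolerance = 1e-6)
  # H pointing away: ~41 degrees, rejected
  expect_equal(nrow(detect_hbonds(base(-0.5, 0.87), "A:1:*", "A:5:*")), 0)
})

test_that("steric clash overlap arithmetic and exclusions", {
  two_c <- structure_model(rbind(
    data.frame(chain = "A", resno = 1, resname = "ALA", atom = "CB",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 5, resname = "ALA", atom = "CB",
               x = 2.0, y = 0, z = 0, stringsAsFactors = FALSE)))
  cl <- detect_clashes(two_c, "A:1:*", "A:5:*")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$overlap, 1.40, tolerance = 1e-9)
  expect_equal(cl$distance, 2.0)

  # same residue and peptide-bond neighbours are excluded
  pep <- structure_model(rbind(
    data.frame(chain = "A", resno = 1, resname = "GLY", atom = "C",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 2, resname = "GLY", atom = "N",
               x = 1.33, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 2, resname = "GLY", atom = "CA",
               x = 3.3, y = 0.5, z = 0, stringsAsFactors = FALSE)))
  expect_equal(nrow(detect_clashes(pep, "A:1:*", "A:2:*")), 0)

  odd <- structure_model(data.frame(
    chain = "A", resno = 1, resname = "UNK", atom = c("FE1", "FE2"),
    x = c(0, 1), y = 0, z = 0, element = "FE",
    stringsAsFactors = FALSE))
  err <- tryCatch(detect_clashes(odd, 1L, 2L), error = function(e) e)
  expect_s3_class(err, "lookup_error")
  expect_match(conditionMessage(err), "FE")
})

test_that("superposition: exact recovery, degeneracy, symmetry", {
  set.seed(42)
  X <- matrix(rnorm(30), ncol = 3)
  self <- superpose(X, X)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  th <- 30 * pi / 180
  R30 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  Y <- X %*% t(R30) + matrix(c(1, -2, 3), nrow(X), 3, byrow = TRUE)
  tr <- superpose(Y, X)
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(apply_transform(Y, tr), X, tolerance = 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)

  expect_error(superpose(X[1:2, ], X[1:2, ]), class = "degeneracy_error")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), class = "degeneracy_error")

  # rmsd symmetric under swapping mobile and reference
  Z <- X + matrix(rnorm(30, sd = 0.3), ncol = 3)
  expect_equal(superpose(X, Z)$rmsd, superpose(Z, X)$rmsd, tolerance = 1e-9)
})

test_that("noisy-fit rmsd agrees with the quaternion oracle", {
  set.seed(7)
  X <- matrix(rnorm(150, sd = 4), ncol = 3)
  tr0 <- random_rigid_transform()
  Y <- apply_transform(X, tr0) + matrix(rnorm(150, sd = 0.2), ncol = 3)
  fit <- superpose(Y, X)
  expect_gt(fit$rmsd, 0.15)
  expect_lt(fit$rmsd, 0.45)
  expect_equal(fit$rmsd, oracle_quaternion_rmsd(Y, X), tolerance = 1e-9)
})

test_that("geometry detectors are rigid-motion invariant", {
  m <- synthetic_rf_complex("mtrf1", "recognized")
  d0 <- min_distance(m, "R:*:*", "A:1493:*")
  hb0 <- detect_hbonds(m, "R:*:*", "A:*:*")
  cl0 <- detect_clashes(m, "R:*:*", "A:1493:*")
  set.seed(5)
  for (k in 1:5) {
    tr <- random_rigid_transform()
    mt <- apply_transform(m, tr)
    expect_equal(min_distance(mt, "R:*:*", "A:1493:*"), d0, tolerance = 1e-6)
    hb <- detect_hbonds(mt, "R:*:*", "A:*:*")
    expect_identical(hb[, c("donor", "acceptor")],
                     hb0[, c("donor", "acceptor")])
    expect_equal(hb$distance, hb0$distance, tolerance = 1e-6)
    cl <- detect_clashes(mt, "R:*:*", "A:1493:*")
    expect_identical(cl[, c("atom_a", "atom_b")],
                     cl0[, c("atom_a", "atom_b")])
    expect_equal(cl$overlap, cl0$overlap, tolerance = 1e-6)
  }
})

test_that("detectors match the naive all-pairs oracle on random models", {
  for (seed in c(2, 17, 33)) {
    m <- random_toy_model(n_res = 25, seed = seed, spread = 14)
    hb <- detect_hbonds(m, seq_len(nrow(m$atoms)), seq_len(nrow(m$atoms)))
    got <- unique(data.frame(a = pmin(hb$donor, hb$acceptor),
                             b = pmax(hb$donor, hb$acceptor),
                             stringsAsFactors = FALSE))
    got <- got[order(got$a, got$b), , drop = FALSE]
    want <- oracle_hbonds(m)[, c("a", "b")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("hbonds seed", seed))

    cl <- detect_clashes(m, seq_len(nrow(m$atoms)), seq_len(nrow(m$atoms)))
    gotc <- data.frame(a = pmin(cl$atom_a, cl$atom_b),
                       b = pmax(cl$atom_a, cl$atom_b),
                       stringsAsFactors = FALSE)
    gotc <- gotc[order(gotc$a, gotc$b), , drop = FALSE]
    wantc <- oracle_clashes(m)[, c("a", "b")]
    rownames(gotc) <- rownames(wantc) <- NULL
    expect_equal(gotc, wantc, info = paste("clashes seed", seed))
  }
})
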