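test_that("dihedral measurement matches the sign convention and the cross-product oracle", {
  # planar cis and trans arrangements
  expect_equal(measure_torsion(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(abs(measure_torsion(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))), 180)
  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(3); b <- a + rnorm(3); c <- b + rnorm(3); d <- c + rnorm(3)
    expect_equal(measure_torsion(a, b, c, d), oracle_dihedral(a, b, c, d),
                 tolerance = 1e-9)
  }
  expect_error(measure_torsion(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("built conformations realize the requested torsions", {
  cases <- list(
    list(ptm_state("LYS", "monomethyl"), "60", 4),
    list(ptm_state("LYS", "acetyl"), "0", 4),
    list(ptm_state("ARG", "dimethyl-sym"), "180", 4),
    list(ptm_state("SER", "GalNAc-alpha"), "-", 3),
    list(ptm_state("ASN", "GlcNAc-beta"), "-", 4)
  )
  set.seed(21)
  for (cs in cases) {
    st <- cs[[1]]
    for (rep in 1:50) {
      ts <- torsion_set(phi = runif(1, -179, 180), psi = runif(1, -179, 180),
                        chi = runif(cs[[3]], -179, 180))
      cf <- build_conformation(st, ts, rotamer = cs[[2]])
      expect_equal(conformation_torsion(cf, c("2:C", "3:N", "3:CA", "3:C")),
                   ts$phi, tolerance = 1e-3)
      expect_equal(conformation_torsion(cf, c("3:N", "3:CA", "3:C", "4:N")),
                   ts$psi, tolerance = 1e-3)
    }
  }
})

test_that("bond lengths and atom counts equal the topology template", {
  st <- ptm_state("LYS", "trimethyl")
  ts <- torsion_set(-63, -43, c(-60, 180, 180, 60))
  cf <- build_conformation(st, ts)
  topo <- ptm_topology(st, "-")
  expect_identical(nrow(cf$atoms), nrow(topo$zmatrix))
  xyz <- as.matrix(cf$atoms[, c("x", "y", "z")])
  for (r in 2:nrow(topo$zmatrix)) {
    d <- sqrt(sum((xyz[r, ] - xyz[topo$zmatrix$i[r], ])^2))
    expect_equal(d, topo$zmatrix$bond[r], tolerance = 1e-9)
  }
})

test_that("torsion arity mismatches are rejected", {
  st <- ptm_state("SER", "GalNAc-alpha")  # needs chi1..chi3
  expect_error(build_conformation(st, torsion_set(-60, 140, chi = -65)),
               "mismatch")
})

test_that("clash detection equals the brute-force oracle across states", {
  set.seed(31)
  states <- list(
    list(ptm_state("LYS", "dimethyl"), "60", 4),
    list(ptm_state("ARG", "monomethyl-NH"), "NH1:0", 4),
    list(ptm_state("THR", "GlcNAc-beta"), "-", 3)
  )
  n_checked <- 0
  for (cs in states) {
    for (rep in 1:10) {
      ts <- torsion_set(phi = runif(1, -179, 180), psi = runif(1, -179, 180),
                        chi = runif(cs[[3]], -179, 180))
      cf <- build_conformation(cs[[1]], ts, rotamer = cs[[2]])
      got <- detect_clashes(cf)
      want <- oracle_clashes(cf)
      expect_identical(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_identical(got[order(got$i, got$j), c("i", "j")],
                         as.data.frame(want[order(want[, 1], want[, 2]), ,
                                            drop = FALSE],
                                       col.names = c("i", "j")),
                        ignore_attr = TRUE)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_identical(n_checked, 30)
})

test_that("overlapping non-bonded atoms are flagged, bonded ones excluded", {
  ts <- torsion_set(-63, -43, c(-60, 180, 180, 60))
  cf <- build_conformation(ptm_state("LYS", "charged"), ts)
  # directly bonded pair ~1.5 A apart must not be flagged
  base <- detect_clashes(cf)
  if (nrow(base)) {
    bd <- cbind(base$i, base$j)
    bonded <- apply(cf$bonds, 1, paste, collapse = "-")
    expect_false(any(apply(bd, 1, paste, collapse = "-") %in% bonded))
  }
  # move the terminal NZ onto the Ace methyl: far apart in the bond graph
  nz <- which(cf$atoms$name == "NZ")
  cf$atoms[nz, c("x", "y", "z")] <- cf$atoms[1, c("x", "y", "z")] + 0.05
  cl <- detect_clashes(cf)
  expect_true(any((cl$i == 1 & cl$j == nz) | (cl$i == nz & cl$j == 1)))
})

test_that("shielding-job input partitions atoms exhaustively and disjointly", {
  ts <- torsion_set(-63, -43, c(-60, 180, 180, 60))
  cf <- build_conformation(ptm_state("LYS", "monomethyl"), ts, rotamer = "180")
  path <- withr::local_tempfile(fileext = ".com")
  part <- write_qc_input(cf, "CE", neighbor_shell = 1, path = path)
  expect_length(intersect(part$high, part$low), 0)
  expect_setequal(c(part$high, part$low), seq_len(nrow(cf$atoms)))
  nms <- cf$atoms$name[part$high]
  expect_setequal(nms, c("CE", "CD", "NZ"))  # focus + its bonded neighbors
  txt <- readLines(path)
  expect_true(any(grepl("6-311+G(2d,p)", txt, fixed = TRUE)))
  expect_true(any(grepl("3-21G", txt, fixed = TRUE)))
  expect_true(any(grepl("NMR=GIAO", txt, fixed = TRUE)))

  part0 <- write_qc_input(cf, "CE", neighbor_shell = 0, path = path)
  expect_identical(cf$atoms$name[part0$high], "CE")
  expect_error(write_qc_input(cf, "XX", path = path), "unknown nucleus")
})

test_that("PDB round trip preserves coordinates and atom classes", {
  pair <- tiny_lys_pair()
  confs <- pair$modified[1:5]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(confs, path)
  back <- read_pdb(path)
  expect_length(back, 5)
  for (m in 1:5) {
    expect_equal(as.matrix(back[[m]]$atoms[, c("x", "y", "z")]),
                 as.matrix(confs[[m]]$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  # byte-determinism
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(confs, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty list -> valid file with zero models
  write_pdb(list(), path)
  expect_length(read_pdb(path), 0)
})

test_that("glycan atoms are written as HETATM and parse with bio3d", {
  skip_if_not_installed("bio3d")
  ts <- torsion_set(-70, 150, chi = c(-65, 60, 180))
  cf <- build_conformation(ptm_state("SER", "GalNAc-alpha"), ts)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cf, path)
  txt <- readLines(path)
  het <- grepl("^HETATM", txt)
  expect_identical(sum(het), sum(cf$atoms$het))
  pdb <- bio3d::read.pdb(path)
  expect_identical(nrow(pdb$atom), nrow(cf$atoms))
  expect_identical(sum(pdb$atom$type == "HETATM"), sum(cf$atoms$het))
  expect_equal(pdb$atom$x, cf$atoms$x, tolerance = 1e-3)
})

test_that("malformed PDB records raise parse errors with a line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", "ATOM      1  CA  GLY A   1    bad"), path)
  expect_error(read_pdb(path), "line 2")
})
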