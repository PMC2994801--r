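test_that("torsion recomputation round-trips the backbone builder", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(5:50, 1)
      tor <- tibble::tibble(phi = runif(n, -180, 180),
                            psi = runif(n, -180, 180),
                            omega = sample(c(180, 170, -175, 0), n, TRUE))
      ch <- build_backbone_from_torsions(tor)
      rt <- compute_torsions(ch)
      expect_lt(max(abs(wrap_angle(rt$phi[-1] - tor$phi[-1]))), 1e-4)
      expect_lt(max(abs(wrap_angle(rt$psi[-n] - tor$psi[-n]))), 1e-4)
      expect_lt(max(abs(wrap_angle(rt$omega[-1] - tor$omega[-1]))), 1e-4)
      ok <- !is.na(rt$phi)
      expect_true(all(rt$phi[ok] > -180 & rt$phi[ok] <= 180))
    }
  })
})

test_that("rigid motions leave torsions and CA distances unchanged", {
  withr::with_seed(21, {
    tor <- tibble::tibble(phi = runif(12, -180, 180),
                          psi = runif(12, -180, 180))
    ch <- build_backbone_from_torsions(tor)
    t0 <- compute_torsions(ch)
    d0 <- ca_distance(ch, 2, 9)
    # random rotation (QR of a random matrix) plus translation
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    shift <- c(10, -5, 3)
    moved <- ch
    for (at in c("n", "ca", "c")) {
      cols <- paste0(at, c("_x", "_y", "_z"))
      moved[cols] <- sweep(as.matrix(ch[cols]) %*% t(R), 2, shift, "+")
    }
    moved <- new_backbone_chain(moved, chain_id = "A")
    t1 <- compute_torsions(moved)
    expect_lt(max(abs(wrap_angle(t1$phi - t0$phi)), na.rm = TRUE), 1e-6)
    expect_lt(max(abs(wrap_angle(t1$psi - t0$psi)), na.rm = TRUE), 1e-6)
    expect_lt(abs(ca_distance(moved, 2, 9) - d0), 1e-6)
  })
})

test_that("mirror-imaged coordinates negate every torsion", {
  withr::with_seed(31, {
    tor <- tibble::tibble(phi = runif(8, -170, 170),
                          psi = runif(8, -170, 170))
    ch <- build_backbone_from_torsions(tor)
    mir <- ch
    for (at in c("n", "ca", "c")) mir[[paste0(at, "_z")]] <-
      -mir[[paste0(at, "_z")]]
    mir <- new_backbone_chain(mir, chain_id = "A")
    t0 <- compute_torsions(ch)
    t1 <- compute_torsions(mir)
    expect_equal(t1$phi[-1], -t0$phi[-1], tolerance = 1e-8)
    expect_equal(t1$psi[-8], -t0$psi[-8], tolerance = 1e-8)
  })
})

test_that("dihedral of a planar anti arrangement is 180 degrees", {
  p1 <- matrix(c(0, 1, 0), 1)
  p2 <- matrix(c(0, 0, 0), 1)
  p3 <- matrix(c(1, 0, 0), 1)
  p4 <- matrix(c(1, -1, 0), 1)
  expect_equal(abs(betaturn:::dihedral_deg(p1, p2, p3, p4)), 180)
})

test_that("torsions agree with an established structural-biology library", {
  withr::with_seed(41, {
    tor <- tibble::tibble(phi = runif(6, -180, 180),
                          psi = runif(6, -180, 180))
    ch <- build_backbone_from_torsions(tor)
    # independent check of one interior phi with bio3d
    xyz <- c(unlist(ch[2, c("c_x", "c_y", "c_z")]),
             unlist(ch[3, c("n_x", "n_y", "n_z")]),
             unlist(ch[3, c("ca_x", "ca_y", "ca_z")]),
             unlist(ch[3, c("c_x", "c_y", "c_z")]))
    expect_equal(compute_torsions(ch)$phi[3],
                 as.numeric(bio3d::torsion.xyz(xyz)), tolerance = 1e-6)
  })
})

test_that("ca_distance is Euclidean, symmetric and guards completeness", {
  ch <- build_backbone_from_torsions(
    tibble::tibble(phi = rep(-60, 4), psi = rep(-45, 4)))
  ch$ca_x <- c(0, 3, 1, 2)
  ch$ca_y <- c(0, 4, 1, 2)
  ch$ca_z <- c(0, 0, 1, 2)
  ch2 <- new_backbone_chain(ch, chain_id = "A")
  expect_equal(ca_distance(ch2, 1, 2), 5)
  expect_equal(ca_distance(ch2, 3, 3), 0)
  expect_equal(ca_distance(ch2, 1, 4), ca_distance(ch2, 4, 1))
  ch$ca_x[2] <- NA
  ch3 <- new_backbone_chain(ch[, setdiff(names(ch), "complete")],
                            chain_id = "A")
  expect_error(ca_distance(ch3, 1, 2), "complete")
})

test_that("cis-peptide detection honors the configurable cutoff", {
  expect_true(is_cis_peptide(0))
  expect_false(is_cis_peptide(180))
  expect_true(is_cis_peptide(29.9))
  expect_false(is_cis_peptide(30.1))
  expect_false(is_cis_peptide(29.9, cis_cutoff = 20))
  expect_true(is_cis_peptide(-350))  # wraps to +10
  expect_error(is_cis_peptide(NA), "undefined")
})

test_that("read_backbone parses ATOM records, altlocs and chain errors", {
  withr::with_seed(51, {
    plant <- plant_turn_chain(10, turns = tibble::tibble(start = 4,
                                                         type = "II"))
    lines <- write_pdb_chain(plant$chain)
    back <- read_backbone(lines, "A")
    cols <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
              "c_x", "c_y", "c_z")
    expect_equal(nrow(back), 10)
    expect_true(all(back$complete))
    expect_lt(max(abs(as.matrix(back[cols]) -
                        as.matrix(plant$chain[cols]))), 1e-3)
    expect_error(read_backbone(lines, "B"), "available chains: A")

    # drop the CA of residue 5: flagged incomplete, others intact
    is_ca5 <- grepl("^ATOM", lines) & substr(lines, 13, 16) == " CA " &
      trimws(substr(lines, 23, 26)) == "5"
    expect_equal(sum(is_ca5), 1)
    drop <- lines[!is_ca5]
    back2 <- read_backbone(drop, "A")
    expect_false(back2$complete[5])
    expect_equal(sum(back2$complete), 9)

    # altloc: the higher-occupancy coordinate wins
    two <- c(
      "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.30  0.00           N",
      "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.70  0.00           N",
      "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
      "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
      "TER", "END")
    b3 <- read_backbone(two, "A")
    expect_equal(b3$n_x[1], 9)
  })
})

test_that("chains without any complete residue are rejected", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "TER", "END")
  expect_error(read_backbone(lines, "A"), "complete")
})
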