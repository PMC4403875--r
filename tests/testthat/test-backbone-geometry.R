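test_that("dihedral follows the IUPAC sign convention", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedral(p1, p2, p3, c(1, 0, 0)), 0)
  expect_equal(dihedral(p1, p2, p3, c(-1, 0, 0)), 180)

  # p4 rotated +90 about the p2->p3 axis from cis must read +90
  R <- helixhb:::rotation_matrix(p3 - p2, 90)
  p4 <- as.vector(R %*% c(1, 0, 0))
  expect_equal(dihedral(p1, p2, p3, p4), 90)

  expect_error(dihedral(p1, p2, p3, c(0, 2, 0) - p2 + p3), "collinear")
})

test_that("torsions are invariant under rigid-body motion", {
  s <- mk_helix(-57, -47, L = 6L)
  t0 <- backbone_torsions(s)
  set.seed(42)
  for (k in 1:5) {
    R <- helixhb:::rotation_matrix(rnorm(3), runif(1, 0, 360))
    shift <- rnorm(3, sd = 20)
    s2 <- s
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
    s2$atoms$x <- xyz[, 1] + shift[1]
    s2$atoms$y <- xyz[, 2] + shift[2]
    s2$atoms$z <- xyz[, 3] + shift[3]
    t1 <- backbone_torsions(s2)
    expect_equal(t1$phi, t0$phi, tolerance = 1e-9)
    expect_equal(t1$psi, t0$psi, tolerance = 1e-9)
  }
})

test_that("builder/torsion round-trip reproduces arbitrary torsion lists", {
  set.seed(11)
  for (rep in 1:5) {
    L <- 8L
    tor <- list(phi = runif(L, -179, 179), psi = runif(L, -179, 179),
                omega = rep(180, L))
    s <- build_peptide(rep("ALA", L), tor)
    got <- backbone_torsions(s)
    expect_equal(got$phi, tor$phi, tolerance = 1e-6)
    expect_equal(got$psi, tor$psi, tolerance = 1e-6)
    expect_equal(abs(got$omega), rep(180, L), tolerance = 1e-6)
  }
  # termini without caps: phi of first and psi of last undefined
  s <- build_peptide(rep("ALA", 4L),
                     list(phi = rep(-62, 4), psi = rep(-43, 4)), caps = FALSE)
  got <- backbone_torsions(s)
  expect_true(is.na(got$phi[1]))
  expect_true(is.na(got$psi[4]))
  expect_equal(got$phi[-1], rep(-62, 3), tolerance = 1e-6)
})

test_that("built peptide geometry matches closed-form expectations", {
  g <- geometry_set("engh_huber")
  s <- mk_helix(-62, -43, L = 4L)
  ca <- s$atoms[s$atoms$name == "CA", c("x", "y", "z")]

  # independent 2D construction of the trans Ca-C-N-Ca fragment:
  # lay the three bonds out in a plane with the geometry-set angles
  ang1 <- (180 - g$a_ca_c_n) * pi / 180
  ang2 <- (180 - g$a_c_n_ca) * pi / 180
  p_ca <- c(0, 0)
  p_c <- c(g$b_ca_c, 0)
  dir1 <- c(cos(ang1), sin(ang1))
  p_n <- p_c + g$b_c_n * dir1
  th2 <- ang1 - ang2  # trans zigzag alternates turning direction
  p_ca2 <- p_n + g$b_n_ca * c(cos(th2), sin(th2))
  d_expect <- sqrt(sum((p_ca2 - p_ca)^2))

  d_built <- dist(ca[1:2, ])[1]
  expect_equal(as.numeric(d_built), d_expect, tolerance = 1e-6)
  expect_equal(d_expect, 3.80, tolerance = 0.01)

  # a cis junction shortens the Ca-Ca distance; same 2D closed form
  # with the turn direction reversed at the nitrogen
  th2_cis <- ang1 + ang2
  p_ca2_cis <- p_n + g$b_n_ca * c(cos(th2_cis), sin(th2_cis))
  d_cis_expect <- sqrt(sum((p_ca2_cis - p_ca)^2))

  s_cis <- build_peptide(rep("ALA", 3L),
                         list(phi = rep(-62, 3), psi = rep(-43, 3),
                              omega = c(180, 0, 180)))
  ca2 <- as.matrix(s_cis$atoms[s_cis$atoms$name == "CA" &
                                 !s_cis$atoms$resname %in% c("ACE", "NME"),
                               c("x", "y", "z")])
  d_cis <- sqrt(sum((ca2[2, ] - ca2[1, ])^2))
  expect_equal(d_cis, d_cis_expect, tolerance = 1e-6)
  expect_lt(d_cis, d_expect - 0.8)
})

test_that("amide hydrogens sit on the external bisector in the amide plane", {
  s <- mk_helix(-62, -43)
  rf <- helixhb:::residue_frames(s)
  n <- nrow(rf)
  placed <- 0L
  for (i in seq_len(n)) {
    if (is.null(rf$H[[i]]) || is.null(rf$N[[i]])) next
    prev <- i - 1L
    H <- rf$H[[i]]; N <- rf$N[[i]]; CA <- rf$CA[[i]]; C <- rf$C[[prev]]
    expect_equal(sqrt(sum((H - N)^2)), 1.00, tolerance = 1e-9)
    # coplanarity with C, N, CA
    nrm <- helixhb:::vcross(C - N, CA - N)
    nrm <- nrm / sqrt(sum(nrm^2))
    expect_lt(abs(sum((H - N) * nrm)), 1e-9)
    # external bisector: equal angles to both substituents
    a1 <- helixhb:::bond_angle(H, N, C)
    a2 <- helixhb:::bond_angle(H, N, CA)
    expect_equal(a1, a2, tolerance = 1e-9)
    placed <- placed + 1L
  }
  expect_gte(placed, 12L)  # residues 2..12 plus NME cap

  # amide planarity: O-C-N-H torsion is 0/180 when omega is trans
  b <- backbone_torsions(s)
  expect_true(all(abs(abs(b$omega) - 180) < 1e-6))
})

test_that("prolines and chain starts receive no amide hydrogen", {
  L <- 5L
  s <- build_peptide(c("ALA", "ALA", "PRO", "ALA", "ALA"),
                     list(phi = rep(-62, L), psi = rep(-43, L)))
  at <- s$atoms
  expect_false(any(at$name == "H" & at$resname == "PRO"))
  expect_true(any(at$name == "H" & at$resseq == 2L))
  # uncapped chain start has no preceding carbonyl
  s2 <- place_amide_hydrogens(build_peptide(rep("ALA", 3L),
                                            list(phi = rep(-62, 3),
                                                 psi = rep(-43, 3)),
                                            caps = FALSE))
  expect_false(any(s2$atoms$name == "H" & s2$atoms$resseq == 1L))
})

test_that("build_peptide validates its inputs", {
  expect_error(build_peptide(c("ALA", "XXX"),
                             list(phi = c(-62, -62), psi = c(-43, -43))),
               "unknown residue")
  expect_error(build_peptide(rep("ALA", 3L),
                             list(phi = rep(-62, 2), psi = rep(-43, 2))),
               "one row per residue")
})

test_that("fixture archives are deterministic and carry resolutions", {
  spec <- demo_archive_spec()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- generate_fixture_archive(spec, d1)
  p2 <- generate_fixture_archive(spec, d2)
  expect_length(p1, 5L)
  expect_identical(lapply(p1, readLines), lapply(p2, readLines))

  s <- parse_pdb(p1[2])
  expect_equal(s$resolution, 1.2)
  expect_equal(assign_resolution_bin(s$resolution), "1.00-1.49")

  expect_error(generate_fixture_archive(rbind(spec, spec[1, ]),
                                        withr::local_tempdir()),
               "duplicate")
  expect_length(generate_fixture_archive(spec[0, ], withr::local_tempdir()),
                0L)
})
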