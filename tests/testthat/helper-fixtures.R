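# Fixtures are built in code: ideal capped oligoalanine helices at the
# classical torsion points, an analytic mathematical helix, and a tiny
# hand-written PDB text.

mk_helix <- function(phi, psi, L = 12L, geometry = "engh_huber",
                     caps = TRUE, omega = 180) {
  build_peptide(rep("ALA", L),
                list(phi = rep(phi, L), psi = rep(psi, L),
                     omega = rep(omega, L)),
                geometry = geometry, caps = caps)
}

# Exact mathematical helix: radius r, turn angle step_deg per point,
# rise per point d.
analytic_helix <- function(n_points, r = 2.3, step_deg = 100, d = 1.5,
                           phase = 0) {
  i <- seq_len(n_points) - 1L
  th <- (phase + step_deg * i) * pi / 180
  cbind(r * cos(th), r * sin(th), d * i)
}

# Classical torsion points used across tests
TP <- list(alpha = c(-57, -47), nhelix = c(-62, -43),
           three10 = c(-49, -26), extended = c(-120, 120))

demo_archive_spec <- function() {
  data.frame(
    label = c("alph", "nhlx", "t310", "mdav", "extd"),
    phi = c(-57, -62, -49, -72.78, -120),
    psi = c(-47, -43, -26, -33.43, 120),
    resolution = c(1.2, 1.2, 1.7, 2.6, 1.2),
    stringsAsFactors = FALSE)
}

new_structure_for_tests <- function() {
  helixhb:::new_structure(helixhb:::empty_atoms())
}

# Minimal hand-written PDB text: two residues, a REMARK 2 resolution,
# and an altloc pair on the second CA.
tiny_pdb_text <- function(resolution_line =
                            "REMARK   2 RESOLUTION.    1.74 ANGSTROMS.") {
  c("HEADER    TEST PROTEIN                            01-JAN-00   1TST",
    resolution_line,
    "EXPDTA    X-RAY DIFFRACTION",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.597   5.516  -4.181  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.430   5.906  -4.227  1.00  0.00           O",
    "ATOM      5  N   ALA A   2      11.021   4.610  -3.297  1.00  0.00           N",
    "ATOM      6  CA AALA A   2      10.123   3.990  -2.320  0.40  0.00           C",
    "ATOM      7  CA BALA A   2      10.223   3.990  -2.320  0.60  0.00           C",
    "ATOM      8  C   ALA A   2      10.905   3.211  -1.263  1.00  0.00           C",
    "ATOM      9  O   ALA A   2      12.111   3.406  -1.094  1.00  0.00           O",
    "HETATM   10  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "TER",
    "END")
}
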