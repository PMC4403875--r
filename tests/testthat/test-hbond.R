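test_that("alpha-helical fixture forms i->i+4 bonds with sane geometry", {
  s <- place_amide_hydrogens(mk_helix(-57, -47))
  b <- detect_hbonds(s, hbond_criteria(max_ha = 2.5))
  expect_true(all(b$register == -4L))
  expect_gte(nrow(b), 8L)

  # cross-check one bond's H...O distance directly from coordinates
  at <- s$atoms
  pick <- function(rs, nm) unlist(at[at$resseq == rs & at$name == nm,
                                     c("x", "y", "z")])
  one <- b[b$donor == 8L, ][1, ]
  d_hand <- sqrt(sum((pick(8L, "H") - pick(one$acceptor, "O"))^2))
  expect_equal(one$d_ha, d_hand, tolerance = 1e-9)
  expect_lte(one$d_ha, 2.5)
  expect_lte(one$d_da, 3.9)
  expect_gte(one$angle_dha, 90)
})

test_that("extended conformation forms no hydrogen bonds", {
  s <- place_amide_hydrogens(mk_helix(-120, 120))
  expect_equal(nrow(detect_hbonds(s)), 0L)
})

test_that("detection requires placed hydrogens", {
  s <- mk_helix(-57, -47)
  s$atoms <- s$atoms[s$atoms$name != "H", ]
  expect_error(detect_hbonds(s), "place_amide_hydrogens")
})

test_that("three-centered bonds emerge at the consensus helix torsions", {
  a <- analyze_structure(mk_helix(-62, -43))
  b <- a$bonds
  expect_true(all(sort(unique(b$register)) == c(-4L, -3L)))
  expect_gte(attr(b, "shared_donors"), 1L)
  # both members of a shared pair are flagged and helical
  sh <- b[b$shared, ]
  expect_true(all(sh$category %in% c("alpha", "three_ten")))
  donors <- split(sh$register, paste(sh$chain_d, sh$donor))
  for (regs in donors) expect_setequal(regs, c(-3L, -4L))
})

test_that("a donor bonded to one acceptor only is not shared", {
  a <- analyze_structure(mk_helix(-49, -26))
  expect_true(all(a$bonds$register == -3L))
  expect_equal(attr(a$bonds, "shared_donors"), 0L)
  expect_false(any(a$bonds$shared))
})

test_that("helix assignment needs two consecutive helical bonds", {
  # minimal synthetic bond tables exercise the pattern rule directly
  mk_bonds <- function(donors, acceptors) {
    n <- length(donors)
    data.frame(chain_d = rep("A", n), donor = donors,
               chain_a = rep("A", n), acceptor = acceptors,
               interchain = FALSE,
               register = as.integer(acceptors - donors),
               d_ha = 2.0, d_da = 2.9, angle_dha = 155, angle_hac = 150,
               audit_fail = FALSE, category = NA_character_,
               segment = NA_integer_, shared = FALSE,
               stringsAsFactors = FALSE)
  }
  # i->i+3 followed by (i+1)->(i+4): shortest legal helix
  b <- mk_bonds(donors = c(9L, 10L), acceptors = c(6L, 6L))
  seg <- assign_helices(b)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 6L)
  expect_equal(seg$end, 10L)
  expect_equal(seg$flavor, "mixed")

  # a single isolated helical bond forms no segment and becomes a turn
  b1 <- mk_bonds(10L, 6L)
  expect_equal(nrow(assign_helices(b1)), 0L)
  expect_equal(classify_hbonds(b1)$category, "turn")

  # non-consecutive donors: still no segment
  b2 <- mk_bonds(c(6L, 9L), c(2L, 5L))
  expect_equal(nrow(assign_helices(b2)), 0L)
})

test_that("each helical fixture yields exactly one segment", {
  for (nm in c("alpha", "nhelix", "three10")) {
    a <- analyze_structure(mk_helix(TP[[nm]][1], TP[[nm]][2]))
    expect_equal(nrow(a$segments), 1L)
    expect_gte(a$segments$end - a$segments$start, 3L)
  }
  a <- analyze_structure(mk_helix(-120, 120))
  expect_equal(nrow(a$segments), 0L)
  # N-helix fixture: one segment spanning the interior, flavor mixed
  a <- analyze_structure(mk_helix(-62, -43))
  expect_equal(a$segments$flavor, "mixed")
  expect_lte(a$segments$start, 1L)
  expect_gte(a$segments$end, 12L)
})

test_that("no bond belongs to two segments", {
  s <- build_peptide(rep("ALA", 26L),
                     list(phi = c(rep(-62, 10), -120, -120, -80, -120,
                                  rep(-62, 12)),
                          psi = c(rep(-43, 10), 120, 120, 60, 120,
                                  rep(-43, 12))))
  a <- analyze_structure(s)
  expect_gte(nrow(a$segments), 2L)
  hel <- a$bonds[!is.na(a$bonds$segment), ]
  expect_true(all(table(paste(hel$chain_d, hel$donor, hel$acceptor)) == 1L))
})

test_that("sheet classification fires on a two-strand ladder", {
  # parallel two-strand fixture: an extended strand plus a translated
  # copy, positioned so the amide H of chain B residue 4 sits 1.9 A
  # beyond the carbonyl O of chain A residue 3 along the C=O direction
  # (the geometric ideal of a beta-ladder hydrogen bond)
  s1 <- place_amide_hydrogens(
    build_peptide(rep("ALA", 6L),
                  list(phi = rep(-119, 6), psi = rep(113, 6)),
                  caps = FALSE))
  at <- s1$atoms
  pick <- function(rs, nm) unlist(at[at$resseq == rs & at$name == nm,
                                     c("x", "y", "z")])
  u <- pick(3, "O") - pick(3, "C")
  u <- u / sqrt(sum(u^2))
  v <- (pick(3, "O") + 1.9 * u) - pick(4, "H")
  at2 <- at
  at2$chain <- "B"
  at2$x <- at2$x + v[1]; at2$y <- at2$y + v[2]; at2$z <- at2$z + v[3]
  s <- helixhb:::new_structure(rbind(at, at2))

  b <- classify_hbonds(detect_hbonds(s, hbond_criteria()))
  inter <- b[b$interchain, ]
  expect_gte(nrow(inter), 3L)
  expect_true(all(inter$category == "sheet"))
  # the alternating parallel-ladder pattern: donors step by 2
  bd <- sort(inter$donor[inter$chain_d == "B"])
  expect_true(all(diff(bd) == 2L))
})

test_that("detection is invariant under rigid motion and monotone in criteria", {
  s <- place_amide_hydrogens(mk_helix(-62, -43))
  b0 <- detect_hbonds(s)

  set.seed(99)
  R <- helixhb:::rotation_matrix(rnorm(3), 137)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 5; s2$atoms$y <- xyz[, 2] - 3
  s2$atoms$z <- xyz[, 3] + 11
  b1 <- detect_hbonds(s2)
  expect_equal(b1[c("donor", "acceptor", "register")],
               b0[c("donor", "acceptor", "register")])
  expect_equal(b1$d_ha, b0$d_ha, tolerance = 1e-9)

  # tightening any single criterion never increases the bond count
  base <- hbond_criteria()
  n0 <- nrow(b0)
  tighter <- list(hbond_criteria(max_ha = base$max_ha - 0.3),
                  hbond_criteria(max_da = base$max_da - 0.3),
                  hbond_criteria(min_dha = base$min_dha + 15),
                  hbond_criteria(min_hac = base$min_hac + 15))
  for (cr in tighter) expect_lte(nrow(detect_hbonds(s, cr)), n0)

  # and every returned bond satisfies the criteria it was found under
  expect_true(all(b0$d_ha <= base$max_ha & b0$d_da <= base$max_da &
                    b0$angle_dha >= base$min_dha &
                    b0$angle_hac >= base$min_hac))
})

test_that("classical criteria separate the alpha and 3-10 registers", {
  strict <- hbond_criteria(max_ha = 2.5)
  a <- analyze_structure(mk_helix(-57, -47), strict)
  n_alpha <- sum(a$bonds$category == "alpha")
  n_310 <- sum(a$bonds$category == "three_ten")
  expect_gt(n_alpha, n_310)

  a2 <- analyze_structure(mk_helix(-49, -26), strict)
  expect_gte(sum(a2$bonds$category == "three_ten"),
             sum(a2$bonds$category == "alpha"))

  # criteria-independent direction: i+4 bonds are the short, straight
  # ones on the alpha fixture, while the 3-10 fixture has no i+4 at all
  ap <- analyze_structure(mk_helix(-57, -47))
  d4 <- mean(ap$bonds$d_ha[ap$bonds$register == -4L])
  d3 <- mean(ap$bonds$d_ha[ap$bonds$register == -3L])
  expect_lt(d4, d3)
})

test_that("strict audit keeps near-miss bonds as disallowed", {
  s <- place_amide_hydrogens(mk_helix(-62, -43))
  crit <- hbond_criteria(min_hac = 95)  # pushes i->i+3 (HAC ~91) below cutoff
  b_plain <- find_shared(classify_hbonds(detect_hbonds(s, crit)))
  b_audit <- find_shared(classify_hbonds(
    detect_hbonds(s, crit, strict_audit = TRUE)))
  expect_false(any(b_plain$category == "disallowed"))
  expect_gt(sum(b_audit$category == "disallowed"), 0L)
  expect_equal(sum(!b_audit$audit_fail), nrow(b_plain))
})
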