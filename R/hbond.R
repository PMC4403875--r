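# Geometric detection and classification of backbone hydrogen bonds,
# three-centered (bifurcated) bond identification, and helix assignment
# from i->i+3 / i->i+4 bond patterns.
#
# Register convention: a bond is stored with register = acceptor residue
# number minus donor residue number, so the alpha-helical i->i+4 bond
# (carbonyl of residue i accepting from the amide of residue i+4) has
# register -4 and the 3_10 bond register -3.  Reports use the field's
# "i->i+k" arrow, i.e. k = -register.

HELICAL_REGISTERS <- c(-3L, -4L)

#' Geometric criteria for backbone hydrogen bonds
#'
#' Permissive cutoffs suited to the solvent-shielded, sterically
#' constrained interior of a protein helix: a hydrogen bond is any amide
#' N-H / carbonyl O pair within the two distance cutoffs whose donor and
#' acceptor angles are on the bonding side of planarity.  No exclusivity
#' is imposed, so one donor may bond several acceptors.  The default
#' H...O cutoff of 3.0 Angstrom is deliberately looser than the
#' classical 2.5 Angstrom HBPLUS value: the longer, bent i->i+3 member
#' of a three-centered helical bond sits near 2.7-3.0 Angstrom, so the
#' strict cutoff blinds a survey to exactly the bonds of interest.  Pass
#' `max_ha = 2.5` for the strict classical behaviour.
#'
#' @param max_ha Maximum H...O distance, Angstrom (default 3.0;
#'   classical strict value 2.5).
#' @param max_da Maximum N...O distance, Angstrom (default 3.9).
#' @param min_dha Minimum N-H...O angle at H, degrees (default 90).
#' @param min_hac Minimum H...O=C angle at O, degrees (default 90).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_ha = 3.0, max_da = 3.9,
                           min_dha = 90, min_hac = 90) {
  stopifnot(max_ha > 0, max_ha < max_da,
            min_dha >= 0, min_dha <= 180, min_hac >= 0, min_hac <= 180)
  structure(list(max_ha = max_ha, max_da = max_da,
                 min_dha = min_dha, min_hac = min_hac),
            class = "hbond_criteria")
}

empty_bonds <- function() {
  data.frame(chain_d = character(), donor = integer(),
             chain_a = character(), acceptor = integer(),
             interchain = logical(), register = integer(),
             d_ha = numeric(), d_da = numeric(),
             angle_dha = numeric(), angle_hac = numeric(),
             audit_fail = logical(), category = character(),
             segment = integer(), shared = logical(),
             stringsAsFactors = FALSE)
}

#' Detect backbone hydrogen bonds
#'
#' Enumerates all amide N-H donors (residues carrying a placed H;
#' proline and chain starts have none) against all backbone carbonyl
#' C=O acceptors, including ACE-cap acceptors and NME-cap donors, and
#' keeps every pair satisfying all four criteria.  Same-chain pairs
#' separated by fewer than two residues are excluded as covalent
#' neighbours.  Multiple bonds per donor are allowed; three-centered
#' bonds emerge naturally.
#'
#' @param structure A `helix_structure` with amide hydrogens present
#'   (see [place_amide_hydrogens()]).
#' @param criteria An [hbond_criteria()] object.
#' @param strict_audit Also return near-miss bonds that pass both
#'   distance cutoffs but fail an angle cutoff by less than 10 degrees,
#'   flagged `audit_fail = TRUE` (they are later categorised
#'   "disallowed").
#' @return Data frame of bonds (uncategorised): donor/acceptor identity,
#'   register, geometry, audit flag.
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria(),
                          strict_audit = FALSE) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  rf <- residue_frames(structure)
  has_h <- !vapply(rf$H, is.null, logical(1))
  if (!any(has_h))
    stop("structure has no amide hydrogens; run place_amide_hydrogens() first",
         call. = FALSE)
  don <- which(has_h & !vapply(rf$N, is.null, logical(1)) &
                 rf$resname != "PRO")
  acc <- which(!vapply(rf$O, is.null, logical(1)) &
                 !vapply(rf$C, is.null, logical(1)))
  if (!length(don) || !length(acc)) return(empty_bonds())

  rows <- list()
  for (i in don) {
    Np <- rf$N[[i]]; Hp <- rf$H[[i]]
    for (j in acc) {
      same_chain <- rf$chain[i] == rf$chain[j]
      if (same_chain && abs(rf$resseq[j] - rf$resseq[i]) < 2L) next
      Op <- rf$O[[j]]
      d_da <- vnorm(Op - Np)
      if (d_da > criteria$max_da) next
      d_ha <- vnorm(Op - Hp)
      if (d_ha > criteria$max_ha) next
      a_dha <- bond_angle(Np, Hp, Op)
      a_hac <- bond_angle(Hp, Op, rf$C[[j]])
      pass <- a_dha >= criteria$min_dha && a_hac >= criteria$min_hac
      near <- !pass &&
        a_dha >= criteria$min_dha - 10 && a_hac >= criteria$min_hac - 10
      if (!pass && !(strict_audit && near)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chain_d = rf$chain[i], donor = rf$resseq[i],
        chain_a = rf$chain[j], acceptor = rf$resseq[j],
        interchain = !same_chain,
        register = if (same_chain) rf$resseq[j] - rf$resseq[i] else NA_integer_,
        d_ha = d_ha, d_da = d_da, angle_dha = a_dha, angle_hac = a_hac,
        audit_fail = !pass, category = NA_character_,
        segment = NA_integer_, shared = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_bonds())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

is_helical_bond <- function(bonds) {
  !bonds$interchain & !bonds$audit_fail &
    bonds$register %in% HELICAL_REGISTERS
}

#' Assign helices from the hydrogen-bond pattern
#'
#' A helix is a maximal run of consecutive helical hydrogen bonds:
#' donors at consecutive residues, each donating an i->i+3 or i->i+4
#' bond (register -3/-4).  At least two consecutive bonds are required,
#' so the shortest helix is i->i+3 followed by (i+1)->(i+4).  Segment
#' flavor is `alpha` when all member registers are -4, `three_ten` when
#' all are -3, `mixed` otherwise.
#'
#' @param bonds Bond table from [detect_hbonds()].
#' @return Data frame of segments: `segment`, `chain`, `start`, `end`
#'   (residue numbers spanned, acceptor of the first bond to donor of
#'   the last), `flavor`, `n_bonds`.
#' @export
assign_helices <- function(bonds) {
  seg_empty <- data.frame(segment = integer(), chain = character(),
                          start = integer(), end = integer(),
                          flavor = character(), n_bonds = integer(),
                          stringsAsFactors = FALSE)
  hel <- bonds[is_helical_bond(bonds), , drop = FALSE]
  if (nrow(hel) == 0L) return(seg_empty)

  segs <- list()
  for (ch in unique(hel$chain_d)) {
    donors <- sort(unique(hel$donor[hel$chain_d == ch]))
    run_id <- cumsum(c(1L, diff(donors) != 1L))
    for (r in unique(run_id)) {
      dr <- donors[run_id == r]
      if (length(dr) < 2L) next
      b <- hel[hel$chain_d == ch & hel$donor %in% dr, , drop = FALSE]
      regs <- unique(b$register)
      flavor <- if (identical(regs, -4L)) "alpha"
                else if (identical(regs, -3L)) "three_ten"
                else "mixed"
      segs[[length(segs) + 1L]] <- data.frame(
        segment = length(segs) + 1L, chain = ch,
        start = min(b$acceptor), end = max(b$donor),
        flavor = flavor, n_bonds = nrow(b), stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) return(seg_empty)
  do.call(rbind, segs)
}

#' Classify detected hydrogen bonds
#'
#' Applies a deterministic category ladder: (1) helical-register bonds
#' (-3/-4) whose donor lies inside an assigned helix become
#' `three_ten`/`alpha`; (2) long-range (|register| >= 5) or interchain
#' bonds supported by a neighbouring ladder-consistent bond become
#' `sheet`; (3) isolated helical-register bonds become `turn`;
#' (4) register +/-2 bonds become `bend`; (5) everything else
#' intrachain becomes `coil`; (6) audit near-misses (strict mode only)
#' are `disallowed`.  Every bond receives exactly one category.
#'
#' @param bonds Bond table from [detect_hbonds()].
#' @param segments Optional segment table from [assign_helices()];
#'   computed when omitted.
#' @return The bond table with `category` and `segment` filled in.
#' @export
classify_hbonds <- function(bonds, segments = NULL) {
  if (nrow(bonds) == 0L) return(bonds)
  if (is.null(segments)) segments <- assign_helices(bonds)

  n <- nrow(bonds)
  cat <- rep(NA_character_, n)
  seg <- rep(NA_integer_, n)

  hel <- is_helical_bond(bonds)
  if (nrow(segments)) {
    for (k in seq_len(nrow(segments))) {
      s <- segments[k, ]
      in_seg <- hel & bonds$chain_d == s$chain &
        bonds$donor >= s$start & bonds$donor <= s$end &
        bonds$acceptor >= s$start & bonds$acceptor <= s$end
      seg[in_seg] <- s$segment
    }
  }
  cat[hel & !is.na(seg) & bonds$register == -4L] <- "alpha"
  cat[hel & !is.na(seg) & bonds$register == -3L] <- "three_ten"

  sheetish <- !bonds$audit_fail &
    (bonds$interchain | (!is.na(bonds$register) & abs(bonds$register) >= 5L))
  # Ladder support: a second long-range bond tying the same two strand
  # stretches together, within the 2-residue pleat period, in either
  # orientation (beta ladders alternate donor direction).
  cand <- which(sheetish & is.na(cat))
  for (i in cand) {
    others <- setdiff(which(sheetish), i)
    supported <- FALSE
    for (j in others) {
      same <- bonds$chain_d[j] == bonds$chain_d[i] &&
        bonds$chain_a[j] == bonds$chain_a[i] &&
        abs(bonds$donor[j] - bonds$donor[i]) <= 2L &&
        abs(bonds$acceptor[j] - bonds$acceptor[i]) <= 2L
      crossed <- bonds$chain_d[j] == bonds$chain_a[i] &&
        bonds$chain_a[j] == bonds$chain_d[i] &&
        abs(bonds$donor[j] - bonds$acceptor[i]) <= 2L &&
        abs(bonds$acceptor[j] - bonds$donor[i]) <= 2L
      if (same || crossed) {
        supported <- TRUE
        break
      }
    }
    if (supported) cat[i] <- "sheet"
  }

  cat[is.na(cat) & hel] <- "turn"
  cat[is.na(cat) & !bonds$audit_fail & !bonds$interchain &
        abs(bonds$register) == 2L] <- "bend"
  cat[is.na(cat) & !bonds$audit_fail] <- "coil"
  cat[bonds$audit_fail] <- "disallowed"

  bonds$category <- cat
  bonds$segment <- seg
  bonds
}

#' Flag three-centered (bifurcated) hydrogen bonds
#'
#' A donor N-H is three-centered when it simultaneously forms the two
#' helical bonds i->i+3 and i->i+4 (registers -3 and -4) and both are
#' classified helical (alpha/three_ten).  Both member bonds are flagged
#' `shared`.  Donors with two bonds that are not this helical pair are
#' generic bifurcations, counted in the `generic_bifurcations`
#' attribute but not flagged.
#'
#' @param bonds Categorised bond table from [classify_hbonds()].
#' @return The bond table with `shared` set; attribute
#'   `shared_donors` (count of three-centered donors) and
#'   `generic_bifurcations`.
#' @export
find_shared <- function(bonds) {
  if (nrow(bonds) == 0L) {
    attr(bonds, "shared_donors") <- 0L
    attr(bonds, "generic_bifurcations") <- 0L
    return(bonds)
  }
  helcat <- bonds$category %in% c("alpha", "three_ten")
  key <- paste(bonds$chain_d, bonds$donor, sep = "\r")
  shared_donors <- 0L
  for (k in unique(key)) {
    idx <- which(key == k & helcat)
    if (length(idx) >= 2L && all(c(-3L, -4L) %in% bonds$register[idx])) {
      bonds$shared[idx] <- TRUE
      shared_donors <- shared_donors + 1L
    }
  }
  multi <- table(key[!bonds$audit_fail])
  attr(bonds, "shared_donors") <- shared_donors
  attr(bonds, "generic_bifurcations") <-
    sum(multi >= 2L) - shared_donors
  bonds
}

#' Full hydrogen-bond analysis of one structure
#'
#' Convenience pipeline: place amide hydrogens when absent, detect
#' bonds, assign helices, classify, and flag three-centered bonds.
#'
#' @inheritParams detect_hbonds
#' @return List with `bonds` (categorised, shared flagged), `segments`,
#'   and `torsions` (from [backbone_torsions()]).
#' @export
analyze_structure <- function(structure, criteria = hbond_criteria(),
                              strict_audit = FALSE) {
  if (!any(structure$atoms$name == "H"))
    structure <- place_amide_hydrogens(structure)
  bonds <- detect_hbonds(structure, criteria, strict_audit = strict_audit)
  segments <- assign_helices(bonds)
  bonds <- find_shared(classify_hbonds(bonds, segments))
  list(bonds = bonds, segments = segments,
       torsions = backbone_torsions(structure))
}
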