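# Backbone torsion measurement, amide-hydrogen placement, and the
# internal-coordinate builder for ideal capped oligopeptides.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "AIB")

# Chain-break rule: a peptide bond is only assumed when the C(i)-N(i+1)
# distance is short and the Calpha separation is physically plausible.
BREAK_CN <- 2.0   # Angstrom
BREAK_CACA <- 4.5 # Angstrom

#' Covalent backbone geometry sets
#'
#' Bond lengths and angles used by the peptide builder.  `"engh_huber"`
#' carries standard crystallographic restraint values; `"pauling"` is the
#' classical model geometry with a 110 degree N-CA-C angle, provided
#' because residues-per-turn is sensitive to the tetrahedral angle at the
#' alpha carbon and the closed-form winding equations embed that older
#' covalent geometry.
#'
#' @param name `"engh_huber"` or `"pauling"`.
#' @return Named list of bond lengths (Angstrom) and angles (degrees).
#' @export
geometry_set <- function(name = c("engh_huber", "pauling")) {
  name <- match.arg(name)
  g <- switch(name,
    engh_huber = list(
      b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
      b_n_h = 1.00, b_ca_cb = 1.521,
      a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
      a_ca_c_o = 120.8, a_n_ca_cb = 110.4),
    pauling = list(
      b_n_ca = 1.47, b_ca_c = 1.53, b_c_n = 1.32, b_c_o = 1.24,
      b_n_h = 1.00, b_ca_cb = 1.54,
      a_n_ca_c = 110.0, a_ca_c_n = 114.0, a_c_n_ca = 123.0,
      a_ca_c_o = 121.0, a_n_ca_cb = 109.5)
  )
  g$name <- name
  stopifnot(all(unlist(g[startsWith(names(g), "b_")]) > 0.8),
            all(unlist(g[startsWith(names(g), "b_")]) < 2.0),
            all(unlist(g[startsWith(names(g), "a_")]) > 90),
            all(unlist(g[startsWith(names(g), "a_")]) < 135))
  g
}

is_cap <- function(resname) resname %in% c("ACE", "NME")

peptide_bonded <- function(prev, cur) {
  # prev/cur are residue_frames rows (lists of coordinates)
  if (is.null(prev$C) || is.null(cur$N)) return(FALSE)
  if (vnorm(cur$N - prev$C) > BREAK_CN) return(FALSE)
  if (!is.null(prev$CA) && !is.null(cur$CA) &&
      vnorm(cur$CA - prev$CA) > BREAK_CACA) return(FALSE)
  TRUE
}

#' Backbone torsion angles of a structure
#'
#' Computes phi, psi and omega per residue with the IUPAC definitions:
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) = N(i)-CA(i)-C(i)-N(i+1),
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i) (the torsion of the amide bond
#' preceding residue i).  Angles are `NA` at termini, where backbone
#' atoms are missing, and across chain breaks (C-N distance above
#' 2.0 Angstrom or Calpha-Calpha above 4.5 Angstrom).  ACE/NME capping
#' groups serve as torsion neighbours but get no row of their own.
#'
#' @param structure A `helix_structure`.
#' @return Data frame with columns chain, resseq, icode, resname,
#'   phi, psi, omega (degrees).
#' @export
backbone_torsions <- function(structure) {
  rf <- residue_frames(structure)
  n <- nrow(rf)
  phi <- psi <- omega <- rep(NA_real_, n)
  row_list <- function(i) list(N = rf$N[[i]], CA = rf$CA[[i]], C = rf$C[[i]])
  for (i in seq_len(n)) {
    cur <- row_list(i)
    prev <- if (i > 1L && rf$chain[i - 1L] == rf$chain[i]) row_list(i - 1L) else NULL
    nxt <- if (i < n && rf$chain[i + 1L] == rf$chain[i]) row_list(i + 1L) else NULL
    has <- function(r, nm) !is.null(r) && !is.null(r[[nm]])

    if (!is.null(prev) && peptide_bonded(prev, cur)) {
      if (has(prev, "C") && has(cur, "N") && has(cur, "CA") && has(cur, "C"))
        phi[i] <- dihedral(prev$C, cur$N, cur$CA, cur$C)
      if (has(prev, "CA") && has(prev, "C") && has(cur, "N") && has(cur, "CA"))
        omega[i] <- dihedral(prev$CA, prev$C, cur$N, cur$CA)
    }
    if (!is.null(nxt) && peptide_bonded(cur, nxt) &&
        has(cur, "N") && has(cur, "CA") && has(cur, "C") && has(nxt, "N"))
      psi[i] <- dihedral(cur$N, cur$CA, cur$C, nxt$N)
  }
  out <- data.frame(chain = rf$chain, resseq = rf$resseq, icode = rf$icode,
                    resname = rf$resname, phi = phi, psi = psi, omega = omega,
                    stringsAsFactors = FALSE)
  out[!is_cap(out$resname), , drop = FALSE]
}

#' Place backbone amide hydrogens
#'
#' Adds an H atom to each amide nitrogen along the external bisector of
#' the C(i-1)-N(i)-CA(i) angle, in the amide plane, at `nh_length` from
#' N.  This is the standard sp2-planar construction for backbone N-H.
#' Prolines (no amide proton) and chain-start nitrogens (no preceding
#' carbonyl) receive no hydrogen.  Existing backbone H atoms are
#' replaced.
#'
#' @param structure A `helix_structure`.
#' @param nh_length N-H bond length in Angstrom (default 1.00).
#' @return A `helix_structure` with H atoms added.
#' @export
place_amide_hydrogens <- function(structure, nh_length = 1.00) {
  rf <- residue_frames(structure)
  at <- structure$atoms
  drop <- at$name == "H" & !(at$resname %in% "ACE")
  at <- at[!drop, , drop = FALSE]

  add <- list()
  for (i in seq_len(nrow(rf))) {
    if (rf$resname[i] %in% c("PRO", "ACE")) next
    if (is.null(rf$N[[i]]) || is.null(rf$CA[[i]])) next
    if (i == 1L || rf$chain[i - 1L] != rf$chain[i]) next
    prev <- list(C = rf$C[[i - 1L]], CA = rf$CA[[i - 1L]])
    cur <- list(N = rf$N[[i]], CA = rf$CA[[i]])
    if (is.null(prev$C) || !peptide_bonded(prev, cur)) next
    u1 <- vunit(prev$C - cur$N)
    u2 <- vunit(cur$CA - cur$N)
    h <- cur$N + nh_length * vunit(-(u1 + u2))
    add[[length(add) + 1L]] <- data.frame(
      serial = 0L, name = "H", altloc = "", resname = rf$resname[i],
      chain = rf$chain[i], resseq = rf$resseq[i], icode = rf$icode[i],
      x = h[1L], y = h[2L], z = h[3L], occ = 1, element = "H",
      stringsAsFactors = FALSE)
  }
  if (length(add)) {
    add <- do.call(rbind, add)
    add$serial <- max(at$serial) + seq_len(nrow(add))
    at <- rbind(at, add)
  }
  new_structure(at, entry_id = structure$entry_id,
                resolution = structure$resolution, method = structure$method,
                source_model = structure$source_model)
}

#' Build an ideal capped peptide from backbone torsions
#'
#' Constructs backbone coordinates (N, CA, C, O, CB for non-glycine, and
#' amide H) by sequential internal-coordinate chain extension at the
#' covalent geometry of a [geometry_set()].  With `caps = TRUE` an
#' N-terminal acetyl (ACE, residue 0) and C-terminal N-methylamide (NME)
#' are added, so that phi of the first and psi of the last residue are
#' realised and the termini can take part in hydrogen bonds.  The build
#' is deterministic and exact: recomputing [backbone_torsions()] on the
#' result reproduces the inputs to well below 1e-6 degrees.
#'
#' @param sequence Character vector of three-letter residue codes
#'   (e.g. `rep("ALA", 12)`).
#' @param torsions Data frame (or list) with numeric `phi`, `psi`,
#'   `omega` of the same length as `sequence`; `omega` defaults to 180
#'   when omitted.  `phi[1]` and `omega[1]` are used only when capped;
#'   `psi` of the last residue orients the C-terminal cap/carbonyl.
#' @param geometry A [geometry_set()] or its name.
#' @param caps Add ACE/NME capping groups (default `TRUE`).
#' @return A `helix_structure`.
#' @examples
#' helix <- build_peptide(rep("ALA", 12),
#'                        list(phi = rep(-62, 12), psi = rep(-43, 12)))
#' @export
build_peptide <- function(sequence, torsions,
                          geometry = geometry_set("engh_huber"),
                          caps = TRUE) {
  if (is.character(geometry)) geometry <- geometry_set(geometry)
  g <- geometry
  L <- length(sequence)
  if (L < 1L) stop("empty sequence", call. = FALSE)
  bad <- setdiff(sequence, AA3)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  tor <- as.data.frame(torsions, stringsAsFactors = FALSE)
  if (is.null(tor$omega)) tor$omega <- 180
  tor$omega[is.na(tor$omega)] <- 180
  if (nrow(tor) != L)
    stop("torsions must have one row per residue", call. = FALSE)

  atoms <- list()
  emit <- function(name, resname, resseq, p, element = substr(name, 1L, 1L)) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = length(atoms) + 1L, name = name, altloc = "",
      resname = resname, chain = "A", resseq = resseq, icode = "",
      x = p[1L], y = p[2L], z = p[3L], occ = 1, element = element,
      stringsAsFactors = FALSE)
  }

  N <- CA <- C <- vector("list", L)
  if (caps) {
    # Seed frame: ACE methyl carbon at origin, carbonyl carbon on +x.
    ch3 <- c(0, 0, 0)
    cac <- c(1.51, 0, 0)
    n1 <- cac + g$b_c_n * c(cos(deg2rad(180 - g$a_ca_c_n)),
                            sin(deg2rad(180 - g$a_ca_c_n)), 0)
    emit("CH3", "ACE", 0L, ch3)
    emit("C", "ACE", 0L, cac)
    N[[1L]] <- n1
    CA[[1L]] <- place_atom(ch3, cac, n1, g$b_n_ca, g$a_c_n_ca, tor$omega[1L])
    C[[1L]] <- place_atom(cac, n1, CA[[1L]], g$b_ca_c, g$a_n_ca_c, tor$phi[1L])
    o_ace <- place_atom(n1, ch3, cac, g$b_c_o, g$a_ca_c_o, 180)
    emit("O", "ACE", 0L, o_ace)
    prev_ca_like <- ch3
  } else {
    N[[1L]] <- c(0, 0, 0)
    CA[[1L]] <- c(g$b_n_ca, 0, 0)
    C[[1L]] <- CA[[1L]] + g$b_ca_c * c(cos(deg2rad(180 - g$a_n_ca_c)),
                                       sin(deg2rad(180 - g$a_n_ca_c)), 0)
    prev_ca_like <- NULL
  }

  for (i in seq_len(L)) {
    if (i > 1L) {
      N[[i]] <- place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                           g$b_c_n, g$a_ca_c_n, tor$psi[i - 1L])
      CA[[i]] <- place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                            g$b_n_ca, g$a_c_n_ca, tor$omega[i])
      C[[i]] <- place_atom(C[[i - 1L]], N[[i]], CA[[i]],
                           g$b_ca_c, g$a_n_ca_c, tor$phi[i])
      # carbonyl O of the previous residue, trans to the new amide N
      o <- place_atom(N[[i]], CA[[i - 1L]], C[[i - 1L]],
                      g$b_c_o, g$a_ca_c_o, 180)
      emit("O", sequence[i - 1L], i - 1L, o)
    }
    emit("N", sequence[i], i, N[[i]])
    emit("CA", sequence[i], i, CA[[i]])
    emit("C", sequence[i], i, C[[i]])
    if (!(sequence[i] %in% c("GLY"))) {
      cb <- place_atom(C[[i]], N[[i]], CA[[i]], g$b_ca_cb, g$a_n_ca_cb, -120)
      emit("CB", sequence[i], i, cb)
      if (sequence[i] == "AIB") {
        cb2 <- place_atom(C[[i]], N[[i]], CA[[i]], g$b_ca_cb, g$a_n_ca_cb, 120)
        emit("CB2", sequence[i], i, cb2, element = "C")
      }
    }
  }

  psi_L <- tor$psi[L]
  if (caps) {
    if (is.na(psi_L)) psi_L <- 180
    n_nme <- place_atom(N[[L]], CA[[L]], C[[L]], g$b_c_n, g$a_ca_c_n, psi_L)
    ch3_nme <- place_atom(CA[[L]], C[[L]], n_nme, 1.455, g$a_c_n_ca, 180)
    o_last <- place_atom(n_nme, CA[[L]], C[[L]], g$b_c_o, g$a_ca_c_o, 180)
    emit("O", sequence[L], L, o_last)
    emit("N", "NME", L + 1L, n_nme)
    emit("CH3", "NME", L + 1L, ch3_nme)
  } else if (!is.na(psi_L)) {
    o_last <- place_atom(N[[L]], CA[[L]], C[[L]], g$b_c_o, g$a_ca_c_o,
                         psi_L + 180)
    emit("O", sequence[L], L, o_last)
  }

  s <- new_structure(do.call(rbind, atoms), entry_id = "BULT",
                     method = "THEORETICAL MODEL")
  place_amide_hydrogens(s, nh_length = g$b_n_h)
}

#' Generate a synthetic archive of ideal-helix PDB files
#'
#' Builds one capped oligopeptide per entry of `spec` and writes it as a
#' PDB file whose REMARK 2 record carries the assigned nominal
#' resolution.  This stands in for a local directory of experimental
#' structures when exercising the survey pipeline.
#'
#' @param spec Data frame with columns `label`, `phi`, `psi`,
#'   `resolution`, and optionally `length` (residue count, default 12)
#'   and `resname` (default `"ALA"`).
#' @param out_dir Output directory (created if missing).
#' @param geometry A [geometry_set()] or its name.
#' @return Invisibly, the paths of the written files.
#' @export
generate_fixture_archive <- function(spec, out_dir,
                                     geometry = geometry_set("engh_huber")) {
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  if (nrow(spec) == 0L) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    return(invisible(character(0)))
  }
  if (anyDuplicated(spec$label))
    stop("duplicate labels in fixture spec", call. = FALSE)
  if (any(spec$resolution < 0 | spec$resolution >= 5))
    stop("nominal resolutions must lie in [0, 5)", call. = FALSE)
  if (is.null(spec$length)) spec$length <- 12L
  if (is.null(spec$resname)) spec$resname <- "ALA"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    L <- spec$length[i]
    s <- build_peptide(rep(spec$resname[i], L),
                       list(phi = rep(spec$phi[i], L),
                            psi = rep(spec$psi[i], L),
                            omega = rep(180, L)),
                       geometry = geometry)
    s$resolution <- spec$resolution[i]
    s$entry_id <- toupper(substr(spec$label[i], 1L, 4L))
    paths[i] <- file.path(out_dir, paste0(spec$label[i], ".pdb"))
    write_pdb(s, file = paths[i])
  }
  invisible(paths)
}
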