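# PDB-format reading/writing and the hierarchical structure model.
#
# The structure is held flat, bio3d-style: one data frame of atoms plus
# entry-level metadata.  Residue hierarchy is recovered on demand from
# (chain, resseq, icode) keys, which keeps parsing simple and fast.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

new_structure <- function(atoms, entry_id = "XXXX", resolution = NA_real_,
                          method = NA_character_, source_model = 1L) {
  stopifnot(is.data.frame(atoms))
  ord <- order(atoms$chain, atoms$resseq, atoms$icode, atoms$serial)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(entry_id = entry_id, resolution = resolution, method = method,
         source_model = source_model, atoms = atoms),
    class = "helix_structure"
  )
}

#' @export
print.helix_structure <- function(x, ...) {
  res <- if (is.na(x$resolution)) "n/a" else sprintf("%.2f A", x$resolution)
  nres <- nrow(unique(x$atoms[, c("chain", "resseq", "icode")]))
  cat(sprintf("<helix_structure> %s  resolution: %s  chains: %s  residues: %d  atoms: %d\n",
              x$entry_id, res,
              paste(unique(x$atoms$chain), collapse = ","),
              nres, nrow(x$atoms)))
  invisible(x)
}

empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), altloc = character(),
             resname = character(), chain = character(), resseq = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), element = character(),
             stringsAsFactors = FALSE)
}

#' Parse a PDB-format file or character stream
#'
#' Reads fixed-column ATOM records (PDB v3.3 dialect), the REMARK 2
#' nominal resolution, and the EXPDTA method line.  Only the first MODEL
#' of a multi-model entry is kept.  Alternate locations are resolved by
#' keeping, per atom, the conformer with the highest occupancy (ties
#' broken by the lexicographically first altloc identifier).  HETATM
#' records and waters are skipped: the model covers polymer ATOM records
#' only, which is all that backbone hydrogen-bond analysis needs.
#'
#' @param x Path to a PDB file, or a character vector of PDB lines
#'   (a single string containing newlines is also accepted).
#' @return A `helix_structure`: entry metadata plus an atom table with
#'   columns serial, name, altloc, resname, chain, resseq, icode,
#'   x, y, z, occ, element.
#' @seealso [write_pdb()], [assign_resolution_bin()]
#' @export
parse_pdb <- function(x) {
  lines <- as_pdb_lines(x)

  entry_id <- "XXXX"
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr)) {
    id <- trimws(substr(hdr[1L], 63L, 66L))
    if (nzchar(id)) entry_id <- id
  }

  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1L],
                    regexec("RESOLUTION\\.\\s+([0-9]+\\.?[0-9]*)\\s+ANGSTROM", rem2[1L]))[[1L]]
    if (length(m) == 2L) resolution <- as.numeric(m[2L])
  }

  method <- NA_character_
  exp <- grep("^EXPDTA", lines, value = TRUE)
  if (length(exp)) method <- trimws(substr(exp[1L], 11L, 79L))

  # first MODEL only
  model_no <- 1L
  imodel <- grep("^MODEL ", lines)
  if (length(imodel)) {
    iend <- grep("^ENDMDL", lines)
    stop_at <- if (length(iend)) iend[1L] else length(lines)
    model_no <- suppressWarnings(as.integer(substr(lines[imodel[1L]], 11L, 14L)))
    if (is.na(model_no)) model_no <- 1L
    lines <- lines[seq(imodel[1L], stop_at)]
  }

  sel <- grep("^ATOM  ", lines)
  if (length(sel) == 0L)
    stop("empty structure: no ATOM records found", call. = FALSE)
  al <- lines[sel]

  f <- function(from, to) substr(al, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    empty <- which(!nzchar(trimws(s)))
    if (length(empty) && what != "occupancy")
      bad <- sort(c(bad, empty))
    if (length(bad))
      stop(sprintf("malformed ATOM record (%s) at line %d: '%s'",
                   what, sel[bad[1L]], al[bad[1L]]), call. = FALSE)
    v
  }

  atoms <- data.frame(
    serial = as.integer(num(f(7L, 11L), "serial")),
    name = trimws(f(13L, 16L)),
    altloc = trimws(f(17L, 17L)),
    resname = trimws(f(18L, 20L)),
    chain = f(22L, 22L),
    resseq = as.integer(num(f(23L, 26L), "residue number")),
    icode = trimws(f(27L, 27L)),
    x = num(f(31L, 38L), "x"),
    y = num(f(39L, 46L), "y"),
    z = num(f(47L, 54L), "z"),
    occ = suppressWarnings(as.numeric(f(55L, 60L))),
    element = trimws(f(77L, 78L)),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in ATOM records", call. = FALSE)
  atoms$occ[is.na(atoms$occ)] <- 1
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$name[blank]), 1L, 1L)

  atoms <- atoms[!(atoms$resname %in% WATER_RESNAMES), , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty structure: no non-water ATOM records", call. = FALSE)

  # altloc resolution: highest occupancy, tie -> first altloc id
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]

  new_structure(atoms, entry_id = entry_id, resolution = resolution,
                method = method, source_model = model_no)
}

as_pdb_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1L && grepl("\n", x))
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}

#' Write a structure as PDB-format text
#'
#' Emits fixed-column ATOM records (coordinates to 3 decimals), a
#' REMARK 2 resolution line when the structure carries one, and TER/END
#' records.  `parse_pdb(write_pdb(s))` reproduces atom names, residue
#' numbering and coordinates.
#'
#' @param structure A `helix_structure`.
#' @param file Optional path; when given, lines are written there.
#' @return Character vector of PDB lines, invisibly when `file` is given.
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "helix_structure"))
  at <- structure$atoms
  if (nrow(at) == 0L) stop("cannot write an empty structure", call. = FALSE)
  if (any(nchar(at$name) > 4L))
    stop("atom name exceeds PDB field width (4 characters)", call. = FALSE)

  out <- character(0)
  out <- c(out, sprintf("HEADER    %-40s%9s   %4s", "SYNTHETIC/ANALYSIS", "", structure$entry_id))
  if (!is.na(structure$resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", structure$resolution))
  else
    out <- c(out, "REMARK   2 RESOLUTION. NOT APPLICABLE.")

  # PDB convention: names of 1-3 chars start in column 14; 4 chars in 13
  nm <- ifelse(nchar(at$name) >= 4L, at$name, paste0(" ", at$name))
  rec <- sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(at)), nm, at$altloc, at$resname, at$chain,
                 at$resseq, at$icode, at$x, at$y, at$z, at$occ, 0,
                 at$element)
  chains <- unique(at$chain)
  for (ch in chains) {
    idx <- which(at$chain == ch)
    out <- c(out, rec[idx], "TER")
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Standard half-Angstrom resolution bins
#'
#' Ten half-open bins `[low, high)` tiling 0-5 Angstrom, labelled
#' "0.00-0.49" ... "4.50-4.99" after the usual survey-table row labels.
#'
#' @return Data frame with columns `low`, `high`, `label`.
#' @export
resolution_bins <- function() {
  low <- seq(0, 4.5, by = 0.5)
  high <- low + 0.5
  data.frame(low = low, high = high,
             label = sprintf("%.2f-%.2f", low, high - 0.01),
             stringsAsFactors = FALSE)
}

#' Assign a nominal resolution to its survey bin
#'
#' Bins are half-open on the right, so 1.49 and 1.50 fall in different
#' bins.  Resolutions at or beyond the last bin edge, and absent (`NA`)
#' resolutions, map to `NA`.
#'
#' @param resolution Numeric vector of nominal resolutions in Angstrom
#'   (`NA` allowed).
#' @param bins Bin table from [resolution_bins()].
#' @return Character vector of bin labels (`NA` where unbinned).
#' @export
assign_resolution_bin <- function(resolution, bins = resolution_bins()) {
  stopifnot(all(bins$low < bins$high))
  if (any(resolution < 0, na.rm = TRUE))
    stop("negative resolution", call. = FALSE)
  idx <- findInterval(resolution, c(bins$low, bins$high[nrow(bins)]),
                      rightmost.closed = FALSE)
  idx[idx < 1L | idx > nrow(bins)] <- NA_integer_
  bins$label[idx]
}

# Per-residue backbone coordinate frame: one row per residue (ordered),
# with list-columns of named coordinates.  ACE/NME caps use CH3 as their
# CA-like atom so that torsions across the caps are well defined.
residue_frames <- function(structure) {
  at <- structure$atoms
  key <- paste(at$chain, at$resseq, at$icode, sep = "\r")
  ukey <- unique(key)
  first <- match(ukey, key)
  out <- data.frame(chain = at$chain[first], resseq = at$resseq[first],
                    icode = at$icode[first], resname = at$resname[first],
                    stringsAsFactors = FALSE)
  grab <- function(names_wanted) {
    lapply(ukey, function(k) NULL)
  }
  pick <- function(i, nm) {
    rows <- which(key == ukey[i] & at$name %in% nm)
    if (length(rows) == 0L) return(NULL)
    c(at$x[rows[1L]], at$y[rows[1L]], at$z[rows[1L]])
  }
  n <- length(ukey)
  out$N <- lapply(seq_len(n), pick, nm = "N")
  out$CA <- lapply(seq_len(n), pick, nm = c("CA", "CH3"))
  out$C <- lapply(seq_len(n), pick, nm = "C")
  out$O <- lapply(seq_len(n), pick, nm = "O")
  out$H <- lapply(seq_len(n), pick, nm = "H")
  out
}
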