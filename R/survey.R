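# Aggregation of per-structure hydrogen-bond classifications into
# resolution-binned survey tables, category reports, and Ramachandran
# density / Boltzmann pseudo-energy maps.

BOLTZMANN_KCAL <- 0.0019872  # kcal/mol/K

# Printed survey tables round half-up (e.g. 246901/718464 -> 34.37),
# whereas base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Survey table from per-bin hydrogen-bond counts
#'
#' Computes the derived percentage columns (two decimals, half-up
#' rounding) for a table of per-resolution-bin bond counts.  Rows with
#' zero total get zero percentages and `total_zero = TRUE`.
#'
#' @param counts Data frame with columns `bin`, `total`, `alpha`,
#'   `three_ten`, `sheet`, `shared` (integer counts).
#' @return The table with `pct_alpha`, `pct_three_ten`, `pct_sheet`,
#'   `pct_shared` and `total_zero` appended.
#' @export
survey_table <- function(counts) {
  need <- c("bin", "total", "alpha", "three_ten", "sheet", "shared")
  stopifnot(all(need %in% names(counts)))
  cnt <- c("total", "alpha", "three_ten", "sheet", "shared")
  stopifnot(all(vapply(counts[cnt], is.numeric, logical(1))),
            all(counts$total >= 0),
            all(counts[cnt] >= 0))
  tot <- ifelse(counts$total > 0, counts$total, NA_real_)
  for (col in c("alpha", "three_ten", "sheet", "shared")) {
    pct <- round_half_up(100 * counts[[col]] / tot, 2)
    counts[[paste0("pct_", col)]] <- ifelse(is.na(pct), 0, pct)
  }
  counts$total_zero <- counts$total == 0
  counts
}

#' Aggregate per-structure results into a resolution-binned survey
#'
#' Sums categorised bond counts per resolution bin and derives the
#' percentage columns.  Structures without a nominal resolution (or at
#' or beyond the last bin edge) are excluded.  With
#' `shared_double_count = TRUE` (default) three-centered bonds are
#' counted both in their register column (alpha or three_ten) and in
#' the shared column; with `FALSE` the register columns exclude shared
#' bonds.  The shared column itself counts three-centered donors.
#'
#' @param results List of per-structure results, each a list with
#'   elements `resolution` (numeric or NA) and `bonds` (categorised
#'   bond table from [analyze_structure()]).
#' @param bins Bin table from [resolution_bins()].
#' @param shared_double_count Counting convention flag (see above).
#' @return A [survey_table()] with one row per bin.
#' @export
tabulate_survey <- function(results, bins = resolution_bins(),
                            shared_double_count = TRUE) {
  acc <- data.frame(bin = bins$label, total = 0L, alpha = 0L,
                    three_ten = 0L, sheet = 0L, shared = 0L,
                    stringsAsFactors = FALSE)
  for (res in results) {
    lab <- assign_resolution_bin(res$resolution, bins)
    if (is.na(lab)) next
    b <- res$bonds
    b <- b[!b$audit_fail, , drop = FALSE]
    i <- match(lab, acc$bin)
    acc$total[i] <- acc$total[i] + nrow(b)
    keep <- if (shared_double_count) rep(TRUE, nrow(b)) else !b$shared
    acc$alpha[i] <- acc$alpha[i] + sum(b$category == "alpha" & keep)
    acc$three_ten[i] <- acc$three_ten[i] + sum(b$category == "three_ten" & keep)
    acc$sheet[i] <- acc$sheet[i] + sum(b$category == "sheet")
    nshared <- attr(res$bonds, "shared_donors")
    if (is.null(nshared))
      nshared <- length(unique(paste(b$chain_d, b$donor)[b$shared]))
    acc$shared[i] <- acc$shared[i] + nshared
  }
  survey_table(acc)
}

#' Category report over a set of classified bonds
#'
#' Summarises bond counts by category the way a survey of a small
#' curated set (e.g. neutron-diffraction structures) is reported:
#' counts for i->i+4, i->i+3, sheet, bends, turns, coils and disallowed
#' bonds, the helical total (i+4 plus i+3), the bifurcated
#' (three-centered donor) count, percentages of the grand total to one
#' decimal, and the bifurcated share of helical bonds.
#'
#' @param bonds Categorised bond table (from [analyze_structure()] or
#'   concatenated across structures), or `NULL` when `counts` is given.
#' @param counts Optional named list/vector of raw counts (`i4`, `i3`,
#'   `sheet`, `bends`, `turns`, `coils`, `disallowed`, `bifurcated`)
#'   to feed the percentage arithmetic directly.
#' @return List of class `category_report`: `counts`, `helical_total`,
#'   `grand_total`, `pct` (percent of grand total, 1 decimal),
#'   `pct_bifurcated_of_helical`.
#' @export
category_report <- function(bonds = NULL, counts = NULL) {
  if (is.null(counts)) {
    stopifnot(is.data.frame(bonds))
    shared_donors <- attr(bonds, "shared_donors")
    if (is.null(shared_donors))
      shared_donors <- length(unique(paste(bonds$chain_d, bonds$donor)[bonds$shared]))
    counts <- list(
      i4 = sum(bonds$category == "alpha"),
      i3 = sum(bonds$category == "three_ten"),
      sheet = sum(bonds$category == "sheet"),
      bends = sum(bonds$category == "bend"),
      turns = sum(bonds$category == "turn"),
      coils = sum(bonds$category == "coil"),
      disallowed = sum(bonds$category == "disallowed"),
      bifurcated = shared_donors)
  }
  counts <- as.list(counts)
  need <- c("i4", "i3", "sheet", "bends", "turns", "coils", "disallowed",
            "bifurcated")
  stopifnot(all(need %in% names(counts)))
  helical_total <- counts$i4 + counts$i3
  grand_total <- counts$i4 + counts$i3 + counts$sheet + counts$bends +
    counts$turns + counts$coils + counts$disallowed
  pct <- if (grand_total > 0) {
    vapply(counts[setdiff(need, "bifurcated")],
           function(x) round_half_up(100 * x / grand_total, 1), numeric(1))
  } else {
    stats::setNames(numeric(7L), setdiff(need, "bifurcated"))
  }
  pct_bif <- if (helical_total > 0)
    round_half_up(100 * counts$bifurcated / helical_total, 1) else 0
  structure(list(counts = counts, helical_total = helical_total,
                 grand_total = grand_total, pct = pct,
                 pct_bifurcated_of_helical = pct_bif),
            class = "category_report")
}

#' @export
print.category_report <- function(x, ...) {
  cat(sprintf("Total i to i+4 bonds: %d (%.1f%%)\n", x$counts$i4, x$pct[["i4"]]))
  cat(sprintf("Total i to i+3 bonds: %d (%.1f%%)\n", x$counts$i3, x$pct[["i3"]]))
  cat(sprintf("Total H-bonds in helices = %d\n", x$helical_total))
  cat(sprintf("Total sheet bonds: %d (%.1f%%)\n", x$counts$sheet, x$pct[["sheet"]]))
  cat(sprintf("Bonds at bends: %d (%.1f%%)  turns: %d (%.1f%%)  coils: %d (%.1f%%)\n",
              x$counts$bends, x$pct[["bends"]], x$counts$turns,
              x$pct[["turns"]], x$counts$coils, x$pct[["coils"]]))
  cat(sprintf("Disallowed bonds: %d (%.1f%%)\n", x$counts$disallowed,
              x$pct[["disallowed"]]))
  cat(sprintf("Grand total: %d\n", x$grand_total))
  cat(sprintf("Bifurcated H-bonds: %d (%.1f%% of helical)\n",
              x$counts$bifurcated, x$pct_bifurcated_of_helical))
  invisible(x)
}

#' Ramachandran occupancy grid
#'
#' Clusters (phi, psi) observations into square bins covering the
#' torsion torus.  Bins are centred on integer multiples of `bin_size`
#' (so the bin labelled -62 covers \[-62.5, -61.5) at the default
#' width): torsions of interest sit at round values, and centring the
#' bins on them keeps such observations away from bin edges.  Pairs
#' with an undefined member are dropped.
#'
#' @param phi,psi Numeric vectors of torsions in degrees.
#' @param bin_size Bin width in degrees; must divide 360 evenly
#'   (default 1).
#' @return Object of class `rama_grid`: `bin_size`, `occupancy` (matrix
#'   phi x psi, dimnames are bin centres), `n` (total observations),
#'   `mode` (centres of the modal bin), and `energy` (`NULL` until
#'   [boltzmann_energy()] fills it).
#' @export
rama_density <- function(phi, psi, bin_size = 1) {
  if (bin_size <= 0 || abs(360 / bin_size - round(360 / bin_size)) > 1e-9)
    stop("bin_size must divide 360 evenly", call. = FALSE)
  keep <- is.finite(phi) & is.finite(psi)
  phi <- phi[keep]; psi <- psi[keep]
  nb <- as.integer(round(360 / bin_size))
  centers <- seq(-180, 180 - bin_size, by = bin_size)
  idx <- function(x) {
    ctr <- floor((x + bin_size / 2) / bin_size) * bin_size  # nearest centre
    ctr <- ((ctr + 180) %% 360) - 180                       # wrap the torus
    match(ctr, centers)
  }
  occ <- matrix(0L, nb, nb, dimnames = list(phi = centers, psi = centers))
  if (length(phi)) {
    tab <- table(factor(idx(phi), levels = seq_len(nb)),
                 factor(idx(psi), levels = seq_len(nb)))
    occ[] <- as.integer(tab)
  }
  mode <- if (length(phi)) {
    w <- which(occ == max(occ), arr.ind = TRUE)[1L, ]
    c(phi = centers[w[1L]], psi = centers[w[2L]])
  } else c(phi = NA_real_, psi = NA_real_)
  structure(list(bin_size = bin_size, occupancy = occ,
                 n = length(phi), mode = mode, energy = NULL),
            class = "rama_grid")
}

#' Boltzmann pseudo-energy from an occupancy grid
#'
#' Converts bin occupancies to relative energies,
#' E = -kT ln(N_bin / N_max), so the modal bin sits at zero and rarer
#' bins climb in units of kT (kT = 0.0019872 kcal/mol/K times the
#' temperature).  Unoccupied bins are reported as `Inf`.  Because only
#' occupancy ratios enter, scaling all counts by a common factor leaves
#' the map unchanged.
#'
#' @param grid A `rama_grid` from [rama_density()].
#' @param temperature Temperature in Kelvin (default 300).
#' @return The grid with `energy` (kcal/mol) and `temperature` filled.
#' @export
boltzmann_energy <- function(grid, temperature = 300) {
  stopifnot(inherits(grid, "rama_grid"))
  occ <- grid$occupancy
  nmax <- max(occ)
  if (nmax == 0L) stop("all-zero occupancy grid", call. = FALSE)
  kT <- BOLTZMANN_KCAL * temperature
  e <- matrix(Inf, nrow(occ), ncol(occ), dimnames = dimnames(occ))
  pos <- occ > 0L
  e[pos] <- -kT * log(occ[pos] / nmax)
  grid$energy <- e
  grid$temperature <- temperature
  grid
}

#' Torsions of residues inside assigned helices
#'
#' Restricts a torsion table to residues covered by helix segments,
#' the population whose (phi, psi) density defines the helical
#' Ramachandran map.
#'
#' @param torsions Torsion table from [backbone_torsions()].
#' @param segments Segment table from [assign_helices()].
#' @return Subset of `torsions`.
#' @export
helical_torsions <- function(torsions, segments) {
  if (nrow(segments) == 0L) return(torsions[0L, , drop = FALSE])
  keep <- rep(FALSE, nrow(torsions))
  for (k in seq_len(nrow(segments)))
    keep <- keep | (torsions$chain == segments$chain[k] &
                      torsions$resseq >= segments$start[k] &
                      torsions$resseq <= segments$end[k])
  torsions[keep, , drop = FALSE]
}

#' Survey a directory of PDB files
#'
#' End-to-end pipeline: parses every `*.pdb` file in a directory,
#' analyses its hydrogen bonds, and aggregates a resolution-binned
#' survey table, an overall category report, and a Ramachandran grid of
#' helical-residue torsions.  Unparseable files are skipped with a
#' warning rather than aborting the survey.
#'
#' @param dir Directory containing PDB files.
#' @param criteria [hbond_criteria()] used for detection.
#' @param bins Bin table from [resolution_bins()].
#' @param shared_double_count Survey counting convention (see
#'   [tabulate_survey()]).
#' @param strict_audit Keep near-miss bonds as `disallowed` (see
#'   [detect_hbonds()]).
#' @param rama_scope `"helical"` (default) restricts the Ramachandran
#'   density to residues inside assigned helices; `"all"` uses every
#'   residue with defined torsions.
#' @param bin_size Ramachandran bin width, degrees.
#' @return List: `survey` (binned [survey_table()]), `report`
#'   ([category_report()]), `rama` ([rama_density()] grid), `bonds`
#'   (combined bond table with an `entry` column), `skipped`
#'   (file names that failed to parse).
#' @export
survey_archive <- function(dir, criteria = hbond_criteria(),
                           bins = resolution_bins(),
                           shared_double_count = TRUE,
                           strict_audit = FALSE,
                           rama_scope = c("helical", "all"),
                           bin_size = 1) {
  rama_scope <- match.arg(rama_scope)
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) stop("no PDB files in ", dir, call. = FALSE)
  results <- list()
  all_bonds <- list()
  phis <- psis <- numeric(0)
  skipped <- character(0)
  total_shared <- 0L
  for (f in files) {
    res <- tryCatch({
      s <- parse_pdb(f)
      c(analyze_structure(s, criteria, strict_audit = strict_audit),
        list(resolution = s$resolution))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("skipping %s: %s", basename(f), conditionMessage(res)),
              call. = FALSE)
      skipped <- c(skipped, basename(f))
      next
    }
    results[[length(results) + 1L]] <-
      list(resolution = res$resolution, bonds = res$bonds)
    b <- res$bonds
    if (nrow(b)) {
      b$entry <- sub("\\.pdb$", "", basename(f))
      all_bonds[[length(all_bonds) + 1L]] <- b
    }
    total_shared <- total_shared + attr(res$bonds, "shared_donors")
    tt <- if (rama_scope == "helical")
      helical_torsions(res$torsions, res$segments) else res$torsions
    phis <- c(phis, tt$phi)
    psis <- c(psis, tt$psi)
  }
  if (!length(results))
    stop("no parseable PDB files in ", dir, call. = FALSE)
  bonds <- if (length(all_bonds)) do.call(rbind, all_bonds) else empty_bonds()
  attr(bonds, "shared_donors") <- total_shared
  list(survey = tabulate_survey(results, bins, shared_double_count),
       report = category_report(bonds),
       rama = rama_density(phis, psis, bin_size = bin_size),
       bonds = bonds, skipped = skipped)
}
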