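---
title: "Backbone hydrogen-bond surveys and helical parameters with helixhb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone hydrogen-bond surveys and helical parameters with helixhb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixhb)
```

## The scientific problem

Protein helices are conventionally described by two classical models:
the alpha helix (i->i+4 backbone hydrogen bonds, about 3.6 residues per
turn) and the tighter 3~10~ helix (i->i+3 bonds, about 3 residues per
turn).  Both models assume each amide N-H donates a single, linear
hydrogen bond to one carbonyl oxygen.  High-resolution crystal
structures tell a subtler story: the amide N-H of a helical residue
often sits between *two* carbonyl oxygens, donating simultaneously to
the i+3 and i+4 acceptors — a three-centered (bifurcated) hydrogen
bond.  Because a coupled, crankshaft-like change of the backbone
torsions (phi, psi) can reorient the amide plane without moving the
alpha carbons, a helix can adopt torsions intermediate between the two
classical points while keeping the alpha-helical winding and rise.
Surveys of well-determined structures place the consensus helical
torsions near (phi, psi) = (-62, -43) rather than the canonical
(-57, -47).

`helixhb` implements the machinery needed to study this at the level of
coordinates: geometric hydrogen-bond detection (with no exclusivity
constraint, so three-centered bonds can emerge), helix assignment from
the bond pattern, resolution-binned survey statistics, Ramachandran
density and pseudo-energy maps, and the closed-form relations between
backbone torsions and helical parameters.  A deterministic
internal-coordinate peptide builder supplies ideal capped oligoalanine
fixtures, so the entire pipeline can be exercised without downloading
any structures.

## The model and its pieces

### Torsions to helical parameters

For a regular helix of planar trans amides, define
$s = (\phi + \psi)/2$ and $t = (\phi - \psi)/2$ (radians).  The
rotation per residue $\theta$ and rise per residue $d$ obey

$$\cos(\theta/2) = -0.817 \sin s + 0.045 \sin t,$$
$$d \sin(\theta/2) = -0.68 \cos t + 2.9 \cos s,$$

with residues per turn $n = 360/\theta$ and pitch $p = n d$.  The
numeric coefficients embed one fixed covalent geometry — the classical
model bond lengths and angles — which has two practical consequences.
First, the independent screw-axis oracle (below) agrees with these
equations most closely when peptides are built with the
`geometry_set("pauling")` values (tetrahedral angle 110 at the alpha
carbon); with modern restraint values (`"engh_huber"`, 111.2) the
agreement is looser but still within 0.1 residues per turn.  Second,
because $|-0.817 \sin s + 0.045 \sin t| \le 0.862$ for all real
angles, the formal domain error (no real $\theta$) can never trigger on
the real torsion plane; the error branch and the `valid` flag of
`parameter_surface()` exist for robustness, not because invalid cells
occur.  At (0, 0) the equations give $\theta = 180$, i.e. the $n = 2$
extended ribbon, smoothly.

```{r params}
helical_params(-57, -47)   # classical alpha helix
helical_params(-49, -26)   # 3_10 helix
helical_params(-62, -43)   # consensus helix: alpha-helical winding
```

The central geometric fact — that the consensus torsions keep the
alpha-helical parameters while the 3~10~ point does not — is directly
assertable: $n(-57,-47)$ and $n(-62,-43)$ agree within 0.01 residues
per turn, while $n(-49,-26)$ differs from both by more than 0.5.

### The screw-axis oracle

`fit_screw_axis()` provides an equation-free check: it superposes the
window of C-alpha atoms $i..i{+}w$ onto $i{+}1..i{+}w{+}1$ (Kabsch
rigid superposition via SVD), reads the rotation angle of the optimal
transform as the per-residue winding and the translation along the
rotation axis as the rise, and averages over window offsets.  The
default window of 4 steps (5 points) spans more than one alpha-helical
turn, the shortest stable choice.  On exact mathematical helices the
fit is correct to better than 1e-9 for any radius, winding and pitch;
on builder output it ties the closed form to actual coordinates.

### Hydrogen-bond detection and the three-centered bond

Detection is purely geometric, over backbone amide N-H donors and
carbonyl C=O acceptors (prolines donate nothing; an N-terminal acetyl
cap is an acceptor, a C-terminal N-methylamide cap a donor).  A bond is
any pair satisfying all four criteria:

| criterion | default | meaning |
|---|---|---|
| `max_ha`  | 3.0 A | H...O distance |
| `max_da`  | 3.9 A | N...O distance |
| `min_dha` | 90 deg | N-H...O angle at H |
| `min_hac` | 90 deg | H...O=C angle at O |

No exclusivity is imposed, so one donor may bond several acceptors and
three-centered bonds emerge rather than being postulated.  The H...O
default of 3.0 A is deliberately looser than the classical strict
2.5 A: on ideal helical geometry the longer, bent i->i+3 member of a
three-centered pair sits at 2.7-2.9 A (and refined experimental
helices show similar values), so the strict cutoff is blind to exactly
the bonds under study.  Both conventions matter scientifically: under
the strict 2.5 A criteria the classical pictures reappear (pure i->i+4
bonding at (-57,-47), pure i->i+3 at (-49,-26)), while the permissive
default reveals the bifurcation at and around the consensus torsions.
Every cutoff is a `hbond_criteria()` field, a config key and a CLI
flag.

Amide hydrogens, when absent (the usual case for X-ray coordinates),
are placed by `place_amide_hydrogens()` at 1.00 A from N along the
external bisector of the C(i-1)-N-CA angle, in the amide plane — the
standard sp2 construction.

### From bonds to helices and categories

Helices are assigned from the bond pattern alone: a maximal run of
consecutive donors each making an i->i+3 or i->i+4 bond, at least two
bonds long (the shortest helix is i->i+3 followed by (i+1)->(i+4)).
Categories are then assigned by a deterministic ladder: helical
register inside a segment (alpha / three_ten); long-range or
interchain bonds with ladder support (sheet); isolated helical
register (turn); register +/-2 (bend); the remainder (coil); and, in
strict-audit mode, near-misses that fail an angle cutoff by under 10
degrees (disallowed).  Ladder support means a second long-range bond
tying the same two strand stretches together within the two-residue
pleat period, in either donor orientation — beta ladders alternate
donor direction and step by two residues on a side, so a one-residue
neighbourhood would never fire on genuine sheets.

A donor is three-centered when it makes both helical bonds (i->i+3
and i->i+4) simultaneously; both member bonds are flagged `shared`.
Donors with two bonds that are not this helical pair are counted as
generic bifurcations but not flagged.

### Survey statistics

`tabulate_survey()` aggregates per-structure categorised bonds into the
ten half-open half-Angstrom resolution bins 0.00-0.49 ... 4.50-4.99
(structures without a nominal resolution are excluded), with
percentages computed per bin and rounded half-up to two decimals —
half-up because that is how the published tables this layout mirrors
were rounded (verified on their printed values: 246901/718464 gives
34.37).  Three-centered bonds are counted both in their register column
and in the shared column by default; `shared_double_count = FALSE`
switches to exclusive counting, since the published tables do not
determine the convention (their columns do not sum to the total either
way).  The shared column counts three-centered donors (one per
bifurcated N-H), which is the quantity whose share of helical bonds the
category report also exposes.

`rama_density()` clusters (phi, psi) pairs into 1-degree bins centred
on integer degrees (so an observation at exactly -62.00 sits mid-bin
rather than on an edge), restricted by default to residues inside
assigned helices; `boltzmann_energy()` converts occupancies to relative
pseudo-energies $E = -kT \ln(N/N_{max})$ with $kT$ at 300 K by default,
the modal bin pinned at zero and empty bins at `Inf`.  Only occupancy
ratios enter, so the map is invariant under rescaling all counts.

## The synthetic fixture generator

`build_peptide()` constructs ideal capped peptides by sequential
internal-coordinate (NeRF-style) chain extension: backbone N, CA, C,
carbonyl O (trans to the next amide nitrogen), CB on non-glycine
residues (improper torsion C-N-CA-CB = -120, the L configuration), and
amide hydrogens, with ACE/NME caps so that phi of the first and psi of
the last residue are realised and the termini can hydrogen-bond.  The
build is exact and deterministic: recomputing torsions on the output
reproduces the input angles to ~1e-13 degrees, which makes the
builder/torsion round-trip a sharp invariant rather than a tolerance
test.  `generate_fixture_archive()` writes a set of such helices as PDB
files with assigned nominal resolutions, standing in for a local
archive of experimental structures.

What these fixtures emulate — and what they do not.  They have exact
uniform torsions, ideal covalent geometry, no side chains beyond CB, no
thermal noise, no solvent, and every residue of a given fixture is
identical.  Consequently bond detection on them is all-or-nothing per
register: at the consensus torsions *every* interior donor is
three-centered under the default criteria, whereas real surveys find
bifurcation in a fraction of helical bonds (the neutron-set arithmetic
reproduced in the tests gives 18.5%).  Passing fixture-level tests
therefore demonstrates the correctness of the geometry, detection,
assignment and aggregation machinery — not the population statistics of
real archives, which depend on coordinate noise and conformational
heterogeneity the generator deliberately omits.

```{r pipeline}
helix <- build_peptide(rep("ALA", 12),
                       list(phi = rep(-62, 12), psi = rep(-43, 12)))
a <- analyze_structure(helix)
table(a$bonds$category)
attr(a$bonds, "shared_donors")   # three-centered donors
a$segments
```

## Numerical and design choices

* **Geometry sets.**  `"engh_huber"` (default): N-CA 1.458, CA-C 1.525,
  C-N 1.329, C=O 1.231, N-H 1.00 A; angles N-CA-C 111.2, CA-C-N 116.2,
  C-N-CA 121.7, CA-C=O 120.8 deg — standard crystallographic restraint
  values.  `"pauling"`: the classical model geometry (N-CA 1.47,
  CA-C 1.53, C-N 1.32, C=O 1.24 A; N-CA-C 110.0, CA-C-N 114.0,
  C-N-CA 123.0 deg), provided because residues-per-turn is sensitive to
  the alpha-carbon angle and the winding coefficients embed this older
  geometry.
* **Chain breaks.**  A peptide bond is assumed only when C(i)-N(i+1)
  <= 2.0 A and CA(i)-CA(i+1) <= 4.5 A; torsions are undefined across
  breaks, at termini and where backbone atoms are missing (undefined,
  not an error).
* **Angle units.**  Degrees at every interface; radians only inside
  trigonometric kernels.
* **PDB handling.**  Model 1 only; alternate locations resolved to the
  highest-occupancy conformer (ties to the lexicographically first
  altloc); HETATM records and waters skipped; REMARK 2 resolution and
  EXPDTA method retained; half-open resolution bins so each structure
  lands in exactly one row.  Insertion-coded residues order after their
  base number alphabetically.  These are the only "cleaning" steps
  applied.
* **Dipole formula.**  Two forms of the dipole-dipole interaction are
  exposed: the bare angular form
  $V = -\mu_1\mu_2(\cos\theta_{12} - 3\cos\theta_1\cos\theta_2)$ and
  the textbook form with the $+\mu_1\mu_2/r^3$ prefactor.  Minimising
  the angular factor over physically consistent coplanar arrangements
  drives the dipoles collinear (alignment at 0 or 180 degrees) — the
  classical argument for why monopole electrostatics favours linear
  hydrogen bonds.  Both forms are kept because the two sign/distance
  conventions appear in the literature; the angular conclusion is the
  same under either.
* **Ramachandran scope.**  The density uses per-residue torsions of
  residues inside assigned helices (switchable to all residues); using
  per-bond observations instead would weight doubly-bonded residues
  twice, and the per-residue convention is the cleaner population
  estimate.

## Problem sizes used in tests and the acceptance script

Fixtures are 12-residue capped oligoalanines (the size at which all
interior registers are populated and one segment spans the chain); the
oracle-vs-closed-form comparison sweeps phi in [-80, -45] by 5 and psi
in [-60, -20] by 5 (72 builds); the demonstration archive holds seven
entries spanning four resolution bins.  These sizes make every result
exactly reproducible in seconds while exercising each code path.

## Known limitations

* The builder produces ideal geometry only — no minimisation, so built
  torsions at a nominal point differ from what an energy model would
  relax them to.
* Side-chain and water-mediated hydrogen bonds are out of scope; the
  category ladder is a documented deterministic convention, not an
  attempt to reproduce any particular assignment program
  (energy-based assignment in the DSSP style is deliberately not
  used).
* Sheet detection requires ladder support and so misses isolated
  long-range bonds (they fall to coil), a conservative choice.
* The closed-form winding relations are valid for regular helices of
  planar trans amides with the embedded covalent geometry; they are
  not refit for other geometries (the screw-axis fit covers that
  case).
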