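---
title: "Methods: mimotope-guided conformational epitope mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mimotope-guided conformational epitope mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A phage-display random peptide library screened against a neutralizing
antibody yields a *mimotope*: a short peptide that mimics the antibody's
epitope without necessarily matching the antigen sequence exactly. To turn a
mimotope into a testable epitope hypothesis one must (i) locate the peptide
on the antigen sequence and (ii) decide, from the antigen's 3D structure,
which residues of the implicated patch are plausible antibody contacts —
solvent-exposed residues — as opposed to residues that merely stabilize the
patch from underneath. `epitomap` implements this workflow for antigens that
act as oligomers bound to receptors, the motivating case being the human
IFN-γ homodimer in complex with its receptor chains.

```{r, eval = FALSE}
library(epitomap)
aln <- align_overlap("TDFLRMMLQEER", "NGTLFLGILKNWKEESDR")
alignment_metrics(aln)   # 35.71% identity, 57.14% similarity
map_region(aln, 25)      # region 27-40, query gaps at 34-35
```

## Sequence stage: overlap alignment

The mimotope is aligned to the antigen with an end-gap-free ("overlap",
also called glocal) affine-gap dynamic program: the query must be fully
consumed, unaligned leading/trailing target residues are free, and an
internal gap of length $k$ costs $g_o + k\,g_e$ with defaults $g_o = 8$,
$g_e = 2$ on BLOSUM62. A pure local (Smith–Waterman) alignment would trim
terminal columns with negative scores and could not report the full mapped
span, which is the object of interest here.

Identity and similarity are computed over **all columns of the aligned
span, gap columns included**: identity counts exact matches, similarity
adds pairs with a strictly positive BLOSUM62 entry. This denominator
convention is what makes a 14-column span with 5 matches read 35.71%.

**Tie-breaking.** Overlap optima are frequently non-unique for 12-mers; in
particular a gapped long-span alignment can tie a gapless shorter one. Since
the purpose of the alignment is to delimit the candidate epitope patch, we
report, among co-optimal alignments, the one with the **longest aligned
span** (maximal antigen coverage), placing gaps leftmost; the traceback is
deterministic (diagonal preferred on ties). We considered the alternative
tie-break "fewest gap columns first" and rejected it: it collapses to the
shorter span and discards antigen residues that the scoring itself does not
disfavor.

A note on recovery: with $g_o = 8, g_e = 2$ a true single-residue deletion
in a 12-mer costs more than realigning without the gap, so heavily mutated
peptides are *not* expected to recover their generating alignment — the
optimum legitimately dominates it in score. The test suite asserts exactly
this (score dominance at 100% of seeds, exact recovery for gapless
mutation loads) rather than a recovery rate the scoring does not support.

## Structure stage

### Structure model

PDB files are read through `bio3d` and reduced to the package's
conventions: protein ATOM records only (waters/ligands dropped, common
modified residues such as MSE mapped to their parent), one conformer per
atom (highest occupancy, ties by altloc label), hydrogens retained but
flagged and excluded from all geometric criteria by default — crystal
structures of this resolution carry none, and every criterion below is
defined over heavy atoms. Author numbering and insertion codes are
preserved; numbering gaps (disordered termini) are simply absent and no
stage assumes contiguity.

### Solvent accessibility

Per-atom SASA uses sphere-point quadrature: each heavy atom carries a
deterministic Fibonacci-spiral point set (default 240 points) on its
solvent-expanded sphere (Bondi-type van der Waals radius + 1.4 Å probe);
the accessible fraction times the sphere area is the atom's SASA. The
spiral point set was chosen over random sampling for seed-free
reproducibility; at 240 points total SASA is converged to well under 3% of
the 960-point value, and per-residue values agree with an independent
reference implementation to under 1% at matched point counts.

Relative SASA divides the residue sum by a **theoretical maximum**
(Tien-style table, shipped as CSV). Burial classes: `< 10%` buried,
`> 25%` exposed, boundaries inclusive to `intermediate`. Accessibility is
computed in the *oligomer context* (for a homodimer: both chains present,
receptor chains excluded), so that residues covered by the partner chain
are counted as buried — which is exactly the evidence used to separate
surface epitope residues from scaffold residues.

### Interface criteria

* **Neighbors**: a residue of chain A neighbors chain B if any heavy-atom
  pair across the chains is **strictly** below 5.0 Å.
* **Hydrogen bonds**: typed heavy-atom donor–acceptor pairs at ≤ 3.5 Å.
  Typing comes from a fixed residue-template table (backbone N donor
  except proline, backbone O acceptor, side-chain roles per residue;
  histidine ring nitrogens both). No angular filter is applied: without
  modeled hydrogens a 0–180° window excludes nothing, so the operative
  criterion is distance, and donor antecedents are not well defined.

### Epitope groups

Burial and contact evidence combine into a total map: group 1 = exposed ∧
neighbor (prime antibody-contact candidates), group 2 = exposed ∧
¬neighbor, group 3 = (buried or intermediate) ∧ neighbor (scaffold),
group 0 = neither (added for totality). Candidates are ranked group 1
first, then by decreasing relative SASA, then receptor-contact membership,
then key — deterministic by construction.

### Energetics and affinity

Residue-fragment interaction energies use the standard decomposition
$\mathrm{IE} = E_{AB} - E_A - E_B$ with a pairwise nonbonded potential
(Lennard-Jones with Lorentz–Berthelot combination + Coulomb,
$k = 332.0636$ kcal·Å/(mol·e²), dielectric 1). Because the potential is
pairwise, IE equals the cross-fragment pair sum; the implementation
computes **both routes and asserts their agreement** on every call. The
parameter set is deliberately minimal and fully pinned in CSV (per-element
LJ terms; heavy-atom template charges whose per-residue sums equal formal
charges). Structures are analyzed as given — no minimization step — so IE
values are self-consistent relative quantities, not literal
molecular-mechanics energies; absolute magnitudes from minimization-based
protocols are out of scope by design.

Binding affinity uses a contact-based linear model: interface contacts at
5.5 Å classified by residue chemical class (charged D,E,K,R,H; polar
N,Q,S,T,Y,W,C; apolar rest) plus the percentage composition of the
non-interacting surface (complex residues with relative SASA ≥ 5% outside
the interface), with frozen published coefficients (intercept −15.9433).
$K_d = \exp(\Delta G / RT)$, $R = 1.9872\times10^{-3}$ kcal/(mol·K);
−9.5 kcal/mol at 298.15 K gives $1.1\times10^{-7}$ M.

Alanine substitution for comparison runs truncates the side chain to Cβ
without repacking — the simplest deterministic mutation operator; its
results should be read as perturbations of the wild-type structure, not as
modeled mutant structures.

## Synthetic fixtures and what they show

`make_synthetic_dimer()` builds two idealized parallel α-helices
(NeRF-placed backbone at φ = −57°, ψ = −47°, Cβ stubs plus one functional
side-chain atom for donor/acceptor types) at a controllable axis
separation, with optional exact-distance donor/acceptor pair placement.
Ground-truth labels come from independent code paths: naive all-pairs
distance scans for neighbors, construction for hydrogen bonds, and a
seeded random-point (Monte-Carlo) burial estimate — never from the
analysis modules. `make_mimotope_pair()` derives peptides from a region by
seeded substitutions/deletions with the true alignment attached.

What passing synthetic tests show: the geometric criteria, quadrature and
classification behave exactly as specified on controlled geometry. What
they do not show: performance on real side-chain rotamer diversity,
crystallographic noise, or genuinely disordered regions — the
structure-dependent checks against the IFN-γ dimer (PDB entry 1FG9) cover
that and require the user to supply the coordinate file locally
(`tests/testthat/data/1fg9.pdb`), as crystal-structure coordinates are not
redistributed with the package.

## Numerical choices and problem sizes

* Quadrature: 240 points/atom default (study condition); convergence and
  oracle tests run at 960.
* Distance comparisons: neighbors strict `<`, hydrogen bonds and interface
  selections inclusive `≤`, matching the stated criteria ("< 5 Å",
  "within 3.5 Å").
* Burial boundaries 10%/25% assigned to the intermediate class.
* Test problem sizes, chosen to exercise every criterion while keeping the
  default suite fast: 20-residue chains for the standard dimer fixture,
  14-residue chains across an 8-spec separation sweep, 40 enumeration
  pairs (length 3–5) for the alignment oracle, 25 seeds for the mimotope
  properties.

## Known limitations

* The forcefield is minimal by design; only relative, self-consistent
  energy comparisons are meaningful.
* The affinity model's NIS term uses the package's own SASA with a 5%
  exposure threshold; small systematic offsets against other SASA
  implementations propagate to ΔG at the ~0.1 kcal/mol scale.
* Overlap-alignment tie-breaking is a modeling choice; other software may
  report a co-optimal alignment with a different span at the same score.
* The synthetic generator produces stub side chains; template-charge
  neutrality holds for full residues, not stubs.
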