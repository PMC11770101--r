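---
title: "Methods: spatial lysine-cysteine distances and lactylation-site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial lysine-cysteine distances and lactylation-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactylKC)
```

## The scientific question

Nonenzymatic lysine D-lactylation by the glyoxalase-pathway thioester
S-D-lactoylglutathione (SLG) is believed to be catalysed by a nearby cysteine:
the thiol is first S-lactylated, then hands the lactyl group to a spatially
proximal lysine amine (S-to-N transfer). If that mechanism operates in cells,
lysines that carry the modification should sit closer to a cysteine thiol in
the folded structure than lysines in general. `lactylKC` provides the
computational side of that argument:

1. **KC distance.** For every lysine in a structure, the Euclidean distance
   (in Angstrom) from its epsilon-amino nitrogen (PDB atom `NZ`) to the
   spatially nearest cysteine thiol sulfur (atom `SG`), with the identity of
   that cysteine.
2. **Site quantification.** Label-free modification-site intensities
   \(I_{ij}\) (site \(j\), sample \(i\)) are converted to relative values
   \(R_{ij} = I_{ij} / \mathrm{mean}_i(I_{ij})\), optionally divided by the
   matching protein's relative value to remove protein-abundance effects,
   then summarised per site as a treated/control fold change with a
   replicate test and Benjamini-Hochberg adjustment. Sites are classified
   `up` / `down` / `unchanged` with default cut-offs fold change > 2.0 and
   adjusted p < 0.05.
3. **Flanking-sequence enrichment.** Position-specific amino-acid
   frequencies around modified lysines are contrasted with windows around
   all other proteome lysines (two-sided Fisher tests per position x residue
   cell), with dedicated counters for the short-range cysteine spacings
   K-x-C, C-x-x-K and C-x-x-x-K.
4. **Class comparison.** KC-distance distributions are compared between all
   lysines, modified lysines, upregulated modified lysines, and subcellular
   compartments, using two-sided Mann-Whitney tests.

A seeded synthetic-data generator stands in for proteome-scale structure
downloads and deposited mass-spectrometry data, so the full pipeline is
testable offline with exact ground truth.

## KC-distance computation

The structure reader consumes fixed-column PDB `ATOM` records. Policy
decisions, all configurable or documented:

* **First model only.** Multi-model (NMR-style) files contribute only their
  first `MODEL` block; predicted single-model structures are unaffected.
* **Alternate locations.** Among altloc conformers of one atom the
  highest-occupancy record wins; ties keep the first record in file order.
* **HETATM excluded.** Only polymer `ATOM` records are considered.
* **Residue numbering** is taken verbatim from the file. For predicted
  single-chain models this is the 1-based sequence position, which is what
  site tables use as the join key.
* **Chain scope.** By default the nearest-cysteine search is confined to the
  lysine's own chain, which is the correct scope for single-chain predicted
  models; `cross_chain = TRUE` searches all chains of experimental
  multi-chain entries.
* **No confidence filter by default.** A `min_plddt` threshold on the
  B-factor column is available for sensitivity analyses, but no filter is
  applied unless requested.
* **Disulfide-bonded cysteines are not excluded.** An oxidised thiol is not
  an available catalyst, so treating every `SG` equally can only shorten
  apparent KC distances; this is a documented caveat rather than a filter,
  because disulfide annotation is unreliable in predicted models.

Residues lacking the reference atom (truncated side chains) are skipped and
counted, never imputed. A lysine whose search scope contains no cysteine
sulfur gets a missing distance and is excluded from downstream
distributions. Ties between equidistant cysteines resolve to the lower
residue index. Distances are exact minima over all in-scope pairs -- the
test suite checks equality against an independent brute-force loop and
invariance under rigid-body transforms (tolerance 1e-6 A, well below the
0.001 A precision of PDB coordinate fields).

## Quantification model

The row mean in \(R_{ij}\) is taken over *observed* samples only. Intensity
zero is treated as non-detection (missing), the established label-free
convention: a mean over true zeros would conflate absence with abundance.
After normalization each site's observed relative values average exactly 1,
which makes the operation idempotent and invariant to rescaling a whole row
-- both properties are asserted in the tests to 1e-9.

Protein correction divides each site's \(R_{ij}\) by the parent protein's
relative value in the same sample; a site profile proportional to its
protein profile corrects to exactly 1 ("modification change fully explained
by expression"). Cells with a missing protein value become missing; sites
without protein-level quantification are dropped with a warning (or kept
uncorrected on request). Without a protein table the correction stage is
skipped and results are flagged uncorrected.

When several peptides cover one site, their corrected per-sample values are
aggregated by the median before testing -- robust to a single aberrant
peptide and neutral when profiles agree.

**Choice of replicate test.** With three replicates per group, per-site
variance estimates have ~4 degrees of freedom and an unmoderated t-test is
severely underpowered once multiplicity correction is applied: in our own
simulations at log2 noise sd 0.3 a planted 4-fold effect typically reaches a
raw Welch p of ~3e-3, which survives Benjamini-Hochberg across 1000 sites
only about half the time. The default test is therefore the empirical-Bayes
moderated t (limma) on log2 corrected values, the standard approach at this
replication level, which shares variance information across sites; a plain
Welch t-test remains available as `test = "welch"` and is cross-checked
against `stats::t.test`. Degenerate inputs (fewer than ten testable rows, or
zero residual variance everywhere, as in noise-free simulations) fall back
to the Welch path, where zero-variance rows with equal means report p = 1
and separated zero-variance rows report p = 0. Sites with fewer than two
observed values in either group are never assigned a p-value and are never
classified up or down. Adjustment is Benjamini-Hochberg across all tested
sites as a single family.

## Motif enrichment

Windows have half-width \(w = 6\) by default -- wide enough to cover the
C-x-x-x-K spacing with margin -- and positions outside the sequence are
boundary-marked and excluded from that position's totals, so N- and
C-terminal sites contribute only their observed flanks. The background is
the set of windows around every proteome lysine *not* in the foreground:
the contrast of interest is "modified versus ordinary lysine", not
"modified lysine versus arbitrary residue". Fisher tests use raw counts;
the displayed log2 enrichment adds a 0.5 pseudocount to all four cells of
the 2x2 table so that empty cells stay finite, and the identity
`fg == bg` gives exactly zero enrichment everywhere. `X` residues are
treated like boundaries (unknown, excluded from totals).

## Class comparison

Summaries (n, mean, median, quartiles) are reported for the classes as
defined: every lysine with a KC distance ("all-K"), identified modification
sites ("lacK"), sites classified up ("up-lacK"), and lacK sites per
compartment. Because lacK is a subset of all-K and up-lacK of lacK, a rank
test between a set and its own superset would compare overlapping samples;
the pairwise Mann-Whitney tests therefore run on the disjoint underlying
sets (modified vs unmodified lysines; upregulated vs non-upregulated sites)
while keeping the class labels in the output. Compartment contrasts are
naturally disjoint. Classes with fewer than three values are excluded from
testing and flagged; `wilcox.test` switches between the exact U distribution
(small tie-free samples) and the normal approximation as usual, and p-values
are BH-adjusted across the tested pairs. Sites with missing KC are excluded
from all distributions rather than imputed.

## The synthetic generator

The generator emulates exactly the features the analyses consume, with
exact ground truth, and nothing else:

* **Geometry.** The analysis only reads NZ and SG coordinates, so residues
  are pseudo-atoms: a C-alpha trace plus one NZ per lysine and one SG per
  cysteine. The default "extended" layout walks a cubic lattice whose
  spacing (80 A) guarantees that each lysine's designated partner cysteine
  -- whose SG is placed at a drawn target distance from the lysine's NZ --
  really is its nearest thiol (targets reach at most ~31 A; any two
  non-partner reference atoms are farther by construction). An ideal-helix
  trace (2.3 A radius, 1.5 A rise, 100 degrees per residue -- textbook
  values) and a random-packed layout are available for realism and for
  stress-testing the brute-force oracle with emergent, uncontrolled
  distances. The manifest's "true" distances are always recomputed from the
  emitted coordinates by direct all-pairs minimisation, so any geometric
  interference would be recorded, not hidden.
* **Sequences** draw residues independently with configurable lysine and
  cysteine frequencies (default 5% each; the elevated cysteine frequency
  keeps most lysines paired with a controllable partner). Per-lysine target
  KC distances are uniform on 2-25 A, shifted +6 A for nuclear proteins so
  that compartment comparisons have a planted effect to recover.
* **Site planting** marks each lysine with a defined KC distance as modified
  with probability \(1/(1+\exp((d-d_0)/s))\), \(d_0 = 10\) A, \(s = 3\) A --
  a smooth susceptibility decaying over roughly the distance range a
  tethered intramolecular transfer could plausibly reach -- or uniformly at
  a fixed rate for null runs. Upregulated status among planted sites uses a
  second logistic with midpoint 8 A, so upregulated sites are a
  shorter-distance subset.
* **Motif planting** rewrites the residue at a fixed offset from a fraction
  of planted sites to cysteine (never overwriting an existing K or C), and
  patches the corresponding structures so sequence and coordinates stay
  consistent; the realised truth of patched proteins is recomputed.
* **Intensities** are log-normal: per-site baseline uniform on 20-30 (log2
  scale, typical of label-free site intensities), plus the planted group
  effect (default log2 effect 2, i.e. 4-fold) for treated samples, plus
  Gaussian noise (default sd 0.3 on log2, ~20% CV), exponentiated. Dropout
  is completely at random (default 10%), with the guarantee that no site
  loses every observation.

What the generator does **not** emulate -- and what passing tests therefore
do not show about real data: intensity-dependent (left-censored) missingness
of real label-free data; correlated noise between sites on one protein;
real side-chain rotamers and packing (KC distances here are planted, not
emergent from folding); sequence composition biases; and structure-quality
heterogeneity (the pLDDT column is a constant placeholder). The worked
STAT1-like example ships as a *synthetic stand-in* structure (two chains,
decoy cysteines, the K193-C174 pair constructed at 19.0 A); it validates
the multi-chain parsing and nearest-thiol machinery end to end, not any
experimental coordinate set.

## Determinism and problem sizes

Every stochastic step is driven by an explicit integer seed
(`sim_config(seed = ...)`), and identical configuration plus seed yields
byte-identical files at every stage, which the test suite asserts at the
TSV level. The shipped checks run at sizes chosen to make their statistical
claims sharp while remaining quick on one CPU: 100 structures for the
brute-force equivalence; 1000 sites (100 planted 4-fold) for detection
power; 10000 null sites for the type-I band; 20 seeded runs for motif and
KC-ordering recovery; 100 seeded plantings for null safety of the
KC-distance comparison.

## Known limitations

* KC distance is a static proxy: no side-chain flexibility, solvent
  accessibility or thiol reactivity (pKa, oxidation state) enters the
  computation.
* Protein correction assumes the protein-level table is itself well
  normalised; systematic sample-loading effects cancel only to the extent
  they affect site and protein intensities equally.
* The moderated test borrows strength across sites and therefore assumes
  exchangeable variances on the log2 scale; strongly heteroscedastic data
  may prefer `test = "welch"` with more replicates.
* Compartment labels are taken from an input table as-is; no localization
  prediction is performed.
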