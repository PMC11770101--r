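# lactylKC

Structural context analysis of lysine D-lactylation sites.

## The problem

Nonenzymatic lysine D-lactylation by the glyoxalase-pathway thioester
S-D-lactoylglutathione (SLG) appears to be catalysed by a neighbouring
cysteine: the thiol is S-lactylated first and then passes the lactyl group
to a spatially close lysine amine. The testable structural prediction is
that modified lysines lie unusually close to a cysteine thiol in the folded
protein. `lactylKC` implements the computational pipeline behind that
argument, for proteomics/structural-bioinformatics users who have:

- a set of structures (PDB files, e.g. predicted single-chain models of a
  proteome),
- a label-free modification-site intensity table (MaxQuant-"Sites"-style
  TSV),
- optionally a protein-level intensity table and a subcellular-localization
  table.

## What it computes

**KC distance.** For every lysine in every structure, the Euclidean
distance (Å) from its ε-amino nitrogen (atom `NZ`) to the spatially nearest
cysteine thiol sulfur (atom `SG`), plus the identity of that cysteine:

    KC(j) = min over cysteines c of || NZ_j − SG_c ||

**Site quantification.** Raw intensities *I*<sub>ij</sub> (site *j*, sample
*i*) become relative values *R*<sub>ij</sub> = *I*<sub>ij</sub> /
mean<sub>i</sub>(*I*<sub>ij</sub>) (mean over observed samples; intensity 0
is treated as non-detection). Each site's *R* is optionally divided by the
parent protein's relative value to cancel expression changes; sites are then
tested treated vs control (moderated t on log2 values by default, Welch
optional), BH-adjusted, and classified `up` / `down` / `unchanged` at fold
change > 2.0 and adjusted p < 0.05.

**Motif enrichment.** Position-specific amino-acid enrichment around
modified lysines versus windows around all other proteome lysines
(two-sided Fisher per position × residue), with counters for the cysteine
spacings KxC, CxxK, CxxxK.

**Class comparison.** Mann-Whitney comparisons of KC-distance distributions
across all-K / lacK / upregulated-lacK classes and subcellular
compartments.

A seeded synthetic generator (`sim_config()`, `simulate_bundle()`) produces
structures, sequences, site tables and intensity matrices with exact ground
truth, so the whole pipeline runs and is tested fully offline.

## Worked example

The package ships a small **synthetic stand-in** structure with STAT1-like
lysine/cysteine numbering (two chains, decoy cysteines, K193 NZ constructed
19.0 Å from C174 SG — see the REMARK lines in the file; these are not
experimental coordinates):

```r
library(lactylKC)
f <- system.file("extdata", "stat1_1yvl_standin_synthetic.pdb", package = "lactylKC")
kc <- compute_kc_table(read_pdb(f))
subset(kc, chain == "A")
#>                    protein_id chain lys_position nearest_cys_chain nearest_cys_position kc_distance
#>  stat1_1yvl_standin_synthetic     A          145                 A                  140    22.00867
#>  stat1_1yvl_standin_synthetic     A          161                 A                  174    32.89014
#>  stat1_1yvl_standin_synthetic     A          193                 A                  174    18.99994
#>  stat1_1yvl_standin_synthetic     A          211                 A                  222    15.52307
#>  stat1_1yvl_standin_synthetic     A          240                 A                  246    23.75900
```

K193's nearest thiol is C174 at ~19 Å. On a full synthetic study bundle the
end-to-end analysis recovers the planted structure-modification
relationship:

```r
cfg <- sim_config(seed = 42, n_proteins = 40, motif_fraction = 0.5)
b   <- simulate_bundle(cfg)
q   <- quantify_sites(b$sites, b$design, proteins = b$proteins)
kcp <- compute_kc_proteome(b$proteome$structures)
cmp <- compare_kc_distributions(
         stratify_sites(kcp, annotate_sites_with_kc(q$table, kcp), b$localization))
cmp$summary
#>              class   n mean_kc median_kc   q25   q75
#>              all-K 404   55.34     18.57 10.55 28.69
#>               lacK  82    6.93      6.50  3.90  9.22
#>            up-lacK  44    5.39      4.67  3.37  7.93
#>       lacK:cytosol  68    6.57      6.32  3.72  8.90
#>  lacK:mitochondria   4    8.52      4.88  4.62  8.77
#>       lacK:nucleus   7    9.87      9.62  8.87 10.98
#>         lacK:other   3    6.27      4.21  3.27  8.24
```

Modified lysines (lacK, median 6.5 Å) sit far closer to a thiol than
lysines in general (18.6 Å), the upregulated subset closer still, and
nuclear sites farther than cytosolic ones — exactly the relationships the
generator planted (logistic susceptibility with midpoint 10 Å, scale 3 Å;
+6 Å nuclear shift). The pairwise Mann-Whitney tests put lacK vs all-K at
adjusted p ≈ 4e-36, and the planted flanking cysteine shows up as the
uniquely significant motif cell (position +2, i.e. KxC; log2 enrichment
3.4, adjusted p ≈ 3e-23).

The same stages run from the shell via the thin wrapper in
`inst/scripts/lactylkc`:

```sh
lactylkc simulate --seed 42 --n-proteins 40 --out bundle/
lactylkc run-all --structures bundle/structures --fasta bundle/proteome.fa \
  --sites bundle/sites.tsv --design bundle/design.tsv \
  --proteins bundle/proteins.tsv --loc bundle/localization.tsv --out results/
```

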