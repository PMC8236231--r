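---
title: "Methods: gene-family characterization with genefamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization with genefamr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

genefamr implements, as one reusable and fully testable pipeline, the
standard desk analysis by which plant transcription-factor gene families —
here modelled on the DREB (dehydration responsive element-binding) subfamily
of AP2/ERF regulators — are characterized genome-wide: candidate retrieval
by protein homology, domain-architecture and residue-conservation filtering,
physicochemical profiling, distance phylogenetics with subgroup assignment,
exon/intron and motif summaries, duplication-mode classification with Ka/Ks
dating, and cross-species synteny. This vignette records the models, the
parameters that matter, and the design decisions, in the order the pipeline
runs them.

## Identification

**Homology search.** Every reference (query) protein is aligned locally
against every target protein with BLOSUM62 and affine gaps (open 11,
extend 1). Significance uses the ungapped Karlin–Altschul form
$E = K\,m\,n\,e^{-\lambda S}$ on the raw score $S$, with the classic
ungapped BLOSUM62 constants $\lambda = 0.3176$, $K = 0.134$. This mirrors
the convention of the early gapped heuristics: the statistics are those of
the ungapped theory even though the alignment allows gaps, which keeps the
E-value a simple monotone transform of the score. The default cutoff is
$10^{-5}$. A target is a candidate when any query reaches the cutoff.

**Domain scan.** Instead of an external profile-HMM library, the AP2 domain
is modelled as a 54-column log-odds profile (PSSM) built from a packaged
seed alignment with the pseudocounted estimator
$\log_2\frac{(c + \alpha\,b)/(t+\alpha)}{b}$ per column (default
$\alpha = 1$; background $b$ a Swiss-Prot-like composition table). Columns
with more than half gaps are dropped. Scanning is *glocal*: the whole
profile must align against any substring of the protein, with affine gaps
on both sides (open −10, extend −1 bits), by dynamic programming with full
traceback. The traceback yields a profile-column → residue map, which is
what the conservation filter reads. Non-overlapping hits are collected
greedily best-first by rescanning the flanks of each accepted hit.

The profile's column numbering starts at the conserved YRG anchor of the
domain, which puts the diagnostic valine at column 14 and the glutamate at
column 19 — the numbering convention of the DREB literature. A protein is
accepted if and only if it has exactly one hit at or above the bit
threshold *and* column 14 of that hit is V; accepted proteins split into
V+E (column 19 = E) and V-only. Rejection reasons are `no_domain`,
`multiple_domains` and `not_V14`; a deletion (gap) at column 14 counts as
not-V. The default bit threshold of 25 sits far above the null: glocally
scanning shuffled proteins of realistic composition scores in the −55 to
−35 bit range (best deletion-heavy paths), while true domain regions score
90–160 bits, so the operating point is insensitive over tens of bits.

**Physicochemical profile.** Molecular weight is the sum of average residue
masses plus one water. The isoelectric point is the root of the net-charge
function built from Bjellqvist-style pKa values (N-terminus 7.5, C-terminus
3.55; side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0),
found by bisection on pH 0–14 to $|q| < 10^{-4}$. The charge function is
strictly decreasing in pH, so the root is unique and bisection cannot fail.
The tables are arguments, not constants, because public calculators differ
in their pKa sets.

## Phylogeny and subgroups

**Alignment.** The family plus the labelled reference panel are aligned by
a deterministic center-star procedure: the center is the sequence with the
highest summed pairwise global score (ties by lexicographic id), and the
other sequences are merged against it under "once a gap, always a gap". An
externally computed alignment can be substituted at any point — the
downstream steps only require equal-length gapped strings. Center-star is a
deliberate simplification relative to iterative refiners; for the dense,
indel-free families the generator produces it is essentially exact, and for
real data the substitution hook is the recommended path.

**Distances and tree.** Pairwise distances use pairwise deletion (only
columns ungapped in both sequences) and the Poisson correction
$d = -\ln(1-p)$. A saturated pair ($p = 1$) or a pair with no shared
columns is an error, not a silent NA. The tree is Saitou–Nei neighbor
joining with the usual Q criterion; ties are broken by the
lexicographically smallest pair of cluster labels so the output is
deterministic. Negative branch-length estimates are clamped to zero with
the deficit moved to the sibling edge, the display convention of common
phylogenetics GUIs; on additive inputs no clamping ever triggers and the
tree reproduces topology and path lengths exactly (a property the test
suite checks against 200 random additive matrices and, for quartets, an
exhaustive three-topology least-squares oracle).

**Bootstrap.** Columns are resampled with replacement; each replicate
rebuilds distances and the NJ tree; supports are the percentage of
replicates containing each non-trivial bipartition of the full-data tree.
Replicates with undefined distances are discarded (more than 10% discarded
is an error). The study parameterization is 1,000 replicates; the
packaged test and acceptance runs use 200, which bounds the Monte Carlo
standard error of a support value by about 3.5 points and leaves the
recovery checks (which do not read supports) unchanged.

**Subgroup assignment.** For each query leaf, the smallest edge-induced
split side containing the query and at least one reference decides: if all
references in it carry one label, that label is assigned (`clade`);
otherwise the patristically nearest reference decides (`nearest`, ties by
id). The fallback is this package's explicit rule for clades that contain
no reference or mixed references — the situation the A6-like subgroup
creates when family members resemble each other more than any reference.

## Gene structure and motifs

Intron phases are the cumulative coding length upstream of each intron
modulo 3, computed in transcription order (gene models are CDS-only, so
every exon base is coding). Phase 0/1/2 therefore means the intron falls
between codons, after the first, or after the second base of a codon.

Motif discovery is expectation-maximization under the ZOOPS model (zero or
one occurrence per sequence): the E-step computes, per sequence, a
posterior over "no site" and every window offset; the M-step re-estimates
the position-weight matrix (pseudocount 0.25 toward the input-estimated
background) and the site prior. Within one width the objective is the
ZOOPS log-likelihood and is non-decreasing across iterations (asserted in
tests). Width is searched over a grid (default 6, 9, …, 48, 50 — the
bounds of the study's 6–50 setting) and chosen by the occurrence
log-likelihood ratio under a BIC-type penalty of $\tfrac{19}{2}\log
n_{\text{sites}}$ per column (19 free frequencies per column). A flat
penalty of one $\log(\text{total windows})$ per column — about 9.5 nats
here — almost exactly equals the overfitting gain of fitting a random
column, which leaves motif boundaries to chance; the BIC form keeps
boundaries where the information is.
Initialization matters: EM restarts seed from the most frequent exact
w-mers in the data (conserved and planted sites leave many identical
copies) plus seeded random windows, which reliably locks the register of a
true motif instead of a shifted local optimum. Discovered sites are
hard-masked and discovery repeats up to 15 motifs or until the penalized
ratio falls below the floor (default 0). Per-protein occurrences are then
re-scanned with a floor of half of each motif's consensus score — well
below the score of a site with a few corrupted columns, and above the
best background window.

## Duplications, Ka/Ks and synteny

**Tandem rule.** Two family genes on one chromosome with at most five
intervening gene loci are tandem; intervening loci are counted over *all*
annotated genes (rank difference minus one), the most natural reading of
"gene loci", with a family-only variant available as an option.

**Collinearity.** Homolog pairs come from a two-stage search (trimer cosine
prefilter, then local-alignment verification with the same E-value model as
identification). Pairs are anchors on the gene-rank grid; per chromosome
pair and orientation, chains that are strictly monotone on both sides with
consecutive rank gaps of at most 25 are extracted best-first by dynamic
programming; chains shorter than 5 anchors are dropped and each anchor
joins at most one block. The 5-anchor / 25-gap defaults are the
conventions of MCScanX-class tools. Within-genome blocks define segmental
duplicates: a family pair that is a block anchor and not already tandem is
segmental (tandem has priority, mirroring the usual classification order).

**NG86.** Synonymous sites are counted fractionally — per codon position,
the fraction of the three single-base changes that are synonymous, with
changes to stop codons counted as nonsynonymous so that $S + N$ is exactly
three per codon — and averaged between the two sequences. Differences
between codons differing at $k$ positions are averaged over all $k!$
substitution pathways that avoid stop codons. Both proportions are
Jukes–Cantor corrected, $d = -\tfrac34\ln(1 - \tfrac43 p)$; $p \ge 3/4$ is
a saturation error. $\omega = K_a/K_s$ is defined only when $K_s > 0$.
Codons gapped in either sequence are excluded entirely. The implementation
is checked to $10^{-9}$ against an independent brute-force
pathway-enumeration oracle over all 61 × 61 sense-codon pairs.

**Dating.** $T = K_s / (2 \times 6.56 \times 10^{-9}) \times 10^{-6}$ MYA:
the synonymous divergence divided by twice the clock rate (substitutions
per synonymous site per year), scaled from years to millions of years.
This unit reading is the only one consistent with dates in the
single-digit-to-hundreds MYA range.

**Cross-species synteny.** The same chaining runs between two genomes; a
family gene "has a collinear ortholog" when it appears in at least one
anchor of at least one cross-genome block.

## The synthetic-data generator

The generator is first-class, tested code: it is the package's stand-in
for the real genome downloads and provides exact planted truth. Its
defaults are the study conditions: 12 chromosomes, a 66-member family
split 11/8/2/18/8/19 over subgroups A1–A6, 40 of 66 members carrying E at
domain column 19, 10 tandem arrays (0–5 intervening loci), 8 segmental
blocks of 6 anchors, pair divergences drawn from $K_s \in \{0.1, 0.3,
0.6\}$ at $\omega = 0.2$, three planted motifs (one family-wide, one
A1-specific, one A6-specific; widths 15, 9, 21 inside the 6–50 search
range; 5% per-column noise), about 86% single-exon genes with the rest
carrying one or three introns, and a decoy set (15% of family size) split
between no-domain, two-domain and alanine-14 proteins derived from the
same family root so that homology search retrieves them and only the
conservation filter can reject them.

Family proteins have a fixed architecture: a 40-residue N flank, the
54-column domain, a 60-residue inherited C flank (these three evolve from
a common root, 0.45 synonymous units to each subgroup ancestor and 0.15
from ancestor to member, under a stop-excluding Gillespie codon process in
which every synonymous single-base change has rate 1/3 and every
nonsynonymous change rate $\omega/3$ — one time unit is then one expected
synonymous substitution per NG86 synonymous site), plus a 70-residue
variable segment that is random per gene and carries the planted motifs at
random non-overlapping offsets. The variable segment is what makes motif
boundaries well-defined: a planted motif's flanking context is background,
so the penalized width search recovers its exact consensus, while the
inherited regions are legitimately discovered as additional wide motifs,
as conserved domains are in real families.

Gene placement enforces one geometric rule: family genes (and decoys) that
are not a planted pair sit at least 26 gene ranks apart and at least 25
ranks away from any planted block. Since 26 exceeds both the tandem rule
(5) and the chain gap (25), unrelated family loci can neither satisfy the
tandem rule nor link into a collinear chain, so the planted duplication
truth is the unique correct answer at the method's own default parameters.
This emulates — at desk scale — the sparsity of real genomes, where family
loci are typically separated by hundreds of annotated genes. The default
genome therefore carries 250 genes per chromosome (3,000 genes in all).

What passing tests do *not* show about real data: the generator produces
indel-free families of equal length, a single transcript per gene, clean
domain boundaries and background genes with i.i.d. composition. Real
proteomes have isoform ambiguity, compositional bias, partial domains and
alignment uncertainty; the recovery results certify the algorithms, not
robustness to those complications.

## Numerical and engineering choices

Coordinates are 0-based half-open everywhere inside the package; GFF3
(1-based inclusive) converts only at the I/O boundary, and gene rank is the
0-based position among all genes of a chromosome ordered by start. CDSs
carry their terminal stop codon when present; translation strips exactly
one. Floating-point ties in dynamic-programming tracebacks are resolved
with a $10^{-9}$ tolerance preferring match states; NJ ties by label; all
stochastic steps take explicit seeds and every pipeline stage derives its
seed from the master seed, so a run is reproducible end to end (the test
suite asserts byte-identical output tables across repeated runs).

Problem sizes used by the packaged checks: the study-scale run (3,000
genes) once, shared across tests; 200 bootstrap replicates; 200 random
additive matrices up to 8 taxa; 20 replicate pairs per $K_s$ target at 300
codons; the full 61 × 61 codon-pair oracle comparison. These sizes were
chosen so the complete suite exercises every claim at comfortable
statistical margins.

## Known limitations

- Center-star alignment degrades on families with long or repeated
  insertions; supply an external MSA for such data.
- The E-value calibration uses ungapped constants with gapped alignments;
  it is a ranking device with a familiar scale, not a calibrated tail
  probability.
- NG86 with a single clock rate is the study's dating model; rate
  variation across sites or lineages is out of scope, as are
  maximum-likelihood codon models.
- ZOOPS discovery is sequential with hard masking; overlapping or
  correlated motifs are found as composites, exactly as sequential
  MEME-style analyses report them.
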