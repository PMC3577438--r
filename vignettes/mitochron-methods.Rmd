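---
title: "Models and methods behind mitochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitochron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochron)
```

mitochron reconstructs and dates mosquito mitochondrial genomes at desk
scale.  This vignette describes the models it implements, the defaults it
chooses and why, and what its simulation-based validation does and does not
demonstrate about real data.

## The simulation model

### Species trees

`simulate_time_tree()` draws a pure-birth (Yule) tree conditioned on the
number of tips and the root age.  Lineages split after exponential waiting
times at per-lineage rate $\lambda$ (default 0.1 per lineage per my, a value
that gives radiations spread over tens of my, comparable to mosquito
sibling-species groups); the realized depth is then rescaled so the root
divergence sits exactly at the requested age and all tips at the present.
Ultrametricity is an invariant (checked to $10^{-9}$ relative tolerance),
and with two taxa the single divergence necessarily sits at the root age.

### Sequence evolution

Sequences evolve by substitution only, under a strict molecular clock: the
branch length in substitutions/site is the substitution rate $\mu$
(default 0.0115 substitutions/site/my, the rate commonly used for insect
mitochondrial DNA) times the branch duration in my.  The default model is
HKY with AT-rich stationary frequencies $(\pi_A, \pi_C, \pi_G, \pi_T) =
(0.40, 0.11, 0.09, 0.40)$, transition/transversion ratio $\kappa = 8$ and
discrete-gamma rate variation with shape $\alpha = 0.3$ over 4 categories —
one fixed choice of the strong compositional bias, transition excess and
rate heterogeneity characteristic of insect mitogenomes.  Each site keeps
its rate category across the whole tree.

Whole-genome simulation (`evolve_genomes()`) adds a codon-position rate
class: third positions of protein-coding genes evolve at their own relative
rate (default twice the rate of positions 1+2, normalized so the mean codon
rate is 1).  With `avoid_stops = TRUE`, substitutions that would create an
internal in-frame stop codon are rejected — a crude stand-in for purifying
selection that keeps all simulated CDS translatable; it is off by default
because the neutral model is the forward counterpart of the inference model.
No indels are simulated by default, so the 13 simulated CDS concatenate to a
fixed-width matrix, matching the fixed-length supermatrix the inference side
assumes.

### The genome template

The default template (`genome_template()`) lays out the ancestral insect
mitochondrial gene order — 13 protein-coding genes, 22 tRNAs, 2 rRNAs and a
control region — contiguously on a 15,274 bp circle, with CDS lengths
divisible by three and a 13-gene total of 11,184 bp.  These sizes mimic the
~15.2–15.4 kb genomes and ~11 kb coding complement of *Anopheles*
mitogenomes; exact per-gene lengths are rounded to full codons rather than
copied from any particular accession.

### Reads

`shotgun_reads()` draws ~300 bp fragments uniformly from the circular
mitogenome and a linear nuclear surrogate in proportion to the
mitochondrial:nuclear copy ratio (default 55-fold, the midpoint of the
50–60-fold coverage excess seen in mosquito shotgun data; mitochondrial
coverage defaults to 500X).  Each fragment yields a forward read and a
reverse-complement mate.  Sequencing error is uniform substitution at a
configurable per-base rate (default 0.2%), with constant Q30 qualities —
platform-specific error profiles, GC bias and heteroplasmy are deliberately
out of scope.  The nuclear surrogate length is a free parameter (1 Mb in the
CLI default): real nuclear genomes are ~200 Mb, but only the per-base
coverage ratio matters to the enrichment heuristics, so a surrogate that is
large relative to the read length is sufficient.

## Read enrichment

Two count-based heuristics reproduce the copy-number enrichment logic:

* `select_duplicated_reads()` keeps reads whose exact sequence occurs at
  least twice (configurable).  At ~500X mitochondrial versus <10X nuclear
  coverage, duplicate reads are overwhelmingly mitochondrial.  Each mate is
  counted independently by default (pair-concordant filtering is a flag);
  reverse complements are *not* collapsed when counting, matching raw read
  identity, and qualities are ignored.
* `abundance_filter_dedup()` keeps one instance of each distinct sequence
  supported by strictly more than 20 reads (the `>` is strict: a sequence
  seen exactly 20 times is dropped).  This simultaneously removes
  error-bearing reads and normalizes coverage before assembly.

Both filters are validated against naive hash-and-count oracles on random
multisets, and purity/recall of the duplicate filter is measured against
simulation truth labels.

## Assembly

`build_graph()` counts canonical k-mers (lexicographic minimum of the
strand pair; odd k enforced so no k-mer is its own reverse complement).
`assemble_contigs()` removes nodes below a coverage cutoff — 70 for deep
raw-read assemblies (k = 29), 1 for deduplicated abundance-filtered sets
(k = 31) — and emits maximal non-branching paths; an isolated cycle (a
clean circular genome) is emitted once as one rotation of the circle.
`anchor_layout()` places contigs on a reference circle by exact 20-mer
diagonal voting on both strands; `collapse_layout()` merges overlapping
contigs, passing agreements through and encoding disagreements as the
minimal covering IUPAC code, with uncovered intervals reported as N-gaps
(the in-silico counterpart of gap-filling by Sanger sequencing is a gap
report, not a sequence).  `polish()` maps all reads back by exact 31-mer
seed and ungapped extension and replaces a draft base only where a strict
majority (>50%) of covering reads disagrees; ties conservatively keep the
draft (a "majority" that is exactly half is none), IUPAC draft positions
resolve to the most common covering base, and zero-coverage positions are
flagged and left unchanged.  One polishing pass is the default; on
error-free data a second pass provably changes nothing, which the tests
assert.

The round-trip invariant — genome to reads to enrichment to assembly to
polish reproduces the genome exactly, up to rotation, for repeat-free
genomes — is the module's headline test, run on 2.5–3 kb toy circles at
100–300X so the suite stays fast; nothing in the algorithms depends on the
genome length.

## Tiling primer design

`build_masked_consensus()` computes a per-column majority consensus over
aligned genomes and masks every column with two or more distinct unambiguous
bases or any gap.  `scan_primer_sites()` enumerates all circular windows of
18–27 bp on both strands and accepts those with at most two masked columns,
none within the last three 3'-end positions (the "last 3' positions" are
implemented as the final 3 bases, configurable), melting temperature within
50–66 °C and GC fraction within 0.20–0.65; masked columns are excluded from
the GC numerator and denominator.  Tm uses the SantaLucia (1998) unified
nearest-neighbor parameters with a 50 mM monovalent-salt entropy correction
at 250 nM primer concentration (the Wallace rule is available as a quick
alternative); the Tm model is engineering configuration, not science, and
the GC/Tm windows were chosen once to be permissive on AT-rich insect
mitogenomes.

`design_tiling()` searches for a circular tiling of (by default) seven
amplicons with products of 2.0–3.5 kb and at least 100 bp overlap between
consecutive products, by depth-first search with backtracking over the
admissible sites, preferring evenly spaced products.  The defaults realize a
seven-amplicon scheme on a ~15.3 kb circle; if no scheme with the target
count exists, the feasible count closest to the target is returned with a
warning, and a fully infeasible instance raises an explicit error.
`verify_scheme()` re-checks every emitted scheme against the constraint
system, and on sparse toy instances the search is tested against exhaustive
enumeration.

## Gene extraction and codon alignment

`extract_genes()` performs a translated search: six-frame translation of the
doubled (circular) genome under the invertebrate mitochondrial code
(translation table 5: TGA = Trp, ATA = Met, AGA/AGG = Ser), local protein
alignment of each of the 13 reference proteins (BLOSUM62, gap open 10 /
extend 0.5), and the best locus per gene with CDS coordinates, extended over
a trailing stop codon when present.  Genes scoring below threshold are
reported missing rather than dropped.  Self-annotation — extracting genes
from a genome using its own translated proteins — recovers the annotation
exactly, and extraction is invariant to genome rotation.

`codon_align()` aligns at the amino-acid level (progressive alignment
against the running consensus, guide order by k-mer similarity to the most
central sequence) and back-translates, so gaps only ever appear as full
triplets and ungapping recovers each input CDS byte-for-byte.  An internal
stop codon is an error naming the offending taxon and codon.
`concatenate()` assembles the per-gene alignments into a supermatrix with a
gene partition map and per-column codon-position classes (1+2 versus 3, the
SRD06 partitioning scheme), written as relaxed PHYLIP plus NEXUS with a
sidecar partition TSV.

## Distances, likelihood and model choice

`pairwise_distances()` wraps closed-form corrected distances (TN93 by
default, with optional continuous-gamma correction) with pairwise deletion
and a cap on saturated pairs.  It also offers `model = "ML"`: a numerical
maximum-likelihood distance under a full model including *discrete*-gamma
rate variation.  The distinction matters: correcting discrete-gamma data
with the continuous-gamma closed form systematically over-corrects (we
measured ~17% upward bias at 0.23 substitutions/site with $\alpha = 0.3$),
while the ML distance under the generating model is unbiased; the
recovery benchmarks therefore use the ML distance.

`log_likelihood()` implements Felsenstein pruning over unique site patterns
with 4-category discrete gamma, in compiled code, optionally partitioned by
codon-position class with independent models and a free relative rate for
class 3 (SRD06 style: HKY+G per class with linked branch durations).  It is
verified against brute-force enumeration of all internal-state assignments
on small trees (tolerance $10^{-8}$) and against an independent
implementation (phangorn).  No numerical rescaling is applied during
pruning, which is safe for the tree sizes this package targets (tens of
taxa); very large trees would need scaled partials.

`select_model()` fits JC69, HKY, HKY+G, GTR and GTR+G on a fixed topology by
L-BFGS-B over log-transformed branch lengths and parameters, with base
frequencies fixed at empirical counts (counted as three free parameters),
and returns the minimum-AIC model, excluding non-converged fits with a
warning.

## Dating

The sampler (`mcmc_date()`) works on a fixed rooted topology under a strict
clock.  This is a deliberate simplification of a relaxed-clock,
topology-sampling analysis: mosquito mitogenome data show little deviation
from clock-likeness, a strict clock keeps the testable surface small, and
node ages from the full machinery are expected to be near, not identical to,
those of a relaxed-clock run.  Topology estimation is delegated to neighbor
joining on corrected distances with outgroup rooting (`nj_tree()`), which on
10,770-site matrices recovers the generating topology in nearly all
simulations.

The prior on node ages is order-constrained uniform with a root-scale
-invariant normalization: conditional on the root age, the internal ages are
uniform order statistics, so the marginal prior of the root is *exactly* the
calibration prior (Normal, default mean 260 mya and sd 8.42 my so that the
central 95% mass spans roughly 243–276 mya; hard truncation at those bounds
is optional and off by default, since a stated range can denote either a
truncation or an implied 95% interval — we adopt the soft reading).  This
choice is what makes honest prior-recovery checks possible at any taxon
count, and it replaces a Yule tree prior, which primarily matters for
topology search — out of scope here.

Proposals are uniform slides of internal ages within their parent/child
bounds (symmetric by construction), a log-scale root move, and a log-scale
rate move when the rate is free; with the rate fixed (default 0.0115
substitutions/site/my) the calibration is unnecessary and the sampler
measures divergence directly.  Chains default to 3 independent runs of
200,000 iterations sampled every 100 with 10% burn-in — structurally a
1/100-scale version of the multi-run, 20M-generation analyses typical of
this literature, sized so a five-taxon run completes in tens of seconds.
Runs are combined by concatenating post-burn-in samples.
`summarize_trace()` reports posterior means, central 95% credible intervals
(2.5%/97.5% quantiles, explicitly *not* HPD intervals) and
autocorrelation-time ESS (Geyer initial positive sequence), warning whenever
ESS ≤ 200.  `rate_date()` implements fixed-rate dating, TMRCA = d/(2$\mu$).

### What the validation shows — and what it does not

The acceptance benchmarks are parameter-recovery simulations run by
`scripts/acceptance.R`: fixed-rate dating of 50 two-taxon replicates with a
true split of 10 my (the age of the youngest named split in the motivating
system); strict-clock MCMC recovery of a 39-my clade root over 20 five-taxon
replicates (200,000 iterations each); and empirical coverage of the 95%
credible intervals over 100 replicates with divergences drawn uniformly in
5–50 my.  All use 10,770-site alignments — the size of the real 13-gene
supermatrix — at the default model and rate, with problem sizes (two to five
taxa, one MCMC run per replicate) chosen so the whole script completes in
minutes on one CPU.

Because the generator and the sampler share the substitution model and the
clock assumption, these checks validate the *machinery* — estimator bias,
interval calibration, sampler correctness — not the biology.  They do not
test robustness to model misspecification, rate variation across lineages,
selection, introgression or incomplete lineage sorting; on real data the
fixed topology and strict clock are approximations, and dates inherit the
full uncertainty of the calibration.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally (1-based inclusive only in
exported tables where noted); circular coordinates unwrap onto a doubled
sequence.  Saturated distances are capped at 5 substitutions/site with a
warning; zero nuclear marker coverage yields an infinite copy ratio with a
flag rather than an error; an empty post-filter k-mer graph returns an empty
contig set with a warning; polishing ties keep the draft base; the dating
sampler refuses to start from a zero-density root age and errors if no
proposal is ever accepted.
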