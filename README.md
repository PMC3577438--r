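# mitochron

Mitogenome assembly, tiling primer design and molecular dating for
sibling-species complexes.

Closely related mosquito species — such as the *Anopheles punctulatus*
group of Papua New Guinea — are often morphologically indistinguishable,
yet their divergence history matters for malaria epidemiology and
biogeography.  The complete mitochondrial genome (~15.3 kb, present in tens
of copies per nuclear genome equivalent) is the workhorse marker for such
groups: it can be enriched from whole-genome shotgun data purely by its
copy-number excess, assembled de novo per individual, and its 13
protein-coding genes concatenated into a supermatrix for Bayesian
divergence dating.

`mitochron` is a desk-scale, fully tested reimplementation of that
workflow, for method developers and students who want every step — from
read simulation to posterior node ages — inspectable, reproducible and
fast on a laptop:

* **synth** — dated Yule species trees; strict-clock HKY+Γ sequence
  evolution on an annotated 15.3 kb circular genome template (13 PCGs, 22
  tRNAs, 2 rRNAs, control region, canonical insect gene order); paired-end
  shotgun reads with a configurable mitochondrial:nuclear copy ratio
  (default 55-fold) and full truth records.
* **enrich** — the two copy-number read filters: keep reads occurring ≥ 2
  times (duplicate enrichment) and keep one instance of each sequence
  supported by > 20 reads (abundance filter with dedup), plus a k-mer
  marker-based copy-ratio estimator.
* **assemble** — canonical-k-mer de Bruijn graph (k = 29, coverage cutoff
  C = 70 for raw reads; k = 31, cutoff 1 for deduplicated sets), unitig
  contigs, reference anchoring by exact-match voting, IUPAC overlap
  collapse, gap report, and strict-majority read-back polishing.
* **amplicons** — variant-masked consensus over aligned genomes and
  DFS design of a circular tiling of (by default) seven 2.0–3.5 kb
  long-range PCR amplicons with ≥ 100 bp overlaps, under the primer-site
  constraints ≤ 2 variants per footprint and a variant-free 3' end.
* **genealign** — translated six-frame search for the 13 protein-coding
  genes (invertebrate mitochondrial code, BLOSUM62 local alignment),
  codon-aware alignment by translate–align–back-translate, and a
  partitioned supermatrix (codon positions 1+2 vs 3).
* **chronophylo** — corrected distances (TN93/ML), neighbor joining with
  outgroup rooting, partitioned pruning likelihood (compiled), AIC model
  selection, fixed-rate dating TMRCA = d/(2μ) at μ = 0.0115
  substitutions/site/my, and a strict-clock Bayesian dating sampler with a
  Normal(260, 8.42) root calibration prior (≈ 243–276 mya central mass)
  and posterior summaries (mean, central 95% credible interval, ESS).

## Worked example: date a simulated split

```r
library(mitochron)

model <- subst_model("HKY", freqs = c(A = .40, C = .11, G = .09, T = .40),
                     kappa = 8, alpha = 0.3)

## a two-species divergence 10 my ago, 10,770 sites at the insect mt rate
tree  <- simulate_time_tree(2, birth_rate = 0.1, root_age = 10, seed = 1)
aln   <- simulate_alignment(tree, 10770, mu = 0.0115, model = model, seed = 2)

## fixed-rate dating from the ML-corrected distance
d <- pairwise_distances(aln, model = "ML", subst = model)[1, 2]
rate_date(d, 0.0115)
#> [1] 10.8367

## Bayesian strict-clock dating with the rate fixed to 0.0115
tt <- mcmc_date(aln, tree, clock = clock_model(0.0115, fixed = TRUE),
                model = model, iterations = 50000, thin = 50, seed = 3)
root_age_summary(tt)
#>      mean    lower   upper      ess
#> 1 10.8706 10.04717 11.7419 898.5969
```

The two dating modes agree closely (point estimate 10.84 my; posterior
mean 10.87 my, 95% credible interval 10.0–11.7 my).  A single 10,770-site
replicate scatters around the simulated 10-my truth with a standard
deviation of roughly 0.6 my — this draw happens to sit high — and
averaging over replicate simulations recovers the truth without bias
(`scripts/acceptance.R` measures exactly this).

A full pipeline — genomes → reads → enrichment → assembly → polishing →
gene extraction → supermatrix → NJ tree → dating — is demonstrated in the
test suite, and each stage is exposed on the command line:

```sh
mitochron simulate --n-taxa 5 --root-age 39 -o sim
mitochron enrich --mode duplicate sim_R1.fastq sim_R2.fastq -o enriched
mitochron assemble --k 29 --min-kmer-cov 70 --reference ref.fasta reads_R1.fastq -o asm
mitochron design-primers aligned.fasta --n-target 7 -o primers
mitochron date supermatrix.phy --topology nj.nwk --rate 0.0115 --seed 1 -o dating
```

(the `mitochron` script is installed under `inst/exec/`).

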