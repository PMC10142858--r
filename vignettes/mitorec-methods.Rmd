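---
title: "Models and methods behind mitorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitorec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitorec analyses whole-mitogenome alignments and short reads from natural
fungal populations, where mitochondria are usually inherited from a single
parent and therefore evolve, in the absence of recombination, as an asexual
linked block exposed to Muller's ratchet. The package asks three questions
of such data: how much diversity the mitochondrial population carries and
how efficiently selection acts on it; whether the genomes recombine, and at
what population-scaled rate; and whether individual mushrooms carry a
detectable second mitochondrial genotype (heteroplasmy), the precondition
for recombination. Everything is exercised end to end on simulated data, so
this vignette also spells out exactly what the simulator does and does not
emulate.

## The coalescent simulator

`simulate_haplotypes()` implements Hudson-style ancestral-recombination-graph
simulation with ancestral-material tracking. Lineages carry intervals of
sequence annotated with the set of sampled sequences descending from them;
coalescence merges interval sets (material whose descendant set reaches all
n samples has found its MRCA and is dropped), recombination splits a
lineage at a point uniform on its ancestral span, at per-site rate
`rho_site/2` per lineage. Mutations are laid down afterwards at rate
`theta_site/2` per site per unit of coalescent time, by sampling logged
branch segments in proportion to duration x length.

Defaults are the conditions this kind of survey reports: per-site
theta = 0.003 (the population mutation parameter of a low-diversity
mitogenome), rho = 0, circular declaration with a linear simulation
coordinate. Circularity is deliberately a *declaration*: the ARG runs on a
linear coordinate, and circular geometry enters only through downstream
distance computations (minimum arc) and through read simulation, where
reads wrap the origin. Under the default infinite-sites model every
mutation occupies a fresh alignment column, so a rho = 0 simulation can
never produce a four-gamete violation -- that exactness is what makes the
simulator usable as an oracle. A finite-sites toggle allows recurrent
mutation (later mutations overwrite earlier ones in time order); it exists
because two of the recombination tests (maximum chi-square and PHI) are
only meaningful when homoplasy is possible.

What a green test on these data does *not* establish: robustness to
demographic structure, selection, alignment error, or indel polymorphism.
The simulator has none of those (structural variants are applied
separately and deterministically by `apply_structural_variant()`).

`simulate_mixture_reads()` draws fixed-length reads from a circular genome,
each read originating from the minor mitotype with the stated probability,
with independent uniform substitution errors -- an Illumina-like error
model without indels, which is all the heteroplasmy estimator's
contamination floor requires. Truth labels ride along in a sidecar, never
in the FASTA/FASTQ records themselves.

## Mitotypes, masking and networks

Short-read mitogenome assemblies disagree most often at single-nucleotide
repeats (assembler slippage at homopolymers) and in gap-rich alignment
stretches. `collapse_mitotypes()` therefore masks (1) columns inside or
immediately flanking a consensus homopolymer run of length >= 5 and (2)
columns in any 11-column window whose gap fraction reaches 0.2, then merges
samples identical on the unmasked columns. The three thresholds are
explicit package choices -- the practice they operationalize is standard,
but no published number exists for any of them; they are exposed as
arguments. The haplotype network is a minimum-spanning network: Kruskal's
construction in which all tied edges joining distinct components at a
distance level are retained, so reticulations survive instead of being
broken arbitrarily.

Biallelic site extraction keeps columns with exactly two alleles among
`A C G T`; gaps and Ns become missing data and the affected samples are
dropped from each pair's computation rather than imputed. The minor-count
threshold defaults to 1 (mitochondrial assemblies are consensus sequences,
so singletons are not sequencing noise the way nuclear genotype calls are);
a threshold of 2 reproduces the stricter filter used for nuclear data.

## Diversity and selection efficacy

`nucleotide_diversity()` is average pairwise difference with *pairwise*
deletion, chosen over complete deletion because gappy mitogenome alignments
would otherwise discard most columns; the windowed values therefore average
back exactly to the global value only on gap-free data. `ne_mu()` converts
pi to the product of effective population size and mutation rate using
theta = 2Ne*mu for a uniparentally inherited haploid genome and 4Ne*mu for
biparental diploids; summaries round to 2 significant figures with ties
away from zero (the convention printed values follow -- note that R's
`signif()` rounds half even and would turn 0.000625 into 0.00062).

`pn_ps()` implements the modified Nei-Gojobori method: potential site
counts weight the single transition at each codon position by the
transition/transversion ratio (default 2) against 1 for each transversion,
so synonymous + nonsynonymous sites always sum to 3 per codon; observed
differences between codons differing at multiple positions are averaged
over all orderings of single-step paths, excluding paths through stop
codons whenever at least one stop-free path exists. Mutations *to* stop
codons count as nonsynonymous (keeping the site-count identity exact).
No multiple-hit correction is applied -- the ratios are raw, comparable
across genomes analysed the same way. Genetic codes: the fungal
mitochondrial table (4; TGA = Trp) and the standard code. The bootstrap
comparison resamples codon columns independently in the two alignments,
which also makes gene concatenation order irrelevant; replicates with an
undefined ratio (no synonymous variation drawn) count as non-support and
are tallied.

## The recombination battery

Four detectors, in increasing model commitment:

1. **Four-gamete scan / haplotype blocks.** A site pair showing all four
   haplotypes is incompatible with a single genealogy under infinite
   sites. Blocks are maximal runs of sites that are pairwise
   <= 3-gamete, found by greedy left-to-right extension (which attains the
   minimal segmentation, verified against a dynamic-programming oracle in
   the tests); on circular data the terminal and initial blocks merge when
   their union is violation-free.
2. **LD-decay Mantel tests.** Within consecutive linear chunks (the
   circle must be cut because distance matrices need linearity), pairwise
   r^2 or D' is correlated with physical distance; site labels are
   permuted. Recombination predicts *negative* correlation, so the default
   test is one-sided toward negative (two-sided by flag). Chunking starts
   at the coordinate origin; an `offset` argument exists because chunk
   boundaries are otherwise arbitrary.
3. **Maximum chi-square.** For every sequence pair a window of
   w = round(2/3 x S) ordered segregating sites slides along the genome
   and is split at its midpoint; the 2x2 chi-square of differ/agree x
   left/right peaks at recombination breakpoints. The statistic is the
   maximum over pairs and positions; the permutation shuffles the order of
   segregating sites. The pairwise (Maynard Smith) formulation is a
   documented choice; the planted-breakpoint fixture in the tests is the
   behavioural contract.
4. **PHI (pairwise homoplasy index).** Mean incompatibility score over
   parsimony-informative site pairs within 100 bp (a conventional default;
   nothing in the source material fixes it) of each other, position-permuted.
   Recombination makes *nearby* pairs less incompatible than a random
   arrangement, so small observed Phi_w is the signal and the one-sided p
   counts permutations with Phi_w <= observed. On homoplasy-free data
   (infinite sites, rho = 0) the statistic is identically zero and p = 1:
   the test is conservative by construction there, which is why its
   type-I calibration in the acceptance suite runs on finite-sites
   simulations with enough recurrent mutation to make the permutation
   distribution non-degenerate.

All permutation p-values use the add-one estimator (1 + hits)/(1 + perms),
so p is never 0 and never smaller than 1/(perms + 1).

## Composite-likelihood rho estimation

The estimator follows the two-locus composite-likelihood design: a lookup
table of two-locus sample-configuration probabilities is built by Monte
Carlo coalescent simulation over a grid of scaled rates C in [0, 100]
(grid: 0 plus geometric points; interpolation is linear in log-likelihood,
flat beyond the last gridpoint). Each simulation tracks both loci's
descendant sets (as bitmasks, so n <= 30) and then drops exactly one
mutation per locus, branch-length weighted -- the small-theta limit of
conditioning on both loci segregating. Configurations are canonicalized
over the 8 symmetries (allele relabelling at each locus, locus exchange);
configurations never observed at a gridpoint receive a pseudocount floor of
0.5/n_sims so composite log-likelihoods stay finite. The table records
theta as metadata; at per-pair mutation rates of order 10^-3 the finite-
theta correction is far below Monte Carlo noise.

`estimate_constant_rho()` sums interpolated log-probabilities over all site
pairs at C = rho x distance (minimum circular arc when the data are
circular) and maximizes over rho by grid search plus golden-section
refinement. r/m is reported both as rho/theta_W and rho/pi, because the
two normalizations answer slightly different questions and field reports
print both.

`estimate_variable_rho()` is a reversible-jump MCMC over piecewise-constant
maps with change points between segregating sites: block rates carry an
exponential prior centred on the constant-rho estimate, each change point
costs `block_penalty` (default 5) on the log scale, and birth/death moves
split and merge blocks with a length-weighted log-rate decomposition
(Jacobian-corrected). The posterior is summarized per 2000 bp window as
the mean and central 95% interval of the windowed average rate. Defaults
are desk-scale (1e5 iterations, thin 500); survey-scale settings (1e6,
thin 5000, 25% burn-in) are plain arguments. Composite likelihoods
overcount dependent pairs, so windowed rates should be read as relative
structure (where recombination concentrates), not as calibrated per-window
point estimates -- the tests assert ordering (hotspot vs background) and
flatness on rho = 0 data, not window-level coverage.

## K-mer heteroplasmy detection

For mitotypes x and y, `build_kmer_library()` enumerates every k-length
window of x on its circular ungapped sequence (k defaults to 251, the read
length), discards windows whose alignment footprint -- the full column
interval they span, including columns where only the other type has a gap
-- contains any gap column, and keeps a window iff its Hamming distance to
*every* y window is at least 2, so a single sequencing error cannot convert
a y-read into a spurious x-match. `estimate_heteroplasmy()` counts reads
exactly matching a library k-mer (either strand by default; shotgun reads
come from both), normalizes by library size, and computes

    H_i = (#R_iM/#K_iM) / (#R_iM/#K_iM + #R_Mi/#K_Mi)

selecting the candidate with the largest normalized minor rate -- a true
minor genotype produces a coherent excess across its whole discriminating
library, which sequencing error against an arbitrary candidate does not.
Ties go to the lowest candidate label and are recorded. #K counts distinct
k-mers (duplicates collapsed; the positional window count is also
reported). Reads of the wrong length are excluded and counted.

Outlier calling fits a beta distribution to the bulk of the per-sample
estimates by least squares of the central order statistics (plotting
positions between the 10% and 90% quantiles) against beta quantiles, then
flags a value when the expected number of observations at least that large,
N(1 - F(v)), falls below rho (default 1). Two boundary behaviours are
deliberate: constant input returns a degenerate no-outlier fit, and
rho >= N disables flagging entirely (the expected-outlier budget covers the
sample). One honest caveat: with rho = 1 even a perfectly fitted model
flags the sample maximum in roughly 60% of datasets (the maximum's tail
expectation is approximately Exp(1)), so single spurious flags among the
top order statistics are intrinsic to this rule, not a fitting failure.

The Mann-Whitney comparison of group medians enumerates the permutation
distribution of U exactly for combined n <= 12 (midranks for ties) and
otherwise uses the tie-corrected normal approximation.

## Numerical and testing choices

* 0-based half-open coordinates internally; 1-based only in VCF output and
  rendered reports.
* Every random stage takes an explicit seed; the workflow driver derives
  logged per-stage sub-seeds from the config seed, and reports regenerate
  byte-identically (timestamps live only in the log file, and the config
  hash excludes output paths).
* Test simulations are scaled to run on one CPU inside the suite budget:
  the acceptance suite uses 200 replicates where the criteria say 200, and
  scales the variable-rho examples down (5 replicates, 8000 iterations),
  which is documented at the test site.
* Known limitations: no demographic models or selection in the simulator;
  no gene-conversion model in the rho machinery; the lookup table requires
  complete cases (pairs with missing samples are skipped, not reweighted);
  the heteroplasmy caller is exact-match only, by design.
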