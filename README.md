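# mitorec

Population-genomic analysis of circular fungal mitochondrial genomes:
does a natural population's mitochondria recombine, how diverse are they,
how efficiently does selection act on them, and do individual samples
carry a second, minor mitochondrial genotype (heteroplasmy)?

Mitochondria are usually inherited from one parent. Without recombination
they evolve as a single asexual linkage block, and deleterious mutations
can accumulate irreversibly (Muller's ratchet). mitorec packages the
statistics used to interrogate this situation from whole-mitogenome
alignments and shotgun reads, for people analysing population samples of
fungal (or other small circular) organellar genomes:

* **Mitotypes and networks** — collapse per-sample assemblies into
  invariant haplotype classes, masking homopolymer-adjacent and gap-rich
  alignment columns, and build a minimum-spanning haplotype network.
* **Diversity and selection efficacy** — nucleotide diversity π with
  pairwise deletion; N<sub>e</sub>µ under θ = 2N<sub>e</sub>µ
  (uniparental haploid) or θ = 4N<sub>e</sub>µ (biparental diploid);
  π<sub>n</sub>/π<sub>s</sub> by the modified Nei–Gojobori method
  (transition/transversion-weighted site counts, default ratio 2) with a
  codon-bootstrap comparison between genomes.
* **Recombination detection** — four-gamete scan and haplotype blocks;
  Mantel tests of LD (r² or D′) decay with distance on linearized chunks;
  Maynard Smith's maximum-χ² over sequence pairs; the pairwise homoplasy
  index (PHI). All significance by permutation with add-one p-values.
* **Recombination rate** — composite-likelihood estimation of the
  population recombination parameter ρ from a simulated two-locus
  coalescent lookup table (C = 0–100), with CL(ρ) = Σ log P(config | ρ·d)
  over site pairs; a constant-ρ estimator with r/m = ρ/θ reported both
  against θ_W and π; and a reversible-jump MCMC piecewise-constant ρ map
  with a block penalty, summarized every 2000 bp.
* **Heteroplasmy** — libraries of read-length k-mers (default 251 bp)
  unique to one mitotype at Hamming distance ≥ 2 from every k-mer of
  another; the minor fraction estimate
  Ĥᵢ = (#R_iM/#K_iM) / (#R_iM/#K_iM + #R_Mi/#K_Mi), with the candidate
  chosen by the largest normalized minor rate; beta-distribution
  right-tail outlier calling; Mann–Whitney group comparison (exact for
  combined n ≤ 12).
* **Simulators** — a Hudson-style coalescent with recombination
  (ancestral recombination graph, infinite sites by default, finite-sites
  toggle) and a circular mixed-mitotype read simulator with truth labels,
  so the whole pipeline is testable without any external data.

## Worked example

```r
library(mitorec)

aln   <- simulate_haplotypes(sim_params(12, 20000, theta_site = 0.003,
                                        rho_site = 2e-3, seed = 42))
sites <- extract_biallelic_sites(aln)
sites
#> mt_sites: 179 biallelic sites over 12 samples (alignment 20000 bp, circular)

fg <- four_gamete_scan(sites, return_pairs = FALSE)
sprintf("four-gamete violations: %d of %d pairs (%.1f%%)",
        fg$n_violating, fg$n_pairs, 100 * fg$n_violating / fg$n_pairs)
#> "four-gamete violations: 1137 of 15931 pairs (7.1%)"
nrow(haplotype_blocks(sites))
#> 11

ld_distance_mantel(aln, chunk_size = 10000, stat = "r2",
                   n_perm = 199, seed = 1)[, c("chunk", "n_sites",
                                               "statistic", "p_value")]
#>   chunk n_sites  statistic p_value
#> 1     1      89 -0.2131519   0.005
#> 2     2      90 -0.1335274   0.005

tab <- build_two_locus_table(12, rho_grid = c(0, exp(seq(log(0.05), log(100),
                                                         length.out = 14))),
                             n_sims = 800, seed = 7)
est <- estimate_constant_rho(sites, tab)
sprintf("rho = %.3g per site; r/m = %.3g (rho/theta_w), %.3g (rho/pi)",
        est$rho_site, est$r_over_m$rho_over_theta_w,
        est$r_over_m$rho_over_pi)
#> "rho = 0.00176 per site; r/m = 0.594 (rho/theta_w), 0.652 (rho/pi)"
```

Reading the numbers: the data were simulated with per-site ρ = 2×10⁻³,
so ~7% of site pairs show all four gametes (impossible without
recombination under infinite sites), LD falls off with distance in both
10 kb chunks (negative Mantel r, one-sided p = 0.005 at 199 permutations),
and the composite-likelihood estimate recovers ρ within a factor of ~1.2.
On recombination-free data the same pipeline reports 0 violating pairs,
a single haplotype block and ρ̂ = 0.

The two end-to-end drivers mirror a field study's analyses:
`run_recombination_suite(config)` (four-gamete + blocks, Mantel at 10 and
20 kb with both statistics, max-χ² whole-genome and in a chosen region,
PHI, constant and variable ρ — emitting a Table-1-style text summary) and
`run_heteroplasmy_survey(config)` (per-sample Ĥ, outlier flags, group
medians, Mann–Whitney). Both take a flat `[section] key = value` config,
log derived sub-seeds, and regenerate byte-identical reports on rerun.
A CLI wraps the same operations: `inst/exec/mitorec simulate|fourgamete|
mantel|maxchi|phi|rho-table|rho-constant|rho-interval|hetlib|hetest|...`.

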