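# codonqueue

Stochastic simulation of mRNA translation as ribosome traffic, and in
silico screens for mRNAs whose translation is sensitive to the depletion of
individual tRNA species.

## The problem

Most mRNAs are translated at a rate set by initiation: ribosomes load at
rate α and elongation capacity comfortably exceeds that demand. But codons
decoded by scarce tRNAs — in yeast, species encoded by a single tRNA gene —
elongate slowly, and when such codons cluster near the 5′ end of an ORF,
a drop in the cognate tRNA's concentration can make ribosomes queue behind
them. Once the queue reaches back into the first ~9 codons it blocks
initiation, and protein output falls. codonqueue is for researchers who
want to ask, quantitatively: *which mRNAs switch from initiation-limited to
elongation-limited translation when a given tRNA is depleted, and why?*

## The model

Translation of one mRNA is a totally asymmetric simple exclusion process
(TASEP) with extended particles on the lattice of its L sense codons:

- ribosomes occlude ℓ = 9 codons; footprints cannot overlap and ribosomes
  cannot overtake;
- initiation at rate α (default 0.3 s⁻¹) requires codons 1..ℓ free;
- elongation at codon *i* is two-state: cognate-tRNA arrival at rate
  k_i = c · (summed abundance of decoding tRNAs), then translocation at
  γ = 35 s⁻¹ if the next footprint codon is free;
- termination from codon L at β = γ.

The current J (proteins/s) and the per-codon A-site density ρ_i are
estimated by an exact continuous-time Gillespie simulation (C++ core,
bit-reproducible from a seed), and verified against an exact
stationary solution of the Markov chain on small lattices, where the
one-ribosome limit has the closed form J = [1/α + Σ 1/k_i + ℓ/γ]⁻¹.
A tRNA depletion multiplies one species' abundance by a factor (default
0.25) before rates are built; screens compare J under wild-type and
depleted rates with paired seeds and call an ORF sensitive when
J_dep/J_wt < 0.5.

## Worked example

```r
library(codonqueue)

trna  <- make_trna_complement(seed = 1)   # 3 single-copy + 3 abundant species
rates <- build_rate_table(trna)
rates
#> <rate_table> 12 codons | gamma = 35 /s, beta = 35 /s, c = 3
#>   k: min 3, median 19.5, max 33 /s

far7 <- far7_like_fixture(trna, seed = 1) # 221 codons, 12 CAG clustered 5'
codon_stats(far7, codons = "CAG", rare_set = rare_codons(trna))
#> # A tibble: 1 × 5
#>   orf_id   length n_CAG first_position rare_codon_ratio
#>   <chr>     <int> <int>          <int>            <dbl>
#> 1 FAR7like    221    12             13              Inf

simulate_orf(far7, rates, alpha = 0.3, seed = 42)
#> <tasep_sim> FAR7like, L = 221 codons, alpha = 0.3 /s
#>   J = 0.205 +/- 0.0021 proteins/s  (1099 terminations in 5362 s, 10 batches)
#>   mean ribosomes on mRNA = 4.35

scan <- alpha_scan(far7, trna, depletion("tRNA-Q-s01", 0.25),
                   alphas = c(0.3, 0.1, 0.05, 0.01), seed = 42)
scan[, c("alpha", "J_wt", "J_dep", "ratio", "ratio_se")]
#>   alpha    J_wt  J_dep ratio ratio_se
#> 1  0.01 0.00975 0.0100 1.027  0.04371
#> 2  0.05 0.04859 0.0409 0.842  0.02041
#> 3  0.10 0.08943 0.0629 0.703  0.02025
#> 4  0.30 0.20486 0.0722 0.353  0.00738
```

Reading the numbers: in the wild type this mRNA produces 0.205 proteins/s
at the physiological initiation rate — close to initiation-limited
(J/α = 0.68) despite its CAG cluster. Depleting the single-copy
CAG-decoding tRNA to 25% collapses output nearly 3-fold (ratio 0.35):
ribosomes queue at the slowed CAG cluster and the queue throttles
initiation. As α is lowered the queue dissipates and the ratio returns to
1 (1.03 ± 0.04 at α = 0.01) — the signature of queue-mediated, not
occlusion-mediated, down-regulation. Swapping every CAG for its synonym
CAA (`swap_codons(far7, "CAG", "CAA")`) makes the ratio exactly 1 at every
α. `autoplot()` methods draw the screen scatter, the scan, and density
profiles; `run_screen()`, `multi_trna_screen()` and
`correlate_sensitivity()` scale the comparison to transcriptomes, and
`inst/cli/codonqueue` exposes the same operations as shell subcommands.

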