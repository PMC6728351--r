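# polusage

Genome-wide tracking of the division of labor among the replicative DNA
polymerases — Pol α, Pol δ and Pol ε — from strand-specific
ribonucleotide-derived end-count tracks, with downstream analysis of
replication initiation and termination.

## The problem and who this is for

In strains where ribonucleotide excision repair is disabled and one
replicase carries a ribonucleotide-permissive variant, embedded
ribonucleotides mark the DNA that polymerase synthesized. Sequencing the 5′
ends exposed by RNase HII cleavage yields, per 50 bp bin and strand, an end
count proportional to how much synthesis each polymerase performed there.
This package is for genomicists analyzing such polymerase-usage tracks (or
modeling them): it implements the full computational pipeline on synthetic
data, so every stage is testable without any external sequencing download.

The core model: the corrected end count in strain *K* at bin *i*, strand
*j* is

> *y₍ᵢⱼK₎ = w₍ᵢⱼ₎ Σₖ s₍ₖK₎ f₍ᵢⱼₖ₎*,  with Σₖ *f₍ᵢⱼₖ₎* = 1

where *f₍ᵢⱼₖ₎* are the per-polymerase synthesis fractions, *s₍ₖK₎* the
ribonucleotide incorporation rates and *w₍ᵢⱼ₎* a position/strand-specific,
polymerase-independent noise factor. Three variant strains give three such
equations; eliminating *w* yields a closed-form solution
*f_δ = (CE − FB)/(FA − CD)* with *f_α* by back-substitution and
*f_ε = 1 − f_α − f_δ*. From the solved fractions the pipeline computes the
**DDAF** — the deviation from the expected Pol δ/α fraction of synthesis,
*1 − f₍ε,top₎ − f₍ε,bottom₎*, which is 0 under the canonical division of
labor, +1 where both strands were made by Pols δ/α, and −1 where both were
made by Pol ε — quantifies DDAF peak areas at origins and termination
zones, calls origins from abrupt strand-concordant shifts in *f_ε*, and
fits a Monte Carlo fork-collision model (fork velocity, firing-time
dispersion, collision tract length) to the observed DDAF.

## Worked example

```r
library(polusage)

program <- replication_program(
  chrom_lengths = c(chr1 = 400000),
  origins = data.frame(chrom = "chr1", pos = c(100000, 300000),
                       t_fire = c(5, 20)),
  v_f = 6000, sigma_t = 2.6, l_coll = 4600)

truth <- simulate_replication(program, n_iterations = 200, seed = 1)
#> true_synthesis: 200 iterations, 2 origins, mean efficiency 1

samples <- forward_model(truth, polymerase_rates(), noise_config(), seed = 2)
normalized <- normalize_by_sites(samples)
corrected <- list()
for (strain in c("wild-type", "alpha-variant", "delta-variant",
                 "epsilon-variant")) {
  treated <- average_replicates(Filter(function(s)
    s$strain == strain && s$treatment == "treated", normalized))
  control <- average_replicates(Filter(function(s)
    s$strain == strain && s$treatment == "control", normalized))
  corrected[[strain]] <- subtract_control(treated, control)
}

windows <- select_calibration_windows(
  truth$strandedness, exclude = program_exclusion_mask(program))
calibration <- estimate_rates(corrected, windows)
fractions <- rescale_epsilon(
  solve_fractions(calibration$corrected, calibration$rates))
#> synthesis_fractions: 8000 bins x 2 strands; 16000 solvable bin-strands;
#> epsilon scale 1.026

call_origins(fractions$f_epsilon)
#>   chrom   pos shift_top shift_bottom concordance
#> 1  chr1 3e+05     0.979       -0.983       0.996
#> 2  chr1 1e+05     0.963       -0.967       0.996
```

Both programmed origins are recovered at their true positions with
near-unit shifts on both strands (the f_ε step from lagging to leading);
the ε rescale factor 1.026 is the correction for the slight rate
underestimation inherent to ≥90%-pure calibration windows. The collision
side of the model runs through the lightweight simulator:

```r
simulate_collisions(program, n_iter = 1000, seed = 3)
#> collision_density: 1000 iterations at v_f = 6000, sigma_t = 2.6,
#> l_coll = 4600; sum of efficiencies 2.0
```

## The analysis workflow

The numbered scripts under `analysis/` run the full study and write tables
under `results/` (intermediate state under `scratch/`):

1. `01_simulate.R` — ground truth + synthetic samples for the shipped
   2 Mb / 12-origin program (`inst/extdata/program_2mb_12ori.yaml`)
2. `02_normalize.R` — restriction-site normalization, replicate averaging,
   control subtraction
3. `03_deconvolve.R` — rate calibration and fraction solving (reports rate
   ratio recovery and |f_ε − truth|)
4. `04_ddaf_origins.R` — DDAF, origin peak areas, origin calling
5. `05_termination_fit.R` — fork velocity, σ_t and l_coll recovery from the
   DDAF
6. `06_initiation_recovery.R` — 30 origins of graded efficiency; the
   area-vs-efficiency line and the extrapolated initiation tract

Run them in order with `Rscript analysis/01_simulate.R` etc. Each prints a
short narrative of what it found and writes machine-readable TSV/JSON.

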