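# hbramp

Position-dependent hydrogen-bond profiling and ramp modeling of ORFeomes.

## The problem

Each codon carries 6–9 Watson–Crick hydrogen bonds in double-stranded DNA
(A:T = 2, G:C = 3 per pair), and synonymous codons of one amino acid can
differ by up to 25% in that count. Since transcription must separate the
strands, genomes can tune the unwinding cost of a gene's 5' end purely
through synonymous codon choice. `hbramp` is for researchers in molecular
evolution and codon-usage biology who want to ask, for any collection of
coding sequences (an ORFeome): does the mean per-codon bond count ramp up
from the 5' end, how is the ramp shaped, and is it maintained by
selection?

The package provides:

- per-codon hydrogen-bond accounting and cheap (6–7 bonds) / expensive
  (8–9) classification of the standard genetic code;
- QC and left-aligned codon matrices from multi-FASTA CDS collections
  (start codon removed; positions labelled from 2);
- positional profiles with bootstrap confidence intervals for any
  per-codon metric: bond counts, class frequencies, RSCU, CAI weights,
  tAI weights, and an adapter for external mRNA unpaired-probability
  tables;
- ramp model fitting — uniform `y = A`, linear `y = Bx + C`, and the
  bounded exponential

  ```
  y(x) = A·C·e^{Bx} / (A + C·(e^{Bx} − 1))
  ```

  with carrying capacity `A`, rate `B`, and initial content `C`
  (`y(0) = C`, `y → A`), selected by AIC with BIC agreement and a Wald
  test on `B` gating the "ramp detected" flag;
- a selection test against a synonymous codon-shuffling null: per-position
  `z² = ((O − E)/σ)²` summing to a χ²-type statistic, the hanging chi-gram
  `(O − E)/E`, and their normalisations;
- operon-position and expression-strata comparisons
  (Wilcoxon/Kruskal–Wallis, Benjamini–Yekutieli adjustment, LOESS
  smoothing) and profile correlation networks;
- a synthetic ORFeome generator with known ground truth (exponential
  tilting toward a chosen ramp curve) so the whole pipeline is testable
  offline.

## Worked example

Generate a synthetic ORFeome with a known ramp (A = 7.9, B = 0.3,
C = 7.0), profile it, fit the models, and test for selection:

```r
library(hbramp)

spec <- generator_spec(n_cds = 2000, length_codons = 101, seed = 7)
orf  <- generate_orfeome(spec) |> qc_filter(n_positions = 100)
mat  <- build_codon_matrix(orf)

prof <- positional_profile(mat, hbond_count, n_boot = 1000, seed = 1,
                           metric_name = "hbonds")
head(prof, 3)
#>   position  mean     se ci_low ci_high     n metric
#> 1        2  7.00 0.0164   6.96    7.03  2000 hbonds
#> 2        3  7.18 0.0192   7.14    7.22  2000 hbonds
#> 3        4  7.37 0.0194   7.33    7.41  2000 hbonds

fits <- fit_models(prof)
select_model(fits)
#> ramp_fit: bounded_exponential (converged)
#>      A      B      C
#> 7.9001 0.2916 6.9876
#> AIC: -564.5839  BIC: -554.1632
```

The mean climbs from 7.00 bonds/codon at position 2 toward the carrying
capacity; the bounded exponential wins model selection and recovers the
implanted parameters (7.90, 0.29, 6.99 against the true 7.9, 0.3, 7.0),
with Wald p-values below 1e-60 for all three. The selection test
compares the observed per-position bond totals with 200 synonymously
shuffled copies of the ORFeome:

```r
null <- null_distribution(orf, n_sims = 200, seed = 2)
sel  <- selection_profile(mat, null)
ramp_of_selection(sel)
#>   mean_norm_zsq_5prime mean_norm_zsq_rest mean_chigram_5prime mean_chigram_rest
#> 1                0.195             0.0103             -0.0215           0.00374
```

Selection signal concentrates at the 5' end (normalised z² 0.195 vs
0.010 elsewhere) and the negative 5' chi-gram (−0.022) says the observed
5' codons carry *fewer* hydrogen bonds than synonymous shuffling would
allow — the signature of a maintained ramp. `autoplot()` methods render
each result type; `tidy()`/`glance()` give tabular fit summaries.

A thin command-line front end over the same functions ships at
`inst/cli/hbramp.R` (subcommands `profile`, `fit`, `selection`,
`simulate`, `strata`).

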