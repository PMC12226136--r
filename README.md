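# cleavemap

Protease cleavage-site mapping from comparative **E/EQ degradomics** —
label-free quantitative (LFQ) comparisons of digests by an active protease
(E) versus its catalytically inactive active-site mutant (EQ) — plus the
enzyme-kinetics layer used to quantify the activity behind those sites.

The package is written for protease biochemists and proteomics analysts
studying extracellular-matrix proteolysis (its worked examples are ADAMTS
protease digests of versican, biglycan and an ADAMTS auto-digest), but the
machinery is substrate-agnostic.

## The statistic at the core

After digestion with a *working protease* (trypsin or GluC), a peptide
with exactly one rule-conforming terminus (a **semi-tryptic / semi-GluC**
peptide) marks a candidate scissile bond P1–P1′ at its nonconforming
terminus. For every peptide quantified in both groups,

&nbsp;&nbsp;&nbsp;&nbsp;*z* = (log₂(E/EQ) − mean) / sd

over all co-quantified peptides of the same digest. A positionally
internal semi-specific peptide with *z* ≥ 2 calls its site; significant
peptides are stratified (not filtered) by Tukey fences Q1 − 1.5·IQR /
Q3 + 1.5·IQR on log₂ abundance; fully specific peptides with *z* ≤ −2
(enriched in the inactive control) corroborate calls whose P1 they span.
Sites are then deduplicated, domain-annotated, compared across enzymes,
and summarised as P5–P5′ specificity logos against a reference proteome
composition.

A synthetic E/EQ experiment generator with planted cleavage sites and
known ground truth makes the entire pipeline testable offline, and the
kinetics layer covers Michaelis–Menten fitting (with RFU calibration and
inner-filter hooks), TIMP active-site titration (x-intercept), and
progress-curve specificity constants.

## Worked example

The package ships the peptide evidence tables of four ADAMTS proteoglycan
digest experiments as fixtures. Calling sites from the ADAMTS9 block of
the biglycan table:

```r
library(cleavemap)
cat9 <- fixture_site_catalog("Table5", enzyme = "ADAMTS9")
cat9[, c("p1_pos", "p1_aa", "p1prime_aa", "domain")]
#>    p1_pos p1_aa p1prime_aa domain
#> 1      99     N          N   LRR1
#> 2     105     L          R   LRR2
#> 3     119     L          V   LRR2
#> 4     157     L          P   LRR4
#> 5     159     S          S   LRR4
#> 6     160     S          L   LRR4
#> 7     271     G          S   LRR9
#> 8     284     L          D   LRR9
#> 9     292     V          P  LRR10
#> 10    361     I          Q  LRR12
```

Ten unique ADAMTS9 cleavage sites in biglycan's leucine-rich repeats, each
inferred from the nonconforming terminus of a significant semi-tryptic
peptide (note the leucines at P1). Across all four enzymes in that table:

```r
compare_enzymes(fixture_site_catalog("Table5"))
#> <sharing_report> 27 unique positions (1 shared by >=2 enzymes)
#>   exclusive: ADAMTS1=10, ADAMTS4=2, ADAMTS5=5, ADAMTS9=9
```

27 biglycan sites in total, exactly one (S160-L161) found by two enzymes.
The same pipeline on a simulated experiment with known ground truth:

```r
sim <- simulate_experiment(synthetic_config())
res <- call_experiment(sim$observations, enzyme = "SYN")
recovery_report(res$calls, sim$truth)
#> <recovery_report> recall 1.000 (10/10), precision 1.000, 10 calls
```

And the kinetics layer, on a Michaelis–Menten curve generated with
kcat = 0.0087 s⁻¹ and Km = 2.6 µM:

```r
S <- c(0.5, 1, 2.5, 5, 10, 20, 40, 80, 160) * 1e-6
v <- 0.0087 * 0.76e-9 * S / (2.6e-6 + S)
fit_mm(S, v, enzyme_conc_active = 0.76e-9)
#> <mm_fit> Km = 2.6e-06 M, Vmax = 6.612e-12 M/s, kcat = 0.0087 1/s,
#>          kcat/Km = 3346 1/(M s)
```

A thin command-line wrapper is installed at
`system.file("exec", "cleavemap", package = "cleavemap")` with
subcommands `classify`, `call`, `density`, `catalog`, `logo`, `simulate`
and `kinetics`.

The methods vignette (`vignettes/cleavemap-methods.Rmd`) documents the
model, its assumptions, all tunable parameters, and what the synthetic
benchmark does and does not demonstrate about real data.

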