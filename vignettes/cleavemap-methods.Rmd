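---
title: "Calling protease cleavage sites from comparative E/EQ degradomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling protease cleavage sites from comparative E/EQ degradomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## The experimental design and its statistical footprint

cleavemap analyses *comparative degradomics* experiments in which a
substrate (or the protease itself, for autolysis) is incubated separately
with an active protease (**E**) and a catalytically inactive point mutant
(**EQ**, active-site Glu→Gln), then digested with a *working protease*
(trypsin or GluC) and quantified label-free by LC-MS/MS. The inactive
control is crucial: every difference between the two digests that survives
normalisation is attributable to the activity of the protease under study.

Proteolysis leaves two complementary signatures among the quantified
peptides:

1. **Semi-specific peptides.** A peptide with exactly one terminus
   conforming to the working protease rule (trypsin: after K/R, not before
   P; GluC: after D/E) marks a candidate scissile bond at its
   nonconforming terminus. In Schechter–Berger notation the residue
   N-terminal to the bond is P1 and the site is written e.g. `E441-A442`.
   Genuine cleavage products are strongly enriched in the E digest.
2. **Spanning peptides.** A fully specific peptide whose interval contains
   a cleavage position is *depleted* in the E digest (the intact stretch
   is being cut), i.e. enriched in the EQ control. Such peptides
   corroborate sites found by route 1, and EQ-enriched spanners covering
   no called site are reported as *orphan signals* — cleavage regions with
   no semi-specific support.

## The two-step caller

**Step 1 — z-scores on log2 ratios.** For every peptide quantified in both
groups the log2(E/EQ) abundance ratio is computed, and standardised
against the mean and sample (n−1) standard deviation of all co-quantified
peptides of the same working-protease digest (trypsin and GluC runs are
z-scored separately; their calls are merged at the site level). Peptides
found in only one group are tagged `E_only`/`EQ_only` and excluded from
the z population — they are reported in a side channel but never
auto-called, because a single-group observation carries no ratio. A
semi-specific, *positionally internal* peptide (its nonconforming terminus
not at a protein terminus) with `z >= 2` contributes its inferred site;
peptides implying the same bond are merged with pooled evidence. The
default threshold of 2.0 reflects the smallest z treated as significant in
the worked examples packaged with this package (2.00–2.06). No
multiple-testing correction is applied, by design: the z-score here is a
ranking and stratification device on a single experiment pair, not a
family of independent hypothesis tests.

**Step 2 — abundance stratification.** Significant peptides are stratified
(never filtered) by log2 abundance against Tukey fences `Q1 − k·IQR` and
`Q3 + k·IQR`, with `k = 1.5` and quartiles by linear interpolation of
order statistics (`stats::quantile` type 7). Calls whose best evidence
falls below the lower fence are retained and flagged `outlier_low`: the
worked examples contain genuine sites supported by peptides with log2
abundance ≈ 2.6 against a bulk of 17–21, so discarding low-abundance
evidence would lose real sites. The published description of the rule
appears in two wordings ("the 1.5 interquartile rule" and "a cut-off of
1 + 1.5 interquartile range"); both readings coincide for the lower fence
used here, and we treat the second as a typographic variant of the first.
The reference abundance of a peptide is the log2 intensity of its
*enriched* group (configurable to the mean of both), since the enriched
group is the evidentiary one and the tables that motivated this package
print a single abundance per peptide.

Corroboration then attaches fully specific peptides with `z <= −2` to any
call whose P1 lies strictly inside their interval.

## Site cataloguing

Site identity is the pair (protein isoform, P1 position). Catalogs
deduplicate on `(protein, p1, enzyme)`; cross-enzyme sharing and
union/novelty counts operate on P1 equality within one isoform. Positions
are **never** transferred between isoforms by alignment at run time:
isoform numbering differs (versican V1 vs V2), and silent renumbering is
the dominant error mode in cross-study site comparisons. Instead an
explicit block-offset correspondence map is supplied
(`fixture_isoform_map()` for versican V1/V2, anchored at the G1 block
shared by both isoforms and the G3-side block whose +767 offset is fixed
by the corresponding cleavage positions in the two numbering systems).

Domain labels come from interval tables. The source tables print domain
*labels* but not boundaries, so the packaged intervals are
reverse-engineered to reproduce every printed label and shipped as
editable fixtures, not code. Lookups take the first containing interval in
file order (deterministic under nesting); one biglycan site (I126-S127)
straddles a repeat boundary and is labelled by that rule.

## Specificity logos

P5–P5′ windows are extracted around each site and scored per position and
residue as the difference between the observed frequency percentage and a
reference proteome composition (percentage scoring). Slots beyond a
protein terminus, and scaffold positions of unknown identity, are excluded
from that position's denominator rather than counted as an extra symbol,
keeping the percentages comparable with the reference set. Per-cell
significance is a two-sided z-test of the observed proportion against the
reference proportion `p0` with standard deviation `sqrt(p0 (1 − p0) / n)`.
The packaged reference is a human proteome-average composition (editable
TSV); it sums to exactly 100 and is renormalised defensively at use.

```{r logo}
sites <- rbind(fixture_site_catalog("Table2")[, c("protein_id", "p1_pos")],
               fixture_site_catalog("Table3")[, c("protein_id", "p1_pos")],
               fixture_site_catalog("Table5",
                                    "ADAMTS9")[, c("protein_id", "p1_pos")])
logo <- logo_scores(extract_windows(sites, fixture_proteins()))
subset(logo, position == "P1" & significant)
```

## Kinetics layer

- `fit_mm()` fits `v0 = Vmax·S/(Km+S)` by Levenberg–Marquardt
  (minpack.lm) with Hanes–Woolf starting values; `kcat = Vmax/[E]` and
  `kcat/Km` follow when the active enzyme concentration is known. The fit
  is exact to machine precision on noiseless generative data.
- `calibrate_rfu()` converts fluorescence rates to molar rates by the
  RFU-per-molar factor obtained from complete digestion of a substrate
  standard; inner-filter corrections enter as user-supplied multiplicative
  per-well factors (unity by default) — the package deliberately does not
  guess an absorbance model.
- `fit_titration()` fits a least-squares line through the initial linear
  region of a tight-binding-inhibitor titration and reports the
  x-intercept as the active enzyme concentration. "Initial linear region"
  defaults to all points with residual activity ≥ 20%, overridable; the
  slope must be negative, otherwise there is no endpoint and the fit
  errors.
- `fit_progress()` models product formation as
  `P(t) = S0 (1 − e^{−(kcat/Km)·E·t})`, the closed form valid for
  substrate far below Km, and returns the single rate constant, which *is*
  the specificity constant. This is a documented assumption: the assays it
  targets use tens of nanomolar substrate against micromolar-scale Km, so
  substrate saturation and depletion nonlinearity are negligible.

## The synthetic experiment generator

`simulate_experiment()` produces an E/EQ experiment with known ground
truth so the whole caller can be validated end to end without any
download. The generative model mirrors the physical experiment:

- The substrate is digested in silico (default: trypsin, ≤ 2 missed
  cleavages, 6–75 residue window — the usual LC-MS/MS search settings and
  detectability window). Each peptide species draws a log-normal base
  abundance (log2 mean 18, sd 1.5, the LFQ intensity scale) and each group
  multiplies it by `exp(N(0, noise_cv))`; noise is multiplicative because
  LFQ intensity error is proportional on the linear scale.
- A planted site cut with efficiency `f` multiplies the E intensity of
  every fully specific peptide spanning it by `1 − f`, and emits the
  terminal peptides of the two cleavage products (complete re-digestion;
  the dominant semi species — missed-cleavage semi variants are second
  order) as semi-specific evidence with `E = f·base` and
  `EQ = 0.01·base`. The 1% EQ trace represents the faint background real
  inactive controls show and keeps the peptide quantified in both groups,
  as the z population requires.
- Spurious semi-specific peptides (in-source fragmentation, nonspecific
  proteolysis) are emitted symmetrically in both groups at
  `background_semi_rate` expected fragments per theoretical peptide
  (Poisson). The default of 1.7 matches the semi:fully ratio observed in
  the real digests this package's worked examples come from (279
  semi-tryptic vs 160 fully tryptic peptides on versican V2): in real
  data, spurious semi peptides *outnumber* fully specific ones. This
  background matters statistically — it dilutes the fraction of the z
  population occupied by genuine outliers and therefore sets the caller's
  power.
- Peptide species are observed with probability `detect_prob` (default
  0.9).

The default configuration (300-residue substrate, 10 sites at 80%
efficiency, seed 7) is deliberately a *hard* regime: ~10–15% of the
co-quantified population are genuine positive outliers and another ~25%
are spanning-depleted negatives, which inflates the ratio standard
deviation and pushes genuine evidence towards the z = 2 boundary. Under
the default seed the pipeline attains recall ≥ 0.9 with precision 1.0
(asserted in the tests); unlucky seeds can land the planted evidence just
below the boundary, and the power grid in the test-suite shows recall is
monotone in cleavage efficiency and (inversely) in noise. What passing
these tests shows about real data is calibration of the machinery, not of
any instrument: the generator does not simulate spectra,
identification error, retention time, glycosylation-driven detectability
gaps, or replicate structure.

```{r synthetic}
sim <- simulate_experiment(synthetic_config())
res <- call_experiment(sim$observations, enzyme = "SYN")
recovery_report(res$calls, sim$truth)
```

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive everywhere, matching UniProt residue
  numbering; there is no exposed 0-based interface.
- Quartiles: type 7 (linear interpolation of order statistics), the R
  default, stated here because fence positions depend on the convention.
- z-scores use the sample (n−1) standard deviation; a degenerate ratio
  distribution (sd = 0) or fewer than 3 co-quantified peptides is an
  explicit error, not a silent NA.
- A region with no theoretical cleavage site reports its mean and maximum
  gap as the region length; with a single site no gap is defined and both
  are NA.
- Ties in domain lookup resolve to the first interval in table order.
- Modified and unmodified forms of one sequence are distinct observations
  (real tables list them as separate rows with separate abundances);
  modifications never affect specificity classification.
- Protein termini count as specific for classification; a mature-protein
  start (post signal peptide) can optionally be treated the same way via
  `classify_peptides(..., mature_start = )`, default off.

## Scaffold fixtures

The packaged protein "sequences" are synthetic scaffolds: every residue
evidenced by the packaged peptide tables (peptides and their flanking
residues, at their published coordinates) is placed, and unknown positions
carry `X`. The assembly errors on any positional conflict, so overlapping
peptides cross-validate the transcription; `X` positions are ignored in
sequence matching and composition counts. The scaffolds support every
packaged worked example, but they are not the real UniProt entries — users
analysing their own data should supply real FASTA files.

## Known limitations

- No peptide-level FDR or multiple-testing control (by design, matching
  the workflow the package implements).
- Only trypsin and GluC rules ship; other specificities can be expressed
  via `protease_rule()`'s residue sets but are untested.
- The progress-curve model assumes `S0 << Km`; it will underestimate
  kcat/Km if that assumption is violated.
- Replicate structure is not modelled: one intensity per group. If your
  search engine emits per-injection intensities, aggregate them before
  import.
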