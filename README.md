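# whistlemod

Tools for asking whether two sympatric dolphin species encode species
identity in the frequency-modulation patterns of their whistles. The package
takes whistle *contours* — per-whistle tables of (time, fundamental
frequency) traced from spectrograms — plus recording metadata, and runs the
complete analysis chain:

* **Selection filters**: per-school whistle quotas (100 for schools under
  100 animals, otherwise group size up to 200), a ≥ 6 dB SNR gate, at most 3
  mutually overlapping whistles, at most 2 repeated stereotyped whistles of
  one type per 5-minute file, and harmonization of mixed 44.1/96 kHz
  recordings to the common 22.05 kHz Nyquist band.
* **Unsupervised categorization** (`artwarp()`): an adaptive-resonance
  network over dynamic-time-warping similarity. Contour similarity is the
  best path-mean of per-sample ratios `100·min(f,g)/max(f,g)` over monotone
  warping paths (warp capped at threefold); a whistle joins the most similar
  category when similarity ≥ the 96% vigilance, else founds a new category,
  and references adapt toward members. Returns a classed model with
  `print`, `summary`, `plot` and `predict` methods.
* **Type taxonomy**: shared / species-specific / single-encounter /
  singleton labels per type, plus a deterministic oscillatory-whistle rule
  (≥ 2 cycles of similar magnitude with ≥ 2 maxima, ≥ 1 kHz peak–trough per
  cycle, spanning ≥ 50% of the contour).
* **Statistics**: a permutation test for an excess of species-specific types
  (whistle-level label shuffling, doubled add-one-smoothed tail);
  Mann–Whitney and chi-squared comparisons of a 56-variable contour-feature
  roster at Bonferroni α = 0.05/56 ≈ 8.9×10⁻⁴, one whistle per type;
  random-forest species classification (out-of-bag, Gini importance) over
  four repertoire subsets (all / species-specific / shared /
  single-encounter whistles) with Fisher-exact accuracy comparisons.
* **Synthetic repertoires** (`generate_repertoire()`): a seeded two-species
  generator with shared and species-exclusive whistle-type templates,
  oscillatory families, stereotyped repeats, encounter structure, frequency
  and duration jitter, and known ground truth — so every stage is testable
  without field recordings.

See the methods vignette (`vignettes/whistle-repertoire-analysis.Rmd`) for
the model details, parameter conventions and limitations.

## Worked example

```r
library(whistlemod)

cfg <- pipeline_config(
  generator = repertoire_config(seed = 1,
                                n_encounters_per_species = c(3, 3),
                                whistles_per_encounter = c(40, 60)),
  rf = rf_config(ntree_start = 500, ntree_max = 500),
  rf_schemes = c("RF1_all", "RF2_species_specific_multi", "RF3_shared"),
  seed = 42)
report <- run_pipeline(cfg)
print(report)
```

```
whistlemod pipeline report (seed 42)
  input: 301 whistles, 6 encounters
  selected: 275; Nyquist-dropped: 3
  types: 18 (shared 10, species-specific 8, single-enc 0, singleton 0)
  permutation: observed 44.4%, null 0.7%, p = 0.001998
  RF1_all: 60.5% OOB accuracy (n = 266)
  RF2_species_specific_multi: 100.0% OOB accuracy (n = 60)
  RF3_shared: 45.6% OOB accuracy (n = 206)
```

Reading the report: the selection rules kept 275 of 301 generated whistles
and the Nyquist filter dropped 3 high-band whistles recorded at 96 kHz; the
categorizer then recovered 18 types, exactly the planted accessible
templates. 44.4% of multiple-encounter types were species-specific, far
above the ~0.7% expected from label shuffling (p = 0.002) — the planted
species structure is detected. The random forests show the same signature
as field analyses: whistles of species-specific types classify species far
better (here perfectly, since synthetic templates are cleanly separated)
than the full whistle pool, and shared-type whistles classify at chance.
The RF4 (single-encounter) subset is omitted here because this dense
synthetic repertoire has no single-encounter types — requesting an empty
subset is an error by contract.

The fixture reproducing a published repertoire decomposition is built by
`make_composition_fixture()`:

```r
s <- type_summary(label_types(make_composition_fixture()$membership))
s$pct_exclusive                               # 62.2
s$pct_species_specific_of_multi_encounter     # 26.2
```

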