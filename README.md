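# tdacohort

Topological data analysis of mixed-type clinical cohorts: find and interpret
the **loops** and **voids** in a "space of patients".

## The problem

A clinical cohort table — continuous labs, ordinal stages, nominal
categories, binary markers, with missing values throughout — places each
patient at a point in a high-dimensional space. Cluster analysis describes
that point cloud only as groupings. Persistent homology goes further: it
detects *holes* in the cloud — combinations of characteristics that no
patient exhibits — stratified by dimension. Dimension-0 classes are the
familiar clusters; dimension-1 classes ("loops") enclose an empty disc;
dimension-2 classes ("voids") enclose an empty ball. A loop or void flags a
constraint structure among clinical variables that clustering cannot see.

`tdacohort` implements the full chain for epidemiologists and
biostatisticians working with such tables:

1. **Mixed-type distances.** Gower dissimilarity (the `daisy` metric) over
   continuous, ordinal, nominal, symmetric-binary and asymmetric-binary
   features, with missing-aware weights:
   `d(i,j) = Σ_k δ_ijk d_ijk / Σ_k δ_ijk`, all distances in [0, 1].
2. **Persistent homology.** The Vietoris–Rips filtration over Z/2 in
   dimensions 0–2, computed in C++ (union-find for dimension 0; persistent
   cohomology with clearing for the pairing; a restricted homology pass for
   **representative cycles** — the patients that actually trace out each
   loop or void).
3. **Significance.** An empirical Bayes two-group mixture on bar durations:
   an exponential null with rate `λ = ln 2 / median(duration)`, a
   conservative null prior `p0`, and per-bar posterior probabilities
   `P(real | duration) = 1 − p0·f0(x)/f̂(x)` of being genuine structure.
4. **Interpretation.** For a significant loop: 20°-sector averaging of every
   feature around the loop centroid, a sinusoidal fit per feature, and the
   goodness-of-fit statistic **κ = MSE/σ²** (small κ = circular behaviour);
   centroid-separation axes for binary variables; a circular-plot export
   table. For a void: three binary axes with a linear-independence
   determinant, a unit-sphere projection, and an OFF mesh of the skeleton.
5. **Synthetic cohorts.** Generators that plant a latent loop (phase-shifted
   binary factors around a circle) or a void (diffused cube vertices pushed
   to a sphere), plus unstructured null cohorts — so the whole pipeline is
   testable without any external data.

## Worked example

Simulate a 300-patient cohort with three phase-shifted binary prognostic
factors planted around a latent loop, then recover and interpret the loop:

```r
library(tdacohort)

ch <- simulate_loop_cohort(seed = 42)   # 300 subjects x 8 mixed features
d  <- daisy_distance(ch)                # Gower distances in [0, 1]
ph <- vietoris_rips(d, max_dim = 1)     # barcode + representative cycles

scored <- score_barcodes(ph)            # empirical Bayes posteriors
head(scored, 3)
#>   dimension      birth      death   duration posterior
#> 1         1 0.16148194 0.37096697 0.20948503 1.0000000
#> 2         1 0.16821712 0.18004559 0.01182847 0.2350549
#> 3         1 0.04404272 0.05601322 0.01197050 0.2343905
glance(attr(scored, "models")[["1"]])
#>    rate    p0     n dimension median_duration
#> 1  126.     1   199         1         0.00551
```

The planted loop is unmistakable: one bar lives for 0.209 units of the
filtration scale while the next-longest survives 0.012, and its posterior
probability of being real structure is 1.00 against a fitted exponential
null (rate 126, null prior 1).

Interpret it by ranking features with κ and by centroid separation:

```r
emb <- embed_distance(d, method = "mds", k = 2)
top <- most_persistent(ph, 1)
lf  <- loop_fit(ch, emb, representative_cycle(ph, top),
                features = setdiff(schema_of(ch)$feature,
                                   c("coord_x", "coord_y")))
head(tidy(lf), 4)[, c("feature", "kappa", "peak_angle")]
#>         feature     kappa peak_angle
#> 1 loop_factor_1 0.1248738   344.8459
#> 2 loop_factor_2 0.1259838   104.3439
#> 3 loop_factor_3 0.1592537   218.8720
#> 4   noise_num_2 0.6970232   125.6299
```

The three planted factors take the three smallest κ values (strongly
circular sector profiles; pure noise sits near κ ≈ 0.9), and their fitted
peaks are ~120° apart — exactly the phase shifts the generator planted.
Their groups are also the most widely separated in the embedding:

```r
chb <- ch
for (f in schema_of(ch)$feature[schema_of(ch)$type == "continuous"])
  chb <- dichotomize_median(chb, f)     # continuous features -> Low/High
dplyr::arrange(centroid_separation(chb, emb), dplyr::desc(separation))
#>         feature separation
#> 1 loop_factor_1  0.3700004
#> 2       coord_x  0.3669328
#> 3 loop_factor_3  0.3599848
#> 4 loop_factor_2  0.3564777
```

`autoplot(ph)` draws the barcode, `autoplot(emb, loop = rep)` the embedding
with the loop overlaid, `write_circos(lf, "circos.csv")` the sector-mean
table for circular-plot tools, and `run_pipeline()` executes the whole
chain and writes every artifact to a directory. A thin command-line
interface (`inst/cli/tdacohort`) exposes each stage as a subcommand
(`simulate`, `distance`, `persist`, `score`, `interpret`, `depend`,
`report`).

## Analyzing your own cohort

Provide a CSV with a header row and a JSON/YAML schema declaring each
column's type (`continuous`, `ordinal`, `nominal`, `binary_symmetric`,
`binary_asymmetric`):

```r
ch <- read_cohort("cohort.csv", "schema.json")
res <- run_pipeline(list(cohort = ch, out_dir = "results", seed = 1))
```

## Vignette

`vignettes/cohort-topology.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, what the synthetic
generators do and do not emulate, the numerical choices (tie-breaks,
truncation, density estimation), and known limitations.
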