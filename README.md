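# danai

Atomic-interaction topology analysis of molecular dynamics trajectories.

## What it does, and for whom

Liquids of small halogenated molecules — the motivating system is
1,1,1,2-tetrafluoroethane (HFA-134a), the propellant of metered dose
inhalers — hold together through weak induced-dipole carbon–carbon
contacts.  A single MD frame of 1000 molecules contains thousands of them,
and the interesting structure is not any one contact but their *local
topology*: isolated pairs, chains, three-membered rings, star-like
junctions.

`danai` is for simulators who want that topology as numbers.  Per trajectory
frame it:

1. extracts the chemically tagged carbon centers (DL_F-style species codes:
   `C180` = monohaloalkane carbon, `C182` = trihaloalkane carbon),
2. builds the **interaction map**: a graph with an edge between every pair
   of centers of different molecules whose minimum-image distance is within
   a cutoff (default **5 Å**),
3. counts the motifs of a 20-statement library written in **DANAI**
   notation (DL_ANALYSER Notation for Atomic Interactions), grouped into
   the macro classes `ID_182_182`, `ID_180_180`, `ID_180_182`,
4. assembles per-frame counts into time series and reports, per mode *i*,
   the mean count μ<sub>i</sub> over frames, its standard deviation, and
   the mode–mode Pearson correlation

   C<sub>x−y</sub> = ⟨ΔC<sub>x</sub>·ΔC<sub>y</sub>⟩ / √(⟨ΔC<sub>x</sub>²⟩⟨ΔC<sub>y</sub>²⟩),  ΔC<sub>i</sub> = C<sub>i</sub> − μ<sub>i</sub>.

A DANAI statement encodes a motif's topology and isolation, e.g.
`[L2]C182:C180` — an isolated pair of one CF3 and one CH2F carbon;
`[R3]c182:c182:c182:c182` — a three-ring whose members may have further
contacts; `[J5]c182:(c182:)c182(:c182):c182` — a four-fold star junction.
The package ships the full grammar (parser, canonicalizer, serializer), a
DL_POLY-style HISTORY and XYZ reader/writer, a synthetic dimer-liquid
generator and planted-motif fixtures, and an independent brute-force census
oracle used by the tests.

## Worked example

```r
library(danai)

# the study system's stated world: 1000 two-center molecules, 53 A cubic box
traj   <- generate_liquid(n_molecules = 1000, box_length = 53,
                          n_frames = 3, seed = 42)
series <- analyze_trajectory(traj)          # 5 A cutoff, 20 built-in modes
sm     <- summarize_series(series)
sm[grepl("182", sm$mode) & !grepl("180", sm$mode), ]
#>                              mode        mean  deviation
#>                     [L2]C182:C182    0.666667   0.471405
#>                     [L2]c182:c182 1560.666667  28.778850
#>                [L3]c182:c182:c182 4434.666667 170.043785
#>           [R3]c182:c182:c182:c182  510.000000  21.354157
#>         [J4]c182:c182(:c182):c182 3821.000000 219.312562
#>         [J4]C182:C182(:C182):C182    0.000000   0.000000
#>  [J5]c182:(c182:)c182(:c182):c182 2249.333333 199.593476
```

Read: across three frames, the CF3–CF3 macro class averaged ~1561 pair
contacts per frame, of which not even one per frame was an *isolated* pair
(uppercase `[L2]C182:C182`, mean 0.67) — in a dense random packing almost
every center has further neighbors.  Chains (`L3`), rings (`R3`) and
junctions (`J4`, `J5`) follow the `sum(choose(degree, k))` census
arithmetic.  (These are i.i.d. random packings, denser in contacts than the
equilibrated liquid; see the methods vignette.)

```r
cm <- correlation_matrix(series)
cm["[L2]c182:c182", "[L3]c182:c182:c182"]
#> [1] 0.9980214   # pair and chain counts rise and fall together

# planted fixture with an exactly known census
fr <- plant_pattern(parse_danai("[R3]c182:c182:c182:c182"))
cnt <- analyze_frame(fr)
cnt[cnt > 0]
#>           [L2]c182:c182      [L3]c182:c182:c182 [R3]c182:c182:c182:c182
#>                       3                       3                       1
```

A planted triangle is one ring, three chains and three pairs — and zero
*isolated* pairs, since every member has degree 2.

## Command line

```sh
Rscript inst/exec/danai generate --n 1000 --box 53 --frames 5 --seed 1 --out HISTORY_synth
Rscript inst/exec/danai analyze  --traj HISTORY_synth --molecule-size 2 --out counts.csv
Rscript inst/exec/danai stats    --counts counts.csv --summary summary.csv --correlation correlation.csv
Rscript inst/exec/danai parse    "[J4]c182:c182(:c182):c182"
```

(After installation the wrapper lives at
`system.file("exec", "danai", package = "danai")`.)  `analyze` also reads
gzip-compressed HISTORY files and multi-frame XYZ (`--format xyz --box L`);
`--config file` supplies `key=value` defaults.

## Layout

* `R/` — cell geometry, trajectory I/O, contact graph, DANAI grammar,
  motif census, oracle, statistics, CSV output, CLI.
* `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
* `vignettes/danai-methods.Rmd` — the model, counting semantics, canonical
  forms, generator scope and numerical choices.
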