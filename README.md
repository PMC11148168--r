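# oxymida

Cultured cells sit at the bottom of a millimetres-deep column of stagnant
medium, and oxygen reaches them only by diffusion from the air–medium
interface. For strongly respiring monolayers (adipocytes, hepatocytes,
macrophages, cardiac organoids) delivery through that column can fall short
of demand, leaving the cells hypoxic even in an 18%-oxygen incubator — with
large downstream effects on glycolysis, lipogenesis and gene expression.
`oxymida` packages the desk-side quantitative tools for working in this
regime:

1. **A steady-state Fick's-law oxygen model of the medium column.** With
   consumption confined to the monolayer, the flux through a column of depth
   *x* is `J = D·Δφ/x`, so the maximum sustainable oxygen consumption rate
   (OCR) is `J_max = D·C_interface/x` and the concentration profile above the
   cells is linear. The model predicts pericellular oxygen, the maximum OCR a
   given plate/volume can support, the maximum depth compatible with a
   demanded OCR, and sensor-window concentration profiles. Defaults:
   `D = 2.69e-3 mm²/s`, interface oxygen 181 µM (140 mmHg), critical oxygen
   4 µM; flux in fmol/mm²/s throughout.

2. **A MIDA estimator of de novo lipogenesis (DNL).** Under labelling with
   8% deuterated water, a fatty acid synthesised de novo draws *N*
   exchangeable hydrogens from the water pool (enrichment *p*), giving a
   binomial isotopologue pattern `M'x = C(N,x)·p^x·(1−p)^(N−x)`. Convolution
   with the natural-abundance envelope of the molecular formula yields the
   newly-synthesised pattern, and the measured M+0…M+4 envelope is the
   mixture `f·Mxn + (1−f)·Mx` of new and pre-existing molecules. The package
   fits (f, p) by bounded multistart least squares, determines *N* by
   scanning for the candidate whose fitted *p* matches the known water
   enrichment, and converts *f* to absolute DNL via the fatty-acid pool size.

Plus extracellular glucose/lactate flux arithmetic normalised to well area,
and seeded synthetic-data generators for every input format, so the whole
pipeline is testable without instrument data.

## Worked example

Is 1 mL of medium in a 12-well plate enough to support an adipocyte
monolayer consuming 200 fmol/mm²/s?

```r
library(oxymida)
oxygen_report(medium_spec(1000, "12-well"), ocr_demand = 200)
#> minimum depth 2.40 mm: capacity 202.7, realised OCR 198.3 fmol/mm^2/s, pericellular O2 4.0 uM [limited]
#> nominal depth 2.63 mm: capacity 185.0, realised OCR 180.9 fmol/mm^2/s, pericellular O2 4.0 uM [limited]
```

Even at the meniscus minimum (2.40 mm) the column can carry ~203 fmol/mm²/s
with pericellular oxygen at zero, but only ~198 while keeping the monolayer
at its 4 µM critical concentration — the cells are diffusion-limited, with
pericellular oxygen pinned at the critical level. The depth ceiling for this
demand is `max_depth(200)` = 2.43 mm.

Simulate a deuterated-water labelling experiment and recover its parameters:

```r
tab <- gen_mida_dataset(f = 0.25, p = 0.08, N = 14, noise_cv = 0.01,
                        n_replicates = 3, seed = 42, amount_nmol = 40)
run_mida_table(tab)
#>   sample fatty_acid      f       p  N       sse converged flags dnl_nmol
#> 1 sim001  palmitate 0.2402 0.08261 14 6.489e-07      TRUE          9.606
#> 2 sim002  palmitate 0.2582 0.07784 14 1.669e-06      TRUE         10.327
#> 3 sim003  palmitate 0.2539 0.08273 13 2.880e-06      TRUE         10.157
```

At 1% multiplicative GC-MS noise the fractional synthesis f = 0.25 is
recovered to within ~0.01 and the N-scan usually lands on the true 14
exchangeable sites; `dnl_nmol = f × 40 nmol` is the absolute amount of newly
synthesised palmitate.

Glucose/lactate fluxes from an endpoint medium assay:

```r
compute_fluxes(medium_assay(25, 13, 0, 8, volume = 1000, duration = 16,
                            plate = "12-well"))
#> <flux_record> glucose uptake 1.974, lactate production 1.316 nmol/mm^2/h; lactate fraction 0.333
```

The lactate fraction is lactate production over twice glucose uptake — the
share of consumed glucose carbon exported as lactate (1.0 = fully anaerobic
glycolysis).

A thin command-line wrapper is installed at
`system.file("cli", "oxymida.R", package = "oxymida")` with subcommands
`oxygen`, `mida`, `fluxes` and `simulate`.

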