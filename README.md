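# starkit

Kinetic modeling, circuit composition and plate-reader analysis of
**regulatory RNA arrays** — single transcripts carrying 1–8 tandem copies of
a small transcription activating RNA (STAR), separated by cleavable
insulators (Csy4 hairpins or ribozymes). Cleaving the array converts one
transcription event into several independently acting activators, so the
output gain of a STAR-controlled gene is tuned by copy number alone. The
package is for synthetic biologists who want to simulate such arrays and
their circuits (amplifiers, activation–activation cascades, 1-to-2
multiplex motifs), analyse plate-reader characterisation data with the
field's standard normalisation pipeline, and sanity-check array designs at
the sequence level.

## The model

One array transcription unit has three species — intact array transcript
*A*, free STAR pool *S*, output RNA *G*:

    A' = u − (k_c + d_A)·A
    S' = ε·n·k_c·A − d_S·S
    G' = a_T·(λ + (1−λ)·θ(S)) − d_G·G,   θ(S) = S/(K+S)

with closed-form steady state `A* = u/(k_c+d_A)`,
`S* = ε·n·k_c·A*/d_S`, `G* = (a_T/d_G)·(λ + (1−λ)·θ(S*))`.
Here `u` is the transcription input into the array, `n` the STAR copy
number, `ε` the per-copy cleavage/release efficiency, `λ` the off-state
leak fraction and `K` the half-activation STAR level (all arbitrary
units). Leak-subtracted output is proportional to θ, so in the
sub-saturating regime output scales linearly with `n`, and as `u → 0` the
8-copy/1-copy gain ratio tends to exactly 8.

## Worked example

```r
library(starkit)

p <- model_params()                    # defaults: k_c=1, d_A=0.1, d_S=d_G=a_T=1,
steady_state(with_params(p, n = 4))    #           K=10, eps=0.9, lam=0.02
#> steady state: A* = 0.454545, S* = 1.63636, G* = 0.157812 (theta = 0.140625)

gain_vs_copies(p, copies = c(1, 2, 4, 6, 8), u = 0.5)
#>  n     G_star
#>  1 0.05851528
#>  2 0.09411765
#>  4 0.15781250
#>  6 0.21313869
#>  8 0.26164384
#> least-squares: G* = 0.03514 + 0.02903 n;  Pearson r = 0.997778

limiting_gain_ratio(p, n_hi = 8, n_lo = 1)   # leak-subtracted 8x/1x, u -> 0
#> [1] 8

# synthetic copy-sweep plate -> correction pipeline -> copy correlation
plate <- generate_copy_sweep(noise = noise_model(seed = 1))
copy_sweep_correlation(correct_plate(plate))
#> $r  0.977  $p  1.78e-13  $df 18  $n 20

# cascade with a 4-copy array amplifier between the two stages
casc <- build_cascade(array = array_spec(c(STAR10 = 4)))
fold_activation_sim(casc)
#> [1] 7.072394
```

The gain table shows the steady-state output at input 0.5 rising almost
linearly from 1 to 8 copies (r = 0.9978; the residual curvature is the
onset of θ saturation). On the noisy synthetic plate (4 biological
replicates, 10% biological CV) the pipeline recovers the linear relation
with r = 0.977 on the 20 replicate-level points (df = 18). The cascade fold
is the on/off ratio of the terminal GFP reporter.

A command-line interface covers the same ground (`exec/starkit`):

```sh
starkit simulate --params inst/extdata/default_params.json --n 4 --u 0.5 --t-end 100 --out traj.csv
starkit sweep --grid 0:1:0.05 --copies 1,2,4,6,8 --out curve.csv
starkit synth --seed 7 --out plate.csv
starkit analyze --plate plate.csv --out report.json
starkit design --star inst/extdata/synthetic_parts.fa --insulator inst/extdata/synthetic_parts.fa --copies 4 --out array.fa
```

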