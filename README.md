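# satif

Even an electrically compact neuron — a cell like a cerebellar granule cell,
with no independent dendritic subunits and a single membrane voltage — can
compute linearly non-separable Boolean functions, provided its synapses
interact through locally *saturating* conductances. `satif` implements the
model behind that claim, the task battery that probes it, and the
certification machinery that proves the task is out of reach for any linear
threshold unit.

The package is for computational neuroscientists and threshold-logic-curious
modellers who want to simulate the model, regenerate the task family, or
reuse the separability certifiers on their own truth tables.

## The model

The **saturating integrate-and-fire (SIF)** neuron is a one-compartment
leaky integrate-and-fire cell,

&nbsp;&nbsp;&nbsp;&nbsp;τ dv/dt = −(v(t) − v_rest) + R · I_s(t),
&nbsp;&nbsp;&nbsp;&nbsp;I_s(t) = Σⱼ gⱼ(t) · (E_s − v(t)),

with a spike-and-reset rule at threshold, whose synaptic inputs are pooled
into a small number of conductance *groups*. Each group j obeys

&nbsp;&nbsp;&nbsp;&nbsp;gⱼ → g_max on each afferent spike (set-to-max),
&nbsp;&nbsp;&nbsp;&nbsp;dgⱼ/dt = −gⱼ/τ_s otherwise,

so a group's conductance is bounded in [0, g_max] no matter how many of its
inputs fire: nearby synapses share a local ceiling on conductance per unit
of membrane surface. The classical **LIF** is the special case of a single
*unbounded additive* group — every spike adds g_max, so total drive depends
only on the spike count ([`make_lif()`]).

Defaults: τ = 20 ms, v_rest = −65 mV, R = 20 MΩ, threshold −62 mV, reset
−65 mV, E_s = 0 mV, τ_s = 1 ms, g_max = 100 pS, four inputs with sources
{1,2} → group 1 and {3,4} → group 2.

The **compact feature binding problem (cFBP)** is the 4-row partial Boolean
function over inputs (1,2,3,4):

| inputs | output |
|--------|--------|
| 0011   | 0 |
| 1100   | 0 |
| 0101   | 1 |
| 1010   | 1 |

Activating one input *cluster* must stay silent; activating one input from
*each* cluster must fire. Summing the two 0-row threshold inequalities gives
w₁+w₂+w₃+w₄ ≤ 2Θ while the two 1-rows give w₁+w₂+w₃+w₄ > 2Θ — no weight
vector exists, so the task is linearly non-separable (as hard as XOR, yet
solvable with purely excitatory inputs). A SIF with two saturating groups
solves it by conductance arithmetic: a clustered pattern saturates one group
(total g = 100 pS) while a scattered pattern recruits both (200 pS).

## Worked example

```r
library(satif)

spec   <- sif_neuron()                      # 4 inputs -> 2 saturating groups
config <- protocol_config(make_cfbp(2), mode = "spike")

calibrate(spec, config)
#> <sif_calibration: drive_scale 100, v_threshold -64.1320 mV, margin 0.2874 mV>

run_protocol(spec, config, calibrate(spec, config)) |> tidy()
#> # A tibble: 4 × 6
#>   pattern expected n_spikes peak_voltage_mV mean_rate_hz output
#> 1 0011           0        0           -64.4            0      0
#> 2 1100           0        0           -64.4            0      0
#> 3 0101           1        1           -64.2            2      1
#> 4 1010           1        1           -64.2            2      1
```

The calibration raises the conductance ceilings a hundredfold (the printed
parameter magnitudes leave single-spike responses ~10 µV above rest) and
places the threshold in the 0.57 mV gap between the clustered and scattered
peak depolarisations; the four stimulation episodes then reproduce the
truth table exactly. The matched LIF cannot — its four episode traces are
bit-for-bit identical, so no threshold separates them:

```r
implements_table(make_lif(spec), config) |> glance()
#> # A tibble: 1 × 6
#>   implements agreement calibratable ... reason
#> 1 FALSE             NA FALSE            not calibratable: no peak-voltage gap...
```

And the task itself is certifiably non-separable:

```r
is_linearly_separable(make_cfbp(2))
#> <separability_certificate: NON-SEPARABLE (lp method)>
attr(check_pairing_contradiction(make_cfbp(2)), "pairing")
#> role  pattern: zero 0011 | zero 1100 | one 0101 | one 1010
```

A command-line interface wraps the same functions
(`inst/exec/satif simulate|protocol|separability|fixtures`); bundled
plain-text fixtures live in `inst/extdata/` and can be regenerated with
`write_fixtures()`.

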