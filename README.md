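# ophthCEA

Markov cohort cost-effectiveness analysis of intravitreal anti-VEGF therapy
— conbercept versus ranibizumab — for three neovascular macular diseases:
age-related macular degeneration (AMD), diabetic macular edema (DME), and
pathological myopia (PM). The package is aimed at health-economics analysts
who want the published Chinese-payer base case as a runnable, testable
model, and at anyone who needs a small, well-tested Markov CEA engine with
deterministic and probabilistic sensitivity analysis.

## The model

Health states are bands of best corrected visual acuity (BCVA, ETDRS
letters): six bands for AMD, five for DME and PM, ordered from no visual
impairment down to blindness. Each band carries a utility weight; DME/PM
utilities come from the linear valuation

```
u = 0.828 − 0.359 × logMAR,   logMAR = (85 − letters) / 50
```

evaluated at the band anchors 75, 60, 45, 30, 15 letters (logMAR 0.2 … 1.4),
while AMD uses literature values (0.9, 0.85, 0.81, 0.57, 0.52, 0.4).

Annual treatment outcomes are letter-change categories (±15 letters for
AMD/DME; ±30 and ±15 for PM) that map to one- and two-band shifts on the
severity ladder, giving a row-stochastic annual transition matrix; shifts
that would leave the ladder fold into the nearest feasible state. The
baseline cohort is propagated for 10 one-year cycles. Costs are
`unit price × annual injections` per cycle; both costs and QALYs are
discounted at 3.5 % per year. Two strategies are compared via

```
ICER = ΔC / ΔE,   CER = C / E,   NMB = λ·E − C
```

with a willingness-to-pay threshold λ of 3 × per-capita GDP
(3 × 70,892 = 212,676 RMB/QALY). Probabilistic sensitivity analysis draws
each arm's total cost from a gamma distribution (shape = 1/cv², scale =
mean·cv², so the draw mean equals the point estimate) and traces
cost-effectiveness acceptability curves.

## Worked example

```r
library(ophthCEA)
sc  <- load_builtin("AMD", "real_world")   # warns: baseline shares sum 0.9999
cmp <- run_scenario(sc)
cmp
#> <cea_comparison> conbercept vs ranibizumab (WTP 212,676.000 RMB/QALY)
#>   cost:  229,308.769 vs 264,944.591  (delta -35,635.822)
#>   QALY:  6.244 vs 6.739  (delta -0.494)
#>   CER:   36,722.155 vs 39,317.988
#>   ICER:  72,125.243
#>   dominance: trade_off; conbercept cost-effective at WTP: no
```

Read: over 10 discounted years conbercept's drug costs total 229,309 RMB
against ranibizumab's 264,945 RMB, so conbercept saves 35,636 RMB but gives
up 0.494 QALYs (its annual vision-gain probability is lower). The ICER of
the south-west comparison is 72,125 RMB per QALY forgone; since each forgone
QALY is valued at 212,676 RMB, the net-monetary-benefit rule says the saving
does not compensate the loss, so conbercept is *not* cost-effective for AMD
under strict NMB logic (see the methods vignette for how this relates to the
published directional reading). For DME and PM, conbercept is cheaper *and*
more effective — dominant — so the decision is unambiguous:

```r
run_scenario(load_builtin("DME"))$dominance
#> [1] "a_dominant"
```

Probabilistic sensitivity analysis and its acceptability curve:

```r
psa <- run_psa(sc, psa_config(iterations = 10000, seed = 1, cost_cv = 0.2))
psa
#> <psa_result> 10000 iterations, cost CV 0.20, seed 1
#>   P(conbercept cost-effective) ~ 0.145 near WTP 220,000 RMB/QALY
```

Deterministic sweeps and the negotiated-price preset:

```r
one_way_sweep(sc, sweep_spec("unit_price_a",
                             fluctuations = c(-0.1, -0.05, 0, 0.05, 0.1)))
run_scenario(negotiated_price_scenario(sc))   # 4,160 / 3,950 RMB prices
```

A command-line interface wraps the same verbs
(`run`, `sweep`, `psa`, `list-scenarios`, `validate`, `generate`):

```sh
Rscript -e 'quit(status = ophthCEA::cea_cli())' run --disease DME --out dme.csv
```

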