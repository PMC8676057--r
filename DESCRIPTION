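Package: ophthCEA
Title: Markov Cohort Cost-Effectiveness Analysis of Anti-VEGF Therapy for
    Macular Disease
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Markov cohort model for the cost-effectiveness of intravitreal
    anti-VEGF therapy (conbercept versus ranibizumab) in age-related macular
    degeneration, diabetic macular edema, and pathological myopia. Health
    states are bands of best corrected visual acuity (ETDRS letters) valued
    with a linear logMAR utility mapping; annual letter-change outcome
    probabilities become row-stochastic transition matrices; discounted costs
    and QALYs feed ICER, CER, dominance, and net-monetary-benefit statistics.
    Includes deterministic one-way/two-way sensitivity sweeps, negotiated
    drug-price scenarios, gamma-cost probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, a built-in scenario library,
    JSON scenario configs, a synthetic scenario generator for property
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
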