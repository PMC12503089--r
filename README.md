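# immunodesign

Optimal blood-sampling schedules for immunization studies whose goal is to
characterize antibody kinetics — the rise of antibody concentration to a peak
after an immunization event and its decay to a plateau.

Optimal design theory can place a study's blood draws where they are most
informative, but for nonlinear kinetic models it requires guesses of abstract
model parameters. `immunodesign` instead takes five quantities a clinician
can state directly at the planning stage:

| input | meaning |
|-------|---------|
| `A0` | antibody concentration at the immunization event (0 unless pre-existing antibodies) |
| `tmax`, `Amax` | time (days) and height of the expected peak |
| `tplat`, `Aplat` | time and height of the expected plateau |

## The model

The mean concentration follows the shape of a beta density until the plateau:

    E[A(t)] = f((t + c)/t_scale, alpha, beta)   for 0 <= t < tplat
            = Aplat                             for t >= tplat

with `f(x, a, b) = x^(a-1) (1-x)^(b-1) / B(a, b)`, shapes `alpha, beta > 1`
(single interior peak at the mode `(alpha-1)/(alpha+beta-2)`), a time scaling
`t_scale`, and a shift `c >= 0` that lets the curve start above zero (`c = 0`
iff `A0 = 0`). The five inputs pin down the parameters uniquely through the
mode equation and one height equation per stated concentration;
`calibrate()` solves this nonlinear system with a multi-start Broyden/Newton
search in constraint-respecting log coordinates.

Measurements are modelled as multivariate normal around the mean with known
standard deviation `sigma` and AR(1) correlation `rho^|i-j|` between draws.
`optimal_design()` minimizes `-ln(det(FIM) + 1)`, `FIM = J' Sigma^-1 J`, over
as many sampling times as parameters (3 or 4) with a bound-constrained
Hooke–Jeeves pattern search; the optimal times do not depend on `sigma` or
`rho`. `d_efficiency()` compares schedules via
`(det FIM_cand / det FIM_opt)^(1/p)`. A 12-scenario preset library and
misspecification sweeps (`sweep_single()`, `sweep_double()`) quantify how
much efficiency a wrong input costs.

## Worked example

A study with no pre-existing antibodies, an expected peak of 10 units at day
30, and a plateau of 1 unit from day 365:

```r
library(immunodesign)

info <- initial_information(A0 = 0, tmax = 30, Amax = 10, tplat = 365, Aplat = 1)
cal <- calibrate(info)
cal
#> Calibration converged (broyden, attempt 17, residual 6.75e-11)
#> Beta-curve parameters: alpha = 1.2351, beta = 15.8123, t_scale = 1919.88, c = 0.0000

des <- optimal_design(cal$params, info)
des
#> Sampling design (days): 0.30, 29.78, 185.57
#>   windows: [0, 365] [0, 365] [0, 365]
#>   objective: -3.12751
#>   det_fim: 21.8171
#>   n_evals: 600

d_efficiency(c(91.25, 182.5, 273.75), des$times, cal$params, error_model())
#> [1] 0.0732
```

Reading the output: the fitted curve peaks at 10 units on day 30 (the
calibration residual of `7e-11` says the five inputs are matched essentially
exactly), and the D-optimal 3-sample schedule draws blood almost immediately
(day 0.3, where the curve rises fastest), at the peak (day 29.8), and
mid-decay (day 185.6). The habitual quarterly schedule (days 91/183/274)
achieves a D-efficiency of only 0.07 — per sample it extracts a small
fraction of the information the optimal schedule gets.

Clinically fixed visits can be imposed as per-time windows
(`optimal_design(..., windows = list(lower = ..., upper = ...))`), and
`sweep_single(scenario(1), "tmax")` shows how robust the schedule is if an
input was misstated. A thin command-line front end over the same functions
is installed at `inst/cli/immunodesign.R` (subcommands `calibrate`, `design`,
`efficiency`, `robustness`, `simulate`, driven by a YAML/JSON config; see
`inst/extdata/example_study.yaml`).

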