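# twopatch

How does increasing dispersal between two habitat patches change the
total population size a species settles at? For two *source* patches
(each viable on its own) connected by symmetric dispersal, the
asymptotic total can end up above or below the sum of the two carrying
capacities, and the answer depends on the interplay of the patches'
intrinsic growth rates and carrying capacities. `twopatch` implements
the complete analysis of this question for the discrete-time
Beverton–Holt two-patch map and its continuous-time logistic analogue.
It is aimed at theoretical ecologists and at anyone evaluating
connectivity measures (corridors, stepping stones, translocation) whose
practical effect is a change in the dispersal rate.

## The model and the response function

Patch $i \in \{A, B\}$ has growth rate $r_i$ and carrying capacity
$K_i$. In discrete time, growth
$f_i(N) = r_i N / (1 + \xi_i N)$ (Beverton–Holt,
$\xi_i = (r_i - 1)/K_i$, $r_i > 1$) is followed by dispersal of a
fraction $\delta \in [0, 1]$ of each patch's output:

$$N_{A,t+1} = (1-\delta) f_A(N_{A,t}) + \delta f_B(N_{B,t}),
\qquad
N_{B,t+1} = (1-\delta) f_B(N_{B,t}) + \delta f_A(N_{A,t}).$$

In continuous time the patches grow logistically,
$f_i(N) = r_i N (1 - N/K_i)$, coupled by the flux
$\delta_c (N_A - N_B)$, $\delta_c \ge 0$. Both systems have a unique
positive equilibrium $(N_A(\delta), N_B(\delta))$ attracting every
non-trivial initial state. Everything revolves around the
**dispersal-response function**

$$H(\delta) = N_A(\delta) + N_B(\delta) - (K_A + K_B),$$

positive when dispersal is beneficial. $H$ is monotone or unimodal and
has at most one non-trivial zero, so exactly four response scenarios are
possible: *monotonically beneficial*, *unimodally beneficial*,
*beneficial turning detrimental*, and *monotonically detrimental* (plus
the neutral equal-capacity case, $H \equiv 0$). The package provides

* the dynamics (`step_discrete()`, `vector_field_continuous()`,
  `simulate()`) and equilibrium solvers (`equilibrium()`,
  `response_curve()`),
* every closed form: the second zero `delta_tilde()`, the argmax
  `delta_max()`, the slope at zero `h_prime_zero()`, the maximum
  attainable total `max_population_summary()`, the replacement
  equilibrium `equilibrium_delta_one()`, continuous-time limits
  `continuous_limits()`, and the threshold constants `kappa_discrete()`
  / `kappa_continuous()`,
* exact parameter-condition classifiers (`classify()`, on the full
  dispersal range or restricted to $[0, 0.5]$) plus an independent
  curve-shape classifier (`classify_empirical()`),
* the chord construction behind the discrete equilibrium
  (`graphical_construction()`), plotting, a seeded scenario sampler
  (`generate_scenario_params()`), and a command line (`exec/twopatch`).

## Worked example

A patch with fast growth and a large capacity coupled to a slow, small
patch — but with the *stronger* competition in the small patch:

```r
library(twopatch)
m <- two_patch(r_A = 3.4, r_B = 1.5, K_A = 8.4, K_B = 1.37)
summary(m)
#> Closed-form summary (discrete mode)
#> Two-patch discrete-time model (Beverton-Holt growth)
#>   patch A: r = 3.4, K = 8.4, xi = 0.2857
#>   patch B: r = 1.5, K = 1.37, xi = 0.365
#>   admissible dispersal: delta in [0, 1]
#>   scenario: beneficial_turning_detrimental
#>   H'(0+):   11.1308
#>   delta_tilde (second zero of H): 0.374844
#>   delta_max: 0.128358 (interior maximum)
#>   max total: 10.1328 at delta = 0.128358
#>   kappa_d:   2.08058
```

Small dispersal rates are strongly beneficial (the initial slope of $H$
is 11.13 individuals per unit dispersal rate): emigrants from the big
patch escape into milder competition. The benefit peaks at
$\delta_{max} = 0.128$, where the total reaches 10.13 individuals versus
$K_A + K_B = 9.77$ when isolated. Beyond $\tilde\delta = 0.375$ the
effect turns detrimental — the small patch becomes oversaturated.
The numeric equilibria tell the same story:

```r
predict(m, delta = c(0, 0.2, 0.5, 1))
#>   delta      N_A      N_B          H
#> 1   0.0 8.400000 1.370000  0.0000000
#> 2   0.2 6.710768 3.380153  0.3209207
#> 3   0.5 4.714511 4.714511 -0.3409785
#> 4   1.0 2.685724 5.166754 -1.9175217
```

`plot(m)` draws the response curve with the $K_A + K_B$ reference line,
the perfect-mixing guide at $\delta = 0.5$ and a marker at the maximum.
The same analyses run from a shell:

```sh
exec/twopatch classify --mode discrete --rA 3.4 --rB 1.5 --KA 8.4 --KB 1.37
exec/twopatch curve --mode discrete --rA 3 --rB 1.5 --KA 2 --KB 1.5 --points 201 --out curve.csv
```

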