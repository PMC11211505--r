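# stmmr — Bayesian spatio-temporal CAR models for areal maternal mortality counts

`stmmr` fits Bayesian spatio-temporal random-effects models to short panels
of areal counts — the setting of state-level maternal mortality ratio (MMR)
surveillance, where N areas on a contiguity graph are observed over a few
rolling reporting periods. It is aimed at epidemiologists and biostatisticians
doing small-area disease mapping who want the full workflow in one place:
simulation, fitting, hot-spot classification, model comparison and
descriptive displays, all reproducible from a single seed.

## The model

Counts follow a Poisson likelihood whose log relative risk decomposes into
level, space, heterogeneity, covariates and trend:

    O_it ~ Poisson(E_it * rho_it)
    log(rho_it) = alpha + s_i + u_i + sum_k beta_k x_ik + (gamma + delta_i) * time_t

* `s_i` — spatially structured effect, intrinsic CAR (ICAR) prior on the
  adjacency graph, sum-to-zero constrained (with `u_i`, the BYM convolution);
* `u_i` — unstructured heterogeneity, iid Normal;
* `gamma` — common linear time trend; `delta_i` — ICAR-distributed
  area-specific trend deviations (positive means locally rising risk);
* `E_it` — expected counts: 1 for already-standardised ratios such as MMR,
  or per-period internal standardisation from denominators.

Inference is adaptive Metropolis-within-Gibbs MCMC. Post-inference, the
spatial relative risk is `exp(posterior mean of s_i)`, the exceedance
probability is `P(rho_i > 1 | Y)`, and areas with exceedance probability
strictly above 0.5 are classified hot spots. Models are compared by DIC with
the effective-parameter count taken over the full latent field. Three
variants are predefined: the spatio-temporal baseline (model 1), a
maternal-health covariate model (model 2) and a health-system covariate
model (model 3).

## Worked example

Simulate a 19-state panel over 5 periods from known truth (overall level
`alpha = 2.3`, common decline `gamma = -0.12`, expected counts 100) and
refit it:

```r
library(stmmr)
g   <- make_srs_graph()                       # 19-state contiguity graph
sim <- simulate_panel(g, truth = list(alpha = 2.3, gamma = -0.12, tau_s = 10,
                                      tau_u = 100, tau_delta = 10),
                      T = 5, expected = matrix(100, 19, 5), seed = 2024)
fit <- stmmr(sim$panel, g, model = 1, expected = matrix(100, 19, 5),
             iters = 4000, burnin = 1500, thin = 2, chains = 2, seed = 1)
summary(fit)
```

```
Posterior summary (mean, sd, 95% credible interval, rr = exp(mean))
 parameter      mean        sd    q2.5     q97.5     rr
     alpha    2.2929 4.744e-02  2.2240    2.4104 9.9032
     gamma   -0.1174 2.445e-03 -0.1222   -0.1126 0.8892
     tau_s  902.0630 1.609e+03  2.7931 5488.7035     NA
     tau_u 1176.3898 1.880e+03  6.1631 6608.5601     NA
 tau_delta   12.8663 4.100e+00  5.9856   22.3726     NA
... plus 57 latent area effects (s, u, delta)
DIC = 970.4 (Dbar = 932.7, pD = 37.7)
```

The fitted common trend (posterior mean −0.117, 95% CI [−0.1222, −0.1126])
recovers the generating value −0.12; `rr = 0.889` says risk falls about 11%
per period. The per-area risk table ranks hot spots:

```r
rk <- risk_report(fit)
head(rk[order(-rk$exceed_prob), ], 5)
```

```
   area_id spatial_rr exceed_prob label delta_mean delta_lo delta_hi
4    area4       1.19       0.824   hot     0.0287   0.0115   0.0452
16  area16       1.29       0.812   hot     0.3278   0.3120   0.3428
12  area12       1.20       0.811   hot     0.1394   0.1229   0.1561
7    area7       1.18       0.803   hot     0.0815   0.0640   0.0976
3    area3       1.10       0.801   hot     0.2093   0.1922   0.2269
```

`spatial_rr` is each area's multiplicative departure from the national
level; `exceed_prob > 0.5` marks a hot spot; a positive `delta_mean` (e.g.
area 16, +0.33 per period above the common trend) flags locally rising risk.

Real data enter through `read_panel()` (counts CSV with columns
`area_id,time_id,observed[,population]`, optional covariates CSV) and
`read_graph()` (neighbour-list text file). `run_pipeline()` drives
simulate/read → descriptives → fit → risk → DIC from a config list or YAML
file and writes a deterministic artifact set with a run log.
`area_trends()` and `heatmap_matrix()` reproduce the descriptive layer
(per-area OLS trend fits with 95% CIs; column-standardised heatmap
matrices).

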