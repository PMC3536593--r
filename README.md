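# tlcnet

Reconstructs networks of biochemical reactions — which species converts into
which, and how fast — from noisy concentration time series, with no prior
knowledge of the topology. It was built for cellular pharmacokinetics: given
measured concentrations of a drug and its metabolites, it proposes the set
of biotransformations connecting them and estimates their rate constants.
The bundled benchmark is the gemcitabine (dFdC) pathway: extracellular and
intracellular drug, its mono-/di-/tri-phosphates, and the deaminated
metabolite dFdU with its phosphorylated forms — ten species joined by 19
first-order conversions.

## The method

Inference runs in two stages.

**Topology from time-lagged correlations.** For every ordered species pair
and every lag $\tau$ on a data-derived grid, the package estimates the
covariance of $X_i(t)$ and $X_j(t+\tau)$ over the lagged scatter plot, with
the pair density of the scatter estimated by a Voronoi tessellation (each
point's density is the reciprocal of its clipped cell area). Correlations
$r_{ij}(\tau) = C_{ij}/\sqrt{|C_{ii}C_{jj}|}$ are collapsed to proximities
$c_{ij} = \max_\tau |r_{ij}(\tau)|$ and distances
$d_{ij} = \sqrt{|c_{ii} - 2c_{ij} + c_{jj}|}$. Measurement errors are
propagated first-order all the way to the distances and to the stress of a
Kruskal–Shepard embedding (downhill simplex), whose dimension (2 vs 3) is
chosen from the error budget. A histogram-mode threshold on the distances
yields the undirected interaction graph, and the lag at which each pair's
correlation peaks orients the edges: the species that leads in time is the
putative reactant. Every edge is emitted as both opposed first-order
conversions — elimination is delegated to the next stage.

**Calibration by maximum likelihood.** The hypothesised reactions induce a
generalized mass action model $\dot X_i = \sum_h \theta_{ih} \prod_w
X_w^{\alpha_w}$. Observed increments $D_i(t_k)$ are Gaussian around
$(t_k - t_{k-1})\,E[f_i(X(t_{k-1}))]$ with a tridiagonal covariance
(diagonal $2\sigma^2$, off-diagonals $-\sigma^2$, from the shared endpoint
noise of consecutive increments). The likelihood is maximised exactly over
the nonnegative rate constants and the noise level, and every reaction whose
estimate is zero or whose relative standard error $\Delta k/\hat k$ reaches
1 is pruned as null kinetics. Inferred networks are scored against a
reference as Expected / Plausible (path-mediated) / Unexpected, with
sensitivity $(E{+}P)/\text{expected}$ and accuracy $E/(E{+}P)$.

## Worked example

```r
library(tlcnet)

res <- run_benchmark(seed = 7)   # simulate -> infer -> calibrate -> evaluate
print(res$inference$grid)
print(res$inference$network)
print(res$report)
```

```
Lag grid: 10 lags, step 0.1005 h, bound tau_min = 0.9375 h
Undirected network: 10 species, 32 edges (threshold 0.9239 on embedded distances)
Evaluation: 15 inferred (11 E, 4 P, 0 U) vs 19 expected
  sensitivity (plausibles included): 78.9%
  sensitivity (plausibles excluded): 57.9%
  accuracy E/(E+P): 73.3%   precision E/(E+P+U): 73.3%
```

Reading this: the lag bound estimated from the data allows lags up to nine
sampling steps; thresholding the embedded correlation distances proposes 32
undirected interactions (64 directed hypotheses); after likelihood
calibration and pruning, 15 reactions survive, of which 11 are exactly the
expected conversions and 4 are plausible chain-mediated shortcuts — none is
an outright false positive in this run. The retained constants sit in
`res$calibrated` (`attr(res$calibrated, "report")` shows every hypothesis
with its $\hat k \pm \Delta k$ and pruning decision).

Individual stages are exported (`simulate_pathway()`, `infer_network()`,
`calibrate()`, `evaluate()`, down to `voronoi_density()` and
`fit_embedding()`), and a thin command-line front end with subcommands
`simulate`, `infer`, `calibrate`, `evaluate` and `run-all` lives in
`inst/cli/tlcnet.R`. The methods vignette
(`vignettes/network-inference-methods.Rmd`) documents the model, every
tunable parameter and the numerical design choices.

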