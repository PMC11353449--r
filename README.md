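# pdmaxent

Accelerated primal–dual solvers for non-smooth, regularized maximum-entropy
(MaxEnt) density estimation over discrete site grids — the estimation
problem behind presence-only species distribution and wildfire occurrence
modeling.

## The problem

Given a strictly positive prior $p_{\mathrm{prior}}$ over $n$ sites, an
empirical distribution $\hat D$ built from occurrence records, and an
$m \times n$ feature matrix $\Phi$, the regularized MaxEnt estimate is

$$\min_{p \in \Delta_n} D_{KL}(p \| p_{\mathrm{prior}})
 + t\,H^{*}\!\big((E_{\hat D}[\Phi] - E_p[\Phi])/t\big),$$

whose dual is penalized maximum likelihood over Gibbs distributions
$p_w(j) \propto p_{\mathrm{prior}}(j) e^{\langle w, \Phi(j)\rangle}$.
Three penalties are supported: elastic net, non-overlapping group lasso,
and the sup-norm.

The solvers are nonlinear primal–dual hybrid gradient (NPDHG) schemes whose
primal proximal step is a Kullback–Leibler divergence, so every primal
update is a closed-form Gibbs distribution and the stepsizes depend only on
the max-column norm $\|A\|_{op} = \max_j \|\Phi(j)\|_2$ — computable in one
$O(mn)$ pass, and often an order of magnitude smaller than the largest
singular value $\|A\|_2$ that classical first-order methods need. A
sublinear-rate scheme covers all penalties; a linear-rate variant covers the
smooth-potential elastic net. An accelerated forward–backward splitting
(FBS) baseline on the dual is included for cross-validation and
benchmarking, along with the full warm-started 141-point
regularization-path protocol and presence-only data preparation
(region-weighted empirical distributions, prior imputation, min–max feature
scaling, synthetic data generation).

See `vignettes/pdmaxent-methods.Rmd` for the model, stepsize formulas,
stopping rules, and design decisions.

## Worked example

Generate a synthetic presence-only data set with 3 planted features among
20, fit the elastic-net regularization path, and check what was selected:

```r
library(pdmaxent)

sim <- generate_synthetic(m = 20, n = 500, sparsity = 3, l = 50000, seed = 42)
sim$problem
#> <maxent_problem> 20 features x 500 sites; ||A||_op = 3.297; 500 sites with empirical mass

reg <- elastic_net(0.95)
t_max(sim$problem, reg)        # path start: smallest t with solution (prior, 0)
#> [1] 0.1709972

path <- fit_path(sim$problem, reg)
path
#> <maxent_path: elastic_net> 141 points from t0 = 0.171; 141 converged; final nonzeros 3/20

prof <- nonzero_profile(path)
tail(data.frame(t_ratio = prof$t_ratio, nonzero = prof$nonzero,
                cumulative = prof$cumulative_nonzero), 3)
#>     t_ratio nonzero cumulative
#> 139   0.060       3          3
#> 140   0.055       3          3
#> 141   0.050       3          3

which(sim$true_w != 0)                                        # planted support
#> [1]  4  5 20
sort(order(abs(path$coefficients[, 141]), decreasing = TRUE)[1:3])  # recovered
#> [1]  4  5 20
```

All 141 warm-started solves converge under the model's optimality-condition
stopping rule, and the three nonzero coefficients surviving at the end of
the path are exactly the planted ones. A single solve at one hyperparameter:

```r
fit <- npdhg_solve(sim$problem, reg, 0.5 * t_max(sim$problem, reg))
fit
#> <solve_result: npdhg_smooth> converged after 512 iterations; dual objective 0.082679721; residual 0.0812
```

## Command line

```sh
Rscript inst/cli/pdmaxent simulate --m 20 --n 500 --seed 42 --out data/
Rscript inst/cli/pdmaxent tmax --features data/features.csv --empirical data/empirical.csv --alpha 0.95
Rscript inst/cli/pdmaxent path --features data/features.csv --empirical data/empirical.csv \
    --model elastic_net --alpha 0.95 --out run/
```

`path` writes `path.csv` (t, t/t0, nonzero counts, residual, iterations,
convergence flag, dual objective), `coefficients.csv`, and the resolved
`run-config.dcf`. Exit codes: 0 success, 1 validation error, 2
non-convergence.

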