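# plsbd — density-ratio change-point detection with a Pearson-like scaled Bregman divergence

`plsbd` detects change points in multivariate time series — offline,
non-parametrically, and without estimating any density. It is aimed at
time-course data where the generating distribution switches between
regimes: sensor streams, simulated benchmarks, and high-dimensional omics
series (thousands of genes, tens of time points) where only a sparse
subset of covariates shifts.

## The statistic

For a post-change density $p$, a pre-change density $q$ and the mixture
measure $m_\alpha = \alpha p + (1-\alpha) q$, the package scores
dissimilarity with the Pearson-like scaled Bregman divergence

$$
D_{PL}(p \| q; m_\alpha) = \frac{1}{2} \int m_\alpha(y)
\left(\frac{p(y)}{m_\alpha(y)} - \frac{q(y)}{m_\alpha(y)}\right)^2 dy
= \frac{1}{2}\mathbb{E}_p[r_\alpha]
- \frac{2-\alpha}{2(1-\alpha)}\mathbb{E}_q[r_\alpha]
+ \frac{1}{2(1-\alpha)},
$$

where $r_\alpha = p/m_\alpha \le 1/\alpha$ is the relative density ratio.
It contrasts the two segment distributions directly (not one of them
against a mixture, as the RuLSIF score does), stays bounded for
$\alpha > 0$ (unlike the Pearson divergence behind uLSIF), and is
symmetric at $\alpha = 1/2$. The ratio is estimated by Gaussian-kernel
ridge regression, $\hat\theta = (\hat H + \lambda I)^{-1}\hat h$, with
$(\sigma, \lambda)$ selected by 5-fold cross-validation; a sliding window
turns the fitted divergence into a score per time point, and candidates
are the maximal runs of scores above $\eta \cdot \max(\text{score})$.
For high-dimensional matrices, a random covariate-subsampling ensemble
(`plsbd_sample()`) aggregates candidate frequencies across many small
random subsets, which rescues changes that a full-matrix run dilutes.
uLSIF and RuLSIF scoring are included as baselines
(`method = "ulsif"` / `"rulsif"`).

## Worked example

```r
library(plsbd)

sim <- simulate_gauss_segments(seed = 1)   # N(0,1) -> N(10,1) -> N(-5,1) -> N(10,1)
cp  <- plsbd(sim$x, method = "plsbd", alpha = 0.5,
             window = 5, step = 50, eta = 0.9, seed = 1)
cp$candidates
#>   peak run_start run_end    score
#> 1  101        95     103 1.925443
#> 2  201       194     204 1.928030
#> 3  301       294     303 1.933060

match_changepoints(cp$candidates$peak, sim$change_points, tol = 10)
#> Matched 3 of 3 true change points (3 detected, tol = 10)
#>  truth detected distance
#>    101      101        0
#>    201      201        0
#>    301      301        0
```

The three candidate peaks land exactly on the times at which the new
regimes begin (101, 201, 301); each `score` is the fitted divergence at
the peak, here near its saturation value 2 for well-separated unit-variance
Gaussians at $\alpha = 0.5$. For a 200-covariate matrix in which only 10
covariates shift, the subsampling ensemble localizes the changes as
high-frequency intervals:

```r
hd <- simulate_highdim(seed = 1)           # changes at t = 26, 51, 76
sr <- plsbd_sample(hd$x, n_samples = 200, subset_size = 20,
                   window = 8, step = 5, seed = 1)
head(sr$intervals, 3)                      # top intervals cover 26, 51, 76
```

A thin command-line interface (`exec/plsbd`) exposes the same pipeline as
`simulate`, `detect`, `sample-detect` and `evaluate` subcommands over
CSV/TSV input, with YAML config mirroring of all flags.

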