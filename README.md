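# autologit

Binary segmentation of multi-band images with **autologistic regression**
— logistic regression extended with an Ising-type spatial interaction on
the 4-neighbour pixel lattice. The package is aimed at exposure-mapping
style problems (e.g. flagging hazard vs non-hazard pixels in satellite
imagery) where labelled training images exist and scenes are large enough
that fully spatial likelihood methods are impractical.

## The model

With coded pixel classes $z_i \in \{L,H\}$, design matrix $X$ and lattice
adjacency $A$:

$$\Pr(Z=z) \propto \exp\Big\{(X\beta)^\top z + \tfrac{\lambda}{2} z^\top A z\Big\},
\qquad
\operatorname{logit}\,\pi_i = (H-L)\Big(x_i^\top \beta + \lambda \sum_{j\sim i} z_j\Big).$$

$\lambda = 0$ is ordinary logistic regression; $\lambda > 0$ adds
model-based spatial smoothing. Both the $\{0,1\}$ and $\{-1,1\}$ codings
and the centred variant are implemented, with exact enumeration oracles
on small lattices and a coding converter that preserves the joint
distribution.

What the package provides:

* **Two-stage plug-in estimation** — fit $\beta$ by balanced-sample
  logistic regression under independence, then choose $\lambda$ on
  validation images by predictive performance. Fast enough for scores of
  megapixel images; only viable with the $\{-1,1\}$ coding (the package
  reproduces this contrast).
* **Maximum pseudolikelihood** (joint $(\beta,\lambda)$, analytic
  gradient) for comparison.
* **Gibbs-sampling prediction** of per-pixel marginal probabilities
  (chequerboard sweeps, Rao-Blackwellised averaging; Rcpp kernel),
  cutoff classification and confusion metrics.
* **Feature machinery** — triangular-basis additive expansions of band
  terms ("j", "j:k" interactions) and fixed-size genetic-algorithm subset
  search.
* **A synthetic scene generator** — random-ellipse foregrounds with
  class-dependent GMRF textures through an antilogit — so the whole
  pipeline can be validated against known truth.

## Worked example

```r
library(autologit)

# 30 labelled 100x100 RGB scenes with known truth, split 10/10/10
scenes <- generate_scenes(100, n = 30,
                          split = c(train = 10, validation = 10, test = 10),
                          seed = 142)

fit <- run_two_stage(scenes,
                     n_sample    = 2e4,              # balanced pixel sample
                     lambda_grid = seq(0, 2, by = 0.1),
                     cfg         = gibbs_config(60, 180),
                     seed        = 7)
fit
#> <two-stage autologistic fit>
#> <autologistic model: standard, {-1,1} coding, lambda = 0.9, r = 4>
#> <lambda search (error): best lambda = 0.9 (criterion 0.18445)>
#> test: <confusion: overall 17.51%, high-class 16.70%, low-class 18.42%>
```

Reading: the balanced logistic stage-1 fit gives the per-band
coefficients (here 0.71, −1.22, −1.11, 1.16 for intercept, R, G, B on
the $\{-1,1\}$ scale — the foreground class is bluer, the background
redder); the search selected $\hat\lambda = 0.9$ — strong spatial
smoothing — which cuts the validation error from 31.7% at $\lambda = 0$
(independent pixels) to 18.4%; the held-out test images confirm 17.5%
overall error, roughly balanced across classes. For comparison,
`fit_mpl()` on the same training images estimates $(\beta, \lambda)$
jointly ($\hat\lambda = 1.05$) and predicts almost identically:

```r
mpl <- fit_mpl(scenes_split(scenes, "train"), design_builder(),
               init = list(beta = fit$stage1$beta, lambda = 0.5))
evaluate_model(mpl$model, scenes_split(scenes, "test"),
               design_builder(), cfg = gibbs_config(60, 180),
               seed = 21)$pooled
#> <confusion: overall 17.21%, high-class 14.42%, low-class 20.36%>
```

A command-line front end with `simulate`, `fit`, `predict`, `evaluate`,
`compare-sizes` and `variant-curves` subcommands is installed at
`system.file("cli.R", package = "autologit")`.

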