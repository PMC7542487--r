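# stylemkl

Binary classification for *style-grouped* data in R: a least-squares SVM
(LSSVM) trained over a learned convex combination of base kernels, with one
affine "style" transformation per sample group learned jointly with the
classifier and applied entirely through the kernel trick.

Many datasets arrive in groups that share a systematic distortion — EEG
recording sets, writers, acquisition sessions.  `stylemkl` models each
group $j$ with a feature-space map $A_j$ regularized toward the identity,

$$
\min_{w,\,b,\,\mu \in \Delta,\,\{A_j\}} \;
\tfrac12 \sum_i \mu_i \|w_i\|^2
+ \tfrac{\lambda}{2} \sum_{j,k} e_{jk}^2
+ \lambda \gamma \sum_j \|A_j^\top - I\|_F^2,
\qquad
y_j^k = w^\top A_j^\top \Phi(x_j^k) + b + e_j^k ,
$$

and solves it by alternating (a) a multi-kernel LSSVM fit — kernel weights
$\mu$ by a semi-infinite linear program solved with cutting planes, dual
variables by one Cholesky solve — with (b) a closed-form update of the
style maps, $A_j^\top = I + \frac{1}{2\lambda\gamma}\sum_{k \in j}
\alpha_j^k \bar w \Phi^\top(x_j^k)$.  The maps are never materialized: the
style-transformed Gram matrix is computed from base kernel values alone.
Three prediction rules cover the deployment cases: ignore style (rule 1),
apply a known group's map (rule 2), or extrapolate to an unseen style via
temporary labels and a refit (rule 3).

The package includes a synthetic stylized-data generator (so everything is
testable offline), an optional front-end for the five-set Bonn single-channel
EEG layout (ASCII loader + kernel-PCA features + the standard experiment
splits), and a command line.

## Worked example

```r
library(stylemkl)

# 4 style groups x 30 samples, strong per-group affine distortion
d  <- generate_styled_data(synth_config(style_strength = 2, seed = 7))
sp <- make_splits(d, train_fraction = 0.5, seed = 1007)

mk <- fit_mkl(gram_stack(sp$train$X), sp$train$y, lam = exp(-1))  # style-free
sr <- fit_sr(sp$train)                                            # style-aware
sr
#> <sr_model> n = 64, 10 kernels, 4 style group(s)
#>   lambda = 0.367879, gamma = 10, 3 outer iteration(s)
#>   objective trace: 4.47488 4.00062 4.09895

evaluate_model(sr, sp$test, rule = 2)                  # 0.9285714
mean(predict_mkl(mk, sp$test$X, sp$train$X) == sp$test$y)  # 0.9107143
```

The objective trace shows the alternation: iteration 1 *is* the plain
multi-kernel fit (4.475), learning the style maps lowers the regularized
objective (4.001), and the guard stops at the first non-improving iterate.
On the test set, normalizing each group with its learned map before
classifying (rule 2, 92.9%) beats the style-free multi-kernel baseline
(91.1%); the gap widens with the generator's `style_strength` and vanishes
at `style_strength = 0`.

Command-line equivalent (see `inst/cli/stylemkl`):

```sh
stylemkl generate --seed 7 --style-strength 2 --out data.csv
stylemkl fit --data data.csv --model m
stylemkl evaluate --model m --data data.csv --rule 2
```

## Bonn EEG front-end (optional)

With a local copy of the five-set Bonn EEG download (one integer amplitude
per line, one directory per set `A`–`E` or `Z/O/N/F/S`):

```r
ds <- kpca_features(load_bonn("path/to/bonn"), n_components = 70)
sp <- build_paper_splits(ds, "DS.2", seed = 1)
sr <- fit_sr(sp$train, lam = exp(3), gamma = exp(-5))
evaluate_model(sr, sp$test, rule = 2)
```

No test depends on this data being present.
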