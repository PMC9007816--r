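# lowmi — low-precision mutual information feature selection

`lowmi` measures how few bits the arithmetic inside mutual-information
(MI) feature selection actually needs. It targets the microarray /
gene-expression regime — tens to low hundreds of samples against
thousands of features — where MI filters such as MIM, mRMR and JMI are
the standard first step, and where deployment on low-power hardware
makes double-precision floating point a luxury.

## The method

The plug-in MI estimator for discretized features is

    I(X;Y) ≈ Σ_x Σ_y p̂(x,y) ln[ p̂(x,y) / (p̂(x) p̂(y)) ],   p̂ = c/C,

with counts c over a population C. `lowmi` replaces its arithmetic with
a fixed-point format of `bi` integer and `bf` fractional bits
(quantization interval q = 2^-bf, total depth b = bi + bf, even split by
default):

* **Saturating counters.** Counters are bounded by M = 2^(bi+bf) − 1;
  when the population count would pass M, every counter is halved
  (floor) and counting continues.
* **Quantized logarithms.** Log-ratios come from a lookup table
  L(i,j) = [ln(i/j)/q]_R · q — rounded to the nearest multiple of q and
  clamped to ±(2^bi − q) — so every unclamped entry is within q/2 of the
  exact value, and the low-precision estimate is within 3q/2 of the
  plug-in value absent saturation.

The estimator is embedded in three greedy filters, each evaluated at any
depth (4, 8, 16, 32 bits, or the full-precision baseline):

| method | criterion at each step |
|--------|------------------------|
| MIM    | I(X_f; Y) |
| mRMR   | I(X_f; Y) − (1/\|S\|) Σ_{s∈S} I(X_f; X_s) |
| JMI    | Σ_{s∈S} I((X_f, X_s); Y) |

Evaluation machinery compares rankings across depths by top-k true
positive rate (the overlap of top-k sets with the full-precision
reference) and measures downstream impact with repeated stratified
cross-validation that performs selection inside the loop. A
deterministic generator of microarray-like data (planted relevant,
redundant and complementary features in Gaussian noise) makes the whole
experiment self-contained.

## Worked example

```r
library(lowmi)

ds  <- synth_microarray(synth_config(n = 100, m = 500, n_relevant = 10,
                                     n_redundant = 5, effect_size = 1.5,
                                     seed = 1))
fit <- lowmi_rank(ds$x, ds$y, method = "mrmr", k = 10, bits = 16)
print(fit)
#> Feature ranking (MRMR, 16-bit, k = 10)
#>  rank feature    score
#>     1    g341  0.34762
#>     2     g11 -0.13926
#>     3    g152 -0.11361
#>     4    g202 -0.15759
#>     5    g286 -0.18213
#>     6    g113 -0.18936
#>     7    g331 -0.18148
#>     8    g209 -0.20103
#>     9    g342 -0.20938
#>    10     g34 -0.22095

full <- lowmi_rank(ds$x, ds$y, method = "mrmr", k = 10, bits = "full")
tpr_top_k(full, fit, 10)
#> [1] 1

run_cv(ds$x, ds$y, method = "mrmr", bits = 16, k = 10, seed = 3)
#> 3 x 5-fold CV: MRMR at 16 bits, top-10 features, knn3 classifier
#>   mean accuracy: 97.00% (fold sd 3.68)
```

The `score` column holds the greedy criterion value at the step each
feature was selected (for mRMR, relevance minus mean redundancy — later
steps can be negative). A TPR of 1 means the 16-bit run selected exactly
the same top-10 set as the full-precision baseline; the cross-validated
accuracy shows what that ranking is worth to a downstream classifier.

The same pipeline is available from a shell via the bundled tool
(`inst/scripts/lowmi`): subcommands `synth`, `rank`, `compare` and `cv`,
each writing a CSV result plus a provenance JSON. CSV (class in the last
column) and ARFF inputs are supported.

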