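# somnet

Decision-support analytics for regional health systems described by
multi-dataset key performance indicators (KPIs). `somnet` is aimed at
health-systems researchers and planners who hold small-area indicator
tables — service availability, placement capacity, workforce capacity and
resource utilisation for a set of catchment areas — and want to explore
system outliers, global and local care patterns, and input–output KPI
relationships with a reproducible, scriptable tool.

## The method

For each indicator dataset `somnet` trains a **self-organising map
(SOM)**: a hexagonal grid of neurons, each carrying a codebook vector
`m_j` on the min–max-normalized indicator scale. Training is batch
Kohonen learning: each epoch assigns every area `x_i` to its best
matching unit (BMU) `b(i) = argmin_j ||x_i − m_j||` under a *masked*
Euclidean distance (missing entries are excluded from distance and
update, never imputed), then recomputes

    m_j = Σ_i h(j, b(i)) · x_i / Σ_i h(j, b(i)),

with a Gaussian neighbourhood `h(j, k) = exp(−d_grid(j, k)² / 2σ_t²)`
whose radius `σ_t` shrinks linearly across epochs. Map quality is
reported as quantization error (mean distance to BMU) and topographic
error (fraction of areas whose first and second BMUs are not grid
neighbours). Neurons holding two or more areas are *unit clusters* of
closely similar areas.

The input maps are networked to the output map through **association
weights** learned over the shared areas:

    M[j, k] = Σ_areas h_in(j, BMU_in(a)) · h_out(k, BMU_out(a)),

row-normalized, so `M[j, ·]` is the distribution of output-map neurons
co-activated with input neuron `j`. A conditional query turns constraint
values into a Gaussian **activation** over the source map
(`exp(−(m_j[v] − x)²/2σ²)` per constraint, multiplied across
constraints), pushes it through `M` (input-driven) or `Mᵀ`
(output-driven), selects the most-weighted region (quantile `q` of the
propagated weights) and reports the weight-averaged, denormalized
codebook values of the requested indicators.

Every reported value also receives a **qualitative category** on a
five-level, 20%-interval scale (`low` … `high`) over the indicator's
observed `[min, max]` range, with left-closed intervals.

Supporting stages: robust per-indicator outlier flagging
(`(x − median)/(1.4826·MAD)`), an explicit drop/winsorize policy
(winsorization to the 97.5th percentile of the other areas), a synthetic
three-region system generator with planted ground truth, deterministic
SVG renderings (component planes, label maps, star glyphs, weight
fields), and a YAML-configured end-to-end pipeline.

## Worked example

Generate the bundled-study-like synthetic system (106 areas in three
regions, four planted outlier areas), process outliers with the preset
policy, train the four maps, network them, and ask what utilisation
pattern goes with three acute-care psychiatrists per 100,000 inhabitants:

```r
library(somnet)

sys  <- generate_system(paper_like_config(seed = 1))
flag_outliers(sys$tables$USE, threshold = 5)
#> Outlier report (USE, |robust z| >= 5): 3 flags
#>  label code direction    score
#>    B19   U4      high 30.56943
#>    B19   U5      high 29.51692
#>    B19   U6      high 29.28609

tabs <- apply_policy(sys$tables, paper_preset_policy())   # 106 -> 102 areas
soms <- lapply(tabs, function(t)
  train_som(normalize_mms(t), som_params(epochs = 30, seed = 1)))
soms$USE
#> Trained USE-SOM: 13x4 hexagonal grid, 102 areas, QE 0.1301, TE 0.1078

nets <- lapply(soms[c("AVA", "PLA", "WOF")], build_association,
               output_som = soms$USE, radius = 1)
res <- run_query(nets, soms, conditional_query("input-driven", c(W1 = 3.0)))
res$estimates
#>   code     value   category region_size dataset
#> 1   U1  1.650293 low-medium          11     USE
#> 2   U2 17.526066 low-medium          11     USE
#> 3   U3  6.712351 low-medium          11     USE
#> 4   U4 14.362910 low-medium          11     USE
#> 5   U5  3.043179 low-medium          11     USE
#> 6   U6 40.913417 low-medium          11     USE
```

The estimates are in each indicator's original units (e.g. `U1`
discharges per 1,000 inhabitants, `U2` length of stay in days), averaged
over the 11 most-weighted output-map neurons, and categorized on each
indicator's observed range — here, conditioning the workforce indicator
`W1` at 3.0 predicts low-medium utilisation throughout. The reverse
question (which `W1` goes with given utilisation targets) is an
output-driven query:

```r
run_query(nets, soms, conditional_query("output-driven",
          c(U1 = 2.0, U2 = 18.0, U3 = 9.0), report = "W1"))$estimates
#>     code    value category region_size dataset
#> WOF   W1 5.152581   medium          11     WOF
```

The whole loop (simulate/load → validate → train → flag outliers → apply
policy → retrain → network → queries → figures → report) runs from one
YAML config via `run_full_analysis()`, or from the thin CLI at
`inst/cli/somnet.R`. Categorization is available directly:

```r
categorize(3.00, make_scale(0.16, 5.23))   # "medium"
categorize(1.94, make_scale(0.16, 5.23))   # "low-medium"
```

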