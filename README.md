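# signoise

Signal and noise correlations in task fMRI networks: estimation, network
analysis, and consequences for task information coding.

## The problem

During tasks, the correlation structure of brain activity reconfigures.
Whether a change in *noise correlation* (NC — the block-to-block
co-fluctuation of two regions within a task, statistically the same thing as
task-state functional connectivity) helps or hurts the information a region
set carries cannot be read off the NC alone: it depends on how the change is
oriented relative to the pair's *signal correlation* (SC — the similarity of
their mean task tuning). `signoise` implements that full analysis for
parcellated block-design fMRI, and ships a synthetic-data generator with
known population SC/NC so every stage is testable without any imaging data.

For regions $i, j$ with task-mean activations $\bar\beta_i(t)$ over tasks
$t$ and block-wise activations $\beta_{i}(t, b)$:

- $\mathrm{SC}_{ij} = \mathrm{corr}_t\left(\bar\beta_i(t), \bar\beta_j(t)\right)$
- $\mathrm{NC}_{ij}(t) = \mathrm{corr}_b\left(\beta_i(t,b), \beta_j(t,b)\right)$;
  tNC = mean over tasks, rNC = the same estimator on interleaved rest blocks
- $\Delta\mathrm{NC} = \mathrm{tNC} - \mathrm{rNC}$
- signal-noise differential $= \mathrm{SC} \odot \Delta\mathrm{NC}$
  (elementwise). Positive = *aligned* (noise moved into the signal
  direction, putatively information limiting); negative = *anti-aligned*
  (putatively information enhancing).

The pipeline covers: beta-series GLM with nuisance regression and FIR
residualization; SC/tNC/rNC/deltaNC and group averaging; intersubject SC;
signed modularity, segregation, and thresholded-PCA gradients of SC/NC
matrices; clique identification on thresholded differential graphs;
leave-one-block-out 26-way decoding with a block-shuffle control; and a
closed-form linear statistical network model
($x = x_\mathrm{shared} + x_\mathrm{private} + 0.75\,s_\mathrm{drive} + 0.75\,g$)
predicting how state-specific correlations behave under pure linear
superposition.

## Worked example

```r
library(signoise)

# A small synthetic study: 8 subjects, 2 networks x 6 regions, each network
# carrying a bipolar tuning axis; task noise shifted against the SC sign.
st   <- signal_axis_scenario(n_subjects = 8, n_systems = 2,
                             regions_per_module = 3, n_tasks = 8,
                             blocks_per_task = 8, rest_blocks = 8, seed = 7)
pair <- make_alignment_scenarios(st$spec, delta_magnitude = 0.2, sc_tol = 0.4)
ds   <- generate_dataset(pair$anti_aligned)

ncs  <- lapply(ds$betas, compute_nc)
sc   <- group_average(lapply(ds$betas, compute_sc))
dnc  <- compute_delta_nc(group_average(lapply(ncs, `[[`, "tnc")),
                         group_average(lapply(ncs, `[[`, "rnc")))
diffm <- signal_noise_differential(sc, dnc)
diffm
#> differential_matrix [group]: 12 regions; 39.4% aligned, 60.6% anti-aligned

alignment_summary(diffm, st$partition)$overall
#>      aligned anti_aligned         null
#>     39.39394     60.60606      0.00000

signed_modularity(sc, st$partition)$q_star
#> [1] 0.8261556

cl <- strongest_clique(diffm, k = 3, sign = "anti_aligned",
                       retain_fraction = 0.4)
cl$cliques[[1]]
#> [1] "R004" "R005" "R006"
cl$strength
#> [1] -0.2935013

decode_multitask(ds$betas[[1]], cl$cliques[[1]], seed = 1)
#> decoding_result [sub-01, unshuffled]: accuracy 0.344 (8-way, chance 0.125, 8 folds)
```

The majority of state-dependent NC changes in this dataset are anti-aligned
with the SC (by construction: the generating task-noise correlations are
shifted opposite to the SC sign on every nonzero-SC pair), the group SC is
strongly modular with respect to the generating module partition, and the
strongest anti-aligned 3-clique decodes the 8 tasks well above the 12.5%
chance level.

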