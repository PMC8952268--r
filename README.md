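# hrtbioind

Bioindicator discovery and quantitative performance prediction for
anaerobic chain-elongation bioreactors, from 16S rRNA amplicon data.

## The problem

Chain-elongation (CE) reactors ferment lactate and xylan into
medium-chain carboxylates — n-butyrate (C4), n-caproate (C6) and
n-caprylate (C8). The hydraulic retention time (HRT, working volume over
daily feed volume) is the main operating lever: shortening it from 8 to
2 days restructures the reactor microbiome and raises C6/C8
productivities. `hrtbioind` asks two questions of the amplicon sequence
variant (ASV) table of such a system:

1. **Which taxa mark an HRT regime?** A random-forest classifier of HRT
   phase (`HRT8` vs `HRT2`) with recursive Gini-importance elimination
   selects, per reactor, the 15 ASVs that best discriminate the regimes;
   ASVs selected in *both* reactors are the shared HRT bioindicators.
   Generalization is always scored on the reactor the model never saw.
2. **Can those taxa predict performance quantitatively?** Regression
   forests predict concentrations, productivities and yields across
   reactors from the bioindicators; performance is reported as the
   out-of-bag explained variance (gate: > 80% in both train
   orientations), the relative root mean square error
   (RRMSE = 100·RMSE/mean, cutoff < 10%) and its replicate-subsampling
   distribution. Per-parameter *non-HRT bioindicators* (top-15 regression
   importances over all ASVs) capture community assembly over time, and
   the HRT bioindicators *not* among them are the regime markers
   "irrespective of time".

Supporting statistics — rarefaction, observed ASVs and Shannon diversity,
Bray–Curtis/NMDS/PERMANOVA beta diversity, SMOTE class balancing,
linear/SVM/random-forest benchmarking, and a Spearman co-occurrence
network (|rho| > 0.7, BH-adjusted p < 0.05, Gephi-ready GEXF/GraphML
export) — are included, as is a synthetic two-reactor experiment
generator with planted ground truth so the whole pipeline is testable
end to end. The methods vignette
(`vignettes/bioindicator-workflow.Rmd`) documents the models, defaults
and limitations.

## Worked example

```r
library(hrtbioind)

sim <- simulate_experiment(simulation_config(seed = 1))
wf  <- run_two_step_workflow(sim$abundance, sim$metadata,
                             parameters = c("prod_C6", "prod_C8"),
                             spec = rf_spec(seed = 1),
                             ground_truth = sim$ground_truth)
print(wf)
#> <workflow_report>
#>   held-out accuracy: A->B 0.941, B->A 1.000
#>   shared HRT bioindicators: 14
#>   time-independent: 2 (ASV006, ASV015)
#>   parameters passing the 80% variance gate: prod_C6, prod_C8
#>   prod_C6 A->B: mean RRMSE 10.67% (HRT set), 8.82% (non-HRT)
#>   prod_C6 B->A: mean RRMSE 17.67% (HRT set), 15.55% (non-HRT)
#>   prod_C8 A->B: mean RRMSE 12.42% (HRT set), 9.70% (non-HRT)
#>   prod_C8 B->A: mean RRMSE 18.41% (HRT set), 12.40% (non-HRT)
#>   ground truth: 10/11 responders in shared set, 2/4 time-independent recovered
```

Reading this: the full-feature classifier trained on one simulated
reactor labels the other reactor's HRT phase with 94–100% accuracy; 14
ASVs survive the top-15 ∩ top-15 intersection, 10 of the 11 planted
regime responders among them; both C6 and C8 productivity clear the 80%
explained-variance gate, and the 100-replicate subsampled predictions on
the held-out reactor reach ~9–18% RRMSE depending on the feature set and
orientation (the planted lineage-divergent markers inflate the HRT-set
numbers — see the vignette for why that trade-off is intrinsic).

```r
head(as.data.frame(wf$shared_set), 3)
#>   asv_id rank importance      share
#> 1 ASV006    1   1.322956 0.08271260
#> 2 ASV023    2   1.293618 0.08089044
#> 3 ASV004    3   1.278706 0.07994823
```

The same stages run from a single configuration via `run_pipeline()`
(YAML-configurable; see `inst/scripts/run_pipeline.R` for a shell entry
point), which writes all tables, a JSON report and an md5 manifest.

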