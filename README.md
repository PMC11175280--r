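# needleplan

Automatic planning of straight percutaneous ablation-needle trajectories for
small liver tumors, from labeled abdominal CT volumes.

Thermal ablation destroys a tumor by heating it through a needle inserted
through the skin. For a rigid needle the plan is a skin entry point: the
trajectory is the segment from that point to the needle target (the tumor
centroid). `needleplan` enumerates one candidate path per skin-surface voxel,
rejects paths that violate the clinical **hard constraints**

* no contact with a risk structure (vessels, bone, lung),
* path length strictly below the needle length `L`,
* insertion angle at the liver capsule at least `angle_min`
  (90° = perpendicular),

and ranks the surviving *feasible insertion region* on three **soft
constraints** — clearance from risk structures `S1` (mm), path length `S2`
(mm), capsule angle `S3` (degrees) — in two independent ways:

1. **Weighted sum.** Each soft value is min–max normalized over the feasible
   set onto 0–10 (direction-aware, 10 best) and scalarized as

       Pscore = Ps1·α1 + Ps2·α2 + Ps3·α3,   default (α1, α2, α3) = (0.3, 0.4, 0.3)

   so `Pscore` ranges from 0 to 10, with 10 marking a path that is
   simultaneously optimal in all three criteria. The top 3 paths are
   recommended.
2. **Pareto screening** (weight-free). The objectives are combined in pairs,
   the two-objective Pareto front is computed in each pairwise coordinate
   system, and the global front is the intersection of the per-pair fronts.
   Interactive screening lists, for a clinician-chosen entry point, every
   feasible path that dominates it in a chosen pair.

Inputs are integer label maps (NIfTI, MetaImage or NRRD) plus a role map
assigning semantic roles (skin, liver, tumor, vessel, bone, lung) to label
values. A synthetic abdominal phantom generator with analytic ground truth
makes the whole pipeline testable without any external data. Results are
persisted in a single-file JSON record store and exportable as JSON/CSV.

See `vignettes/path-planning-methods.Rmd` for the model, numerical choices
and limitations.

## Worked example

```r
library(needleplan)

# a 64^3 labeled phantom at 2.5 mm spacing: skin shell, liver, 10 mm tumor,
# rib-like bone slab, intrahepatic vessel
ph  <- generate_phantom(phantom_config())
cfg <- planning_config(needle_length = 150, angle_min = 20,
                       weights = c(0.3, 0.4, 0.3), skin_stride = 9)

res <- run_plan(ph$volume, cfg)
res$feasible
#> <feasible_set> 821/978 candidates feasible
#> rejections: collision=157, length=0, no_crossing=0, angle=0
res$ranked
#> <ranked_plan> 821 feasible paths, top 3 recommended
#>   entry_x entry_y entry_z    S1    S2    S3 Ps1   Ps2   Ps3 Pscore
#> 1   122.5      45   117.5 11.84 48.11 87.17  10 9.645 9.504  9.709
#> 2   112.5      35   115.0 11.84 49.63 87.77  10 9.308 9.742  9.646
#> 3   120.0      50   125.0 11.84 48.92 87.22  10 9.467 9.525  9.644
```

157 of 978 candidate entries are discarded because their path would cross the
bone slab or the vessel. The best path enters at (122.5, 45, 117.5) mm, stays
11.8 mm clear of the nearest risk structure, is 48.1 mm long (well under the
150 mm needle) and meets the liver capsule at 87° — nearly perpendicular. Its
score of 9.71/10 is not a perfect 10 because slightly shorter and slightly
steeper paths exist separately. Clearance ties at 11.84 mm across many
entries: every path ends at the same target, so the closest approach to the
vessel is often at the target itself.

```r
res$pareto
#> <pareto_result> per-pair fronts: S1-S2=2, S1-S3=1, S2-S3=10
#> global intersection empty; weighted-sum fallback reported
```

Here no single path is on all pairwise fronts, so the screen reports the
per-pair fronts and falls back to the weighted ranking (flagged as such).

Evaluating a clinician's own entry point, on the same 0–10 scale:

```r
cand <- evaluate_user_path(c(40, 40, 120), ph$volume, cfg)
cand <- score_user_path(cand, res$feasible, cfg)
cand[, c("S1", "S2", "S3", "Pscore")]
#>    S1    S2    S3 Pscore
#> 1 5.8 73.15 73.29   4.11
nrow(dominators_of(cand, res$feasible, ph$volume, cfg))
#> [1] 439
```

This entry is feasible but mediocre (score 4.11): 439 planned paths are both
shorter and at least as clear of risk structures.

## Command line

```sh
Rscript inst/cli/needleplan.R phantom --out ph/ --seed 1
Rscript inst/cli/needleplan.R plan --volume ph/phantom.nrrd --roles ph/roles.json \
    --needle-length 150 --angle-min 20 --weights 0.3,0.4,0.3 --stride 9 --out run/
Rscript inst/cli/needleplan.R screen --volume ph/phantom.nrrd --roles ph/roles.json \
    --entry 40,40,120 --pair length:clearance --stride 9
Rscript inst/cli/needleplan.R report --store run/records.json --id 1 \
    --out report.csv --format csv
```

`plan` writes `paths.csv` (every candidate with soft values, feasibility and
rejection reason), `recommended.csv` (top-k paths), `report.json` and a
record in the store. Exit codes: 0 success, 1 usage error, 2 I/O/format
error, 3 no feasible path. A role-map example ships in
`inst/extdata/roles_example.json`.

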