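# rgtpipe

Analysis pipeline for **rodent gambling task (rGT)** experiments that
combine risk-based choice behavior, in vivo extracellular recordings
from orbitofrontal cortex (OFC), and qPCR quantification of dopamine
markers. It is written for experimenters who have trial tables, spike
timestamps, event markers and Ct tables (plain CSV) and want the full
chain — behavioral preference metrics, event-locked firing analysis,
response-profile clustering, relative expression — as tested,
reproducible code, plus a seeded synthetic-data generator that stands
in for animal data in every test.

## The task and the analysis core

In the rGT a rat chooses, on each of 90 trials, between a **low-risk**
lever (1 pellet, p = 0.9) and a **high-risk** lever (3 pellets,
p = 0.3) with balanced expected value; trials without a press within
15 s are omissions, and completed trials fall into four response
classes (LR, LNo, HR, HNo: low/high risk × rewarded/not).

The pipeline computes:

* **Choice preference index** per 10-trial block:
  `CPI = (n_low − n_high) / (n_low + n_high)` over completed presses,
  in [−1, 1]; +1 = risk-averse, −1 = risk-prone. Curves are smoothed
  with a 3-point shrinking-window moving mean; omission rate, latency
  summaries and trial-by-trial response maps complete the behavioral
  layer.
* **Peri-event time histograms**: spike counts in 50-ms bins from 5 s
  before to 10 s after each lever press, averaged over events,
  Gaussian-smoothed (3-bin kernel), and Z-scored against the 5-s
  pre-press baseline: `Z = (x − m)/SD`.
* **Response clustering**: each unit's feature vector is its activity
  ratio (mean rate 5 s post-press / 5 s pre-press) per response
  class; units firing below 0.5 Hz are excluded; average-linkage
  agglomeration on Euclidean distances, with the partition chosen at
  the largest gap between consecutive merge distances below a linkage
  threshold of 3. Per-cluster mean Z quantifies response magnitude,
  and a **flexibility score** counts the classes a cluster encodes
  (|mean Z| ≥ 1.96).
* **Delta-Ct expression**: `2^−(Ct_target − Ct_GAPDH)` from replicate
  Ct tables, with Mann–Whitney group comparisons.

## Worked example

Simulate a session whose agent prefers the low-risk lever
(p = 0.9) and switches to risk-prone choice (p = 0.3) at trial 41 —
the behavioral signature of inflammatory pain — with two planted unit
populations: one excited after low-risk rewarded presses, one after
high-risk rewarded presses.

```r
library(rgtpipe)

agent <- agent_params(p_low_choice = 0.9, p_omit = 0.05,
                      switch_trial = 41, p_low_after = 0.3)
gains <- rbind(lr_responsive = c(LR = 3, LNo = 1, HR = 1, HNo = 1),
               hr_responsive = c(LR = 1, LNo = 1, HR = 3, HNo = 1))
cfg <- run_config(sim = sim_config(agent = agent,
                                   units = planted_units(gains, n_per_cluster = 6),
                                   seed = 42))
rep <- run_pipeline(cfg)

head(rep$behavior$preference_curve[, c("block", "cpi", "smoothed")], 7)
#>   block    cpi smoothed
#> 1     1  0.600   0.6000
#> 2     2  0.600   0.7333
#> 3     3  1.000   0.7833
#> 4     4  0.750   0.3241
#> 5     5 -0.778   0.0278
#> 6     6  0.111  -0.3556
#> 7     7 -0.400  -0.1439
rep$behavior$switch_block
#> [1] 6
```

The CPI sits near +0.7 (risk-averse) through block 4 and collapses
after the planted switch; the smoothed curve first turns negative at
block 6, one block after the switch block — within the localization
the method promises.

```r
table(rep$clustering$labels)
#> 1 2
#> 6 6
round(rep$clustering$cluster_mean_z, 2)
#>             LR   LNo   HR  HNo
#> cluster1 13.94 -0.03 0.06 0.06
#> cluster2 -0.02 -0.09 8.19 0.09
rep$clustering$flexibility
#> cluster1 cluster2
#>        1        1
```

The dendrogram cut recovers exactly the two planted populations; each
cluster shows a large mean Z only in its planted class (LR-rewarded
vs HR-rewarded presses) and correspondingly a flexibility score of 1
— it encodes a single response class.

A thin command-line wrapper is included at
`inst/scripts/rgt_pipeline.R`
(`Rscript rgt_pipeline.R --config cfg.yaml --seed 1 --out DIR`).

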