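# megnet

Resting-state MEG functional networks and cognition: phase lag index
(PLI) connectivity over cortical atlas regions, resting-state-network
(RSN) averaging, minimum spanning tree (MST) topology, cognitive z-score
composites against matched-control norms, and the nonparametric
statistics that link them — plus a coupled-oscillator synthetic cohort
generator so the whole chain is testable without patient recordings.

It is written for researchers analysing source-space MEG in clinical
cohorts (brain-tumour, epilepsy, MS, ...) who want a reproducible,
validated implementation of the classic PLI + MST analysis, and for
methodologists who need a ground-truthed simulator of band-limited,
phase-coupled ROI signals.

## The analysis in brief

For ROI phase series \(\phi_i(t)\) (analytic-signal phase of brick-wall
band-passed signals, per epoch), connectivity is the phase lag index

\[ \mathrm{PLI}_{ij} = \bigl| \langle \operatorname{sign}
   \sin(\phi_i(t) - \phi_j(t)) \rangle_t \bigr| \in [0, 1], \]

which ignores zero-lag coupling and is therefore robust to volume
conduction.  PLI matrices are averaged over epochs and summarized as the
mean within each RSN (DMN, left/right frontoparietal; AAL-based
defaults) and globally.  Per epoch, Kruskal's algorithm extracts the
maximum-PLI spanning tree, summarized by maximum degree, leaf fraction,
mean eccentricity, maximum betweenness centrality and tree hierarchy
\(T_H = L/(2\,m\,BC_{max})\), averaged over epochs.  Cognitive raw
scores become z-scores against matched-control means/SDs (higher =
better; impairment at \(z \le -1.5\)) and six domain composites.  Groups
are compared per domain with an exact Mann-Whitney U test (one-tailed by
default); brain-behaviour associations use Kendall's tau-b (two-tailed)
with tie-corrected inference — both implemented from first principles
with exact small-sample options.

## Worked example

```r
library(megnet)

cohort <- generateCohort(cohortConfig(seed = 1))   # 20 patients / 20 controls,
                                                   # 78 ROIs, 5 x 4096 @ 625 Hz
res <- runPipeline(cohort, allDomains = TRUE)

subset(res$tables$cognition_group, domain == "working_memory")
#>           domain patient_mean patient_sd  control_mean control_sd   U         p
#> 3 working_memory   -0.4375263   1.553955 -1.600282e-16          1 244 0.1211348

subset(res$tables$rsn_mst_correlations,
       domain == "working_memory" & measure %in% c("pli_DMN", "mst_degree"))
#>            domain  band    measure       tau           p  n
#> 17 working_memory theta    pli_DMN 0.3789474 0.019491843 20
#> 20 working_memory theta mst_degree 0.4325905 0.008998988 20
```

This synthetic cohort carries a built-in effect: each patient's
working-memory score is rank-linked to their true within-DMN coupling
strength (target Kendall tau 0.5) and shifted down by 0.55 control-SDs.
The run above recovers it: the working-memory z-scores correlate
positively with DMN-theta PLI (tau = 0.379, p = 0.019) and with the MST
maximum degree (tau = 0.433, p = 0.009), while the one-tailed group test
(p = 0.121 here) illustrates that a 0.55 SD deficit at n = 20/20 is
detected in only about half of cohorts — single-cohort significance is
a coin flip at this effect size.

Ground truth is retained for validation: `trueKappa(cohort)` returns
each subject's coupling strength, so recovery can be checked directly.

A thin command-line wrapper ships in `inst/exec/megnet`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","megnet",package="megnet"))')" \
    synth --out cohort/ --seed 1
Rscript ... run --data cohort/ --out results/ --all-domains
```

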