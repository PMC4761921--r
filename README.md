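# circaprime

Detection of circadian miRNA primary transcripts from nascent
transcription time series, with downstream analysis of miRNA
over-expression experiments.

## The problem

Mature miRNAs are extremely stable (average mammalian half-life on the
order of 119 h). A first-order kinetic argument shows that even a
strongly rhythmic primary transcript then yields a mature miRNA pool
whose 24-h oscillation is attenuated by the factor
k/&radic;(k&sup2;+&omega;&sup2;) (k = ln2/t<sub>1/2</sub>,
&omega; = 2&pi;/24 h) — about 0.02 at 119 h — which is why surveys of
circadian miRNAs at the mature level disagree. `circaprime` instead
detects circadian miRNAs at the **primary transcript** level from two
independent nascent-transcription time courses (GRO-seq / Nascent-seq
style RPKM matrices), for bioinformaticians analysing circadian
transcription and anyone who needs a tested, reusable implementation of
this pipeline.

The core statistic: each transcript is fit per dataset with a 24-h
cosinor regression `y = m + a cos(ωt) + b sin(ωt)` (amplitude
A = &radic;(a&sup2;+b&sup2;), peak phase φ = atan2(b,a)/ω, F-test vs.
intercept), and the two datasets are combined into the significance
score

    S = −log2(p1) − log2(p2)   (bits)

A transcript is called circadian when **S &gt; 9** and the circular
phase difference between datasets is **&lt; 4 h**; the false discovery
rate of that rule is estimated by permutation (shuffling each
transcript's values within each dataset and re-running the pipeline).

Downstream modules cover the follow-up over-expression experiment:
per-gene two-way ANOVA on a CT10/CT22 × treatment design with
Group I–IV classification, Fisher / proportion enrichment tests,
relative-amplitude (log2FC(CT10/CT22)) change classification, the
kinetic attenuation model, and construction of TF–miRNA feed-forward
motifs (BMAL1/CLOCK with CT10-peaking repressed targets, REV-ERBα/β
with CT22-peaking ones) from ChIP peak calls with dataset-support
rules. A synthetic-data generator with planted ground truth makes the
whole pipeline testable without any external data.

## Worked example

```r
library(circaprime)

# Two synthetic nascent datasets, 500 transcripts, 20% rhythmic
p   <- rhythm_sim_params(n_transcripts = 500, frac_rhythmic = 0.2, seed = 20)
sim <- simulate_nascent_pair(p)

res <- detect_rhythmic(sim$dataset_a, sim$dataset_b)
head(res[res$pass, c("transcript", "score", "phase_diff", "combined_phase")], 5)
#>        transcript score phase_diff combined_phase
#> 1 transcript_0001 17.25     0.3868          20.71
#> 2 transcript_0002 23.40     1.7821          18.43
#> 3 transcript_0003 13.20     0.7301           7.56
#> 4 transcript_0004 21.98     0.1373          12.07
#> 5 transcript_0005 21.51     1.1424          23.06
sum(res$pass)   # 98 of the 100 planted rhythmic transcripts detected

counts <- permute_and_score(sim$dataset_a, sim$dataset_b,
                            n_perm = 200, seed = 20)
estimate_fdr(res, counts)
#> Permutation FDR (200 perms, S > 9 & dphase < 4): 98 real passes,
#>   2.39 mean permuted, FDR = 2.4%

# Over-expression experiment: two-way ANOVA and group classification
oe  <- simulate_overexpression(oe_sim_params(n_genes = 1000, seed = 20))
grp <- classify_groups(two_way_anova(oe$expression))
table(grp$group)
#>    I   II  III   IV none
#>   55    6   49   11  879

kinetic_attenuation(half_life = 119, period = 24)
#> First-order attenuation: half-life 119 h, period 24 h ->
#>   amplitude x 0.02224, peak lag 5.92 h
```

`score` is S in bits, `phase_diff` the cross-dataset phase disagreement
in hours, `combined_phase` the −log2(p)-weighted circular mean peak
time (CT hours). The FDR is the mean permuted pass count over the real
pass count. Group I/III are CT10-/CT22-peaking genes repressed by the
over-expressed miRNA — its candidate circadian targets. The last line
quantifies why a 119-h half-life erases mature-level rhythms.

A thin command-line interface over the same functions is installed at
`system.file("cli", "circaprime.R", package = "circaprime")` with
subcommands `simulate`, `rhythm fit`, `rhythm fdr`, `oe anova` and
`amplitude kinetics`; identical arguments and seeds give byte-identical
outputs.

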