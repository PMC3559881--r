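# spliceSRE

Identification of splicing regulatory elements (SREs) and cooperative SRE
pairs from cassette-exon inclusion profiles measured across tissues.

## The problem and the model

Alternative splicing of a cassette exon is controlled by splicing factors
(SFs) that bind short cis-acting elements — here, hexamers in five regions
around the exon: the 5′ and 3′ ends of the upstream intron (UU, UD), the
exon body (EXON), and the 5′ and 3′ ends of the downstream intron (DU,
DD). Which hexamers act as enhancers or silencers, and which pairs act
cooperatively, is the inference target.

The package models spliceosome assembly as a single binding reaction with
Boltzmann weight `q0`; an SF bound to its SRE carries weight `x_f` and
couples to the spliceosome with cooperativity `c_f` (`c_f > 1` enhances,
`c_f < 1` represses), and two SFs may couple with factor `c_pair`. At
equilibrium the ratio of inclusion to skipping isoform expression
satisfies

    ln(N1/N2) = ln(a q0) + sum_f g_f + gamma_pair,
    g_f = ln((1 + c_f x_f) / (1 + x_f)),

which is *exactly linear* in binary presence indicators once unknown
per-exon constants are removed by centering the logit inclusion ratio
`y = logit(IR) - mean_t logit(IR_t)` across tissues:

    y_i = sum_k gamma_k s_ik + sum_kl gamma_kl s_ik s_il + eps_i .

With 4096 hexamers x 5 regions (20 480 main effects) plus pairwise
products, the model is fit by a four-stage high-dimensional framework:

1. **Screening** — per-column simple-regression t-tests; interaction
   screening of pairs among retained columns, with a hypergeometric
   co-occurrence test and a 1% presence filter;
2. **Lasso / adaptive Lasso** — coordinate descent with a cross-validated
   penalty; adaptive weights `1/|beta_lasso|`;
3. **Refitted cross-validation (RCV)** — split-half estimation of the
   residual variance, used to pick the sparsest model on the adaptive path
   whose OLS-refit variance still exceeds it (an overfitting guard);
4. **OLS refit + FDR** — two-sided t-tests and Benjamini–Hochberg
   selection; effect signs (enhancer/silencer) are called from SF
   expression across tissues via a monotonicity argument on `g_f`.

A forward simulator generates region sequences with planted motifs,
tissue-varying SF activity and noisy expression tables with known ground
truth, so the whole pipeline can be validated end to end.

## Worked example

```r
library(spliceSRE)

# a small synthetic study: 300 exons, 5 tissues, 3 planted SREs
pl <- data.frame(hexamer = c("UGCAUG", "CUCUCU", "GGGGCA"),
                 region  = c("DU", "UD", "EXON"),
                 cf = c(5, 1/5, 5), presenceProb = 0.25)
sc  <- sreScenario(nAses = 300, nTissues = 5, regionLen = 80,
                   planted = pl, targetR2 = 0.7, seed = 41)
sim <- simulateBiophysical(sc)

y  <- responses(computeResponse(sim$ir))[, sim$truth$targetTissue]
fm <- buildFeatureMatrix(sim$regions)
fit <- fitSreModel(y, fm, tissue = sim$truth$targetTissue,
                   cvFolds = 10, rcvRepeats = 3, seed = 7)
fit
#> SreFit [ tissue01 ]: n = 300 ASEs
#>   selected: 3 SREs, 0 pairs; 3 pass FDR
#>   R2 = 63.01 % ; sigma2(RCV) = 0.05456
modelResults(fit)[, c("key", "coefficient", "qValue")]
#> CUCUCU:UD    -0.402  3.2e-30
#> GGGGCA:EXON  +0.436  1.3e-33
#> UGCAUG:DU    +0.401  9.8e-26
```

All three planted motifs are recovered and nothing else passes the FDR
stage (`evaluateRecovery(fit, sim$truth)` reports precision and recall
1.0); the model explains ~63% of the response variance. The coefficient
signs are centered effects: the silencer CUCUCU comes out negative
because its SF happens to be elevated in the reported tissue, and
`classifyEffect()` is what turns signs plus SF expression into
enhancer/silencer calls.

For annotation-driven runs, `readGenePred()` + `selectCassetteExons()` +
`extractRegions()` take a genePred table and genome FASTA to the same
feature matrix, and `runSrePipeline()` orchestrates the whole file-based
analysis per tissue (see `inst/scripts/sre-tool.R` for a thin CLI).
`overlapEnrichment()` compares a discovered SRE list against external
motif collections by one-sided Fisher's exact test over the 4096-hexamer
universe.

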