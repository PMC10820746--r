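# pppmfa

Bayesian ¹³C metabolic flux analysis (MFA) of upper glucose metabolism:
glycolysis and the oxidative/non-oxidative pentose phosphate pathway (PPP),
estimated from parallel glucose tracer experiments ([1,2-¹³C],
[4,5,6-¹³C] and [U-¹³C]glucose, each diluted 1:1 with unlabeled glucose)
and GC–EI–MS fragment labeling measurements of intracellular sugar
phosphates and trioses.

The package is aimed at researchers quantifying PPP/glycolysis flux
partitioning — e.g. in immune cells, where oxidative-PPP up-regulation
drives the oxidative burst — from limited ex vivo material, and at method
developers comparing tracer and fragment panel designs.

## The model in brief

An eight-pool network (G6P, F6P, a lumped Ru5P+X5P pool, R5P, S7P, E4P,
DHAP, GAP) is constrained by one steady-state balance per pool, `S v = 0`.
With glucose uptake fixed at `Z1 = 100`, choosing the net glycolytic
cleavage `ΔQ2`, the net transaldolase flux `ΔTAL` and the active unlabeled
inputs as independent coordinates determines every other net flux linearly,
`v_dep = M v_indep`; only `Z3` (oxidative PPP), `Q4` (R5P drain) and `Q11`
(triose drain) are sign-constrained, so the permissible flux space is a
low-dimensional polytope (2 dimensions closed, +1 per input). Reversible
reactions additionally carry exchange magnitudes, with
`forward = max(net,0) + exchange` and `backward = max(-net,0) + exchange`.

Fragment carbon mass distributions (CMDs) are simulated by an elementary
metabolite unit (EMU) cascade over the network's carbon atom maps and
compared to measurements with a Dirichlet likelihood: a measured CMD with
precision parameter `NC` ("number of counts") is scored under concentration
`NC · CMD_predicted`, giving element variance `Mi(1−Mi)/(NC+1)` and the
negative abundance correlations that normalization induces. The posterior
over independent net fluxes (uniform on the polytope) and exchanges
(log-uniform) is sampled by an affine-invariant ensemble MCMC (an adaptive
random-walk backend is also provided), with split-R̂ and effective sample
size reported for every flux. A full-isotopomer fixed-point solver serves
as an independent reference implementation for the EMU cascade, and a
synthetic-data generator, a precision-score metric for design comparison,
and a flux-table PCA (varimax + jackknife) complete the workflow.

## Worked example

```r
library(pppmfa)

model <- ppp_network()                 # default: S7P input active
truth <- default_truth(model)          # documented synthetic truth
data  <- generate_measurements(truth, seed = 42)   # 3 tracers x 7 fragments

fit <- mfa_fit(data, model,
               config = mfa_config(chains = 2, warmup = 150, iter = 200,
                                   seed = 7))
s <- summary(fit)
s[s$flux %in% c("dQ2", "dTAL", "S_Input", "Z3", "Q4", "Q11"), ]
```

```
    flux   mean    sd ci68_low ci68_high rhat
     dQ2  86.59  5.14    81.25     91.99 1.02
    dTAL   5.03  1.14     3.89      6.21 1.03
 S_Input   2.62  0.38     2.26      3.02 1.00
      Z3  23.47  3.00    20.30     26.67 1.02
      Q4  13.63  6.49     6.87     20.29 1.02
     Q11 175.58 11.49   163.77    187.56 1.02
```

All fluxes are in units of glucose uptake = 100. The posterior recovers
the generating values (`ΔQ2 = 85`, `ΔTAL = 5`, `S_Input = 3`, `Z3 = 25`,
`Q4 = 16`, `Q11 = 172`) within one to two posterior standard deviations,
with split-R̂ ≈ 1 on every flux. Pairwise posterior regions expose the
structural couplings:

```r
pairwise_region(fit, "dGPI", "Z3")
#> 68% confidence region of (dGPI, Z3)
#>   mean (76.528, 23.472), correlation -1.0000 [degenerate: segment]
#>   half-axes 6.402 / 0.000, angle 135.0 deg
```

— the G6P balance forces `ΔGPI = Z1 − Z3`, so the pair collapses to a
segment.

Design comparison and PCA:

```r
sc   <- scenario_suite()                       # fragment/tracer designs
ref  <- apply_scenario(data, sc[["i_3PG"]])    # triose-only reference
fit0 <- mfa_fit(ref, model)
precision_report(flux_table(fit0), flux_table(fit))  # P > 1: panel wins

pca <- pca_fluxes(flux_matrix)   # samples x fluxes; varimax + rescaling
jackknife_loadings(flux_matrix)  # leave-one-out loading significance
```

A thin command-line wrapper is installed under `inst/cli/pppmfa`
(`simulate`, `fit`, `score`, `pca`, `validate-data`, `print-config`).

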