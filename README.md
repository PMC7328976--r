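# metacred

Meta-analysis and cumulative-evidence grading for genetic association
studies.

## The problem

Field synopses collect every case-control study of a set of genetic
variants and a set of diseases, pool the per-study odds ratios, and grade
how credible each significant association is.  `metacred` implements that
whole chain for variant-cancer catalogues, as used in synopses of the
chromosome 8q24 risk region:

* **Per-study effects** — minor-allele 2x2 odds ratios from genotype
  counts (with Haldane-Anscombe continuity correction), reported-OR
  fallback, chi-square and exact Hardy-Weinberg tests on the control arm.
* **Pooling** — fixed-effect inverse-variance and DerSimonian-Laird
  random-effects on the log-OR scale:
  θ̂ = Σwᵢθᵢ/Σwᵢ with wᵢ = 1/seᵢ² (fixed) or 1/(seᵢ² + τ²) (random),
  Cochran's Q, I² = max(0, (Q − (k−1))/Q), and the moment estimator
  τ² = max(0, (Q − (k−1))/(Σwᵢ − Σwᵢ²/Σwᵢ)).
* **Sensitivity suites** — leave-one-out, drop the first-published study,
  drop HWE-violating studies; cumulative meta-analysis by publication
  year; subgroup pooling; meta-regression.
* **Small-study bias** — Harbord's modified regression test:
  Z = a − (a+b)(a+c)/n, V = (a+b)(c+d)(a+c)(b+d)/(n²(n−1)), OLS of Z/√V on
  √V; a non-zero intercept signals funnel asymmetry.
* **FPRP** — Wacholder's false-positive report probability,
  FPRP = α(1−π) / (α(1−π) + power·π), with power at a target OR of 1.5
  over a grid of priors π.
* **Venice grading** — amount of evidence (test alleles: A > 1000,
  B 100–1000, C < 100), replication (I²: A < 25%, B 25–50%, C > 50%),
  protection from bias (Harbord test, sensitivity stability, and the
  OR < 1.15 smallness rule with a GWAS-replication exception); composite
  strong/moderate/weak plus a one-level upgrade when FPRP < 0.05.
* **Genetic model-free inference** — pooled per-genotype ORs and
  λ = logOR₁/logOR₂ with a study-level bootstrap CI, classifying the mode
  of inheritance (λ ≈ 0 recessive, ≈ 0.5 additive, ≈ 1 dominant).
* **Synthetic catalogues** — a seeded generator of case-control genotype
  counts under HWE with per-genotype odds (1, OR₂^λ, OR₂), between-study
  heterogeneity τ², and an optional publication-selection mechanism, so
  every stage is testable without external data.

The package also ships an encoded catalogue of the published summary
results (pooled OR/CI/p, I², FPRP category, grades) for 27 variants in
8q24 across seven cancers — see `load_8q24_synopsis()`.

## Worked example

```r
library(metacred)

cfg <- sim_config(n_studies = 12, maf = 0.3, or2 = 1.69, lambda = 0.5,
                  tau2 = 0, n_cases = 1500, n_controls = 1500, seed = 20)
catalogue <- simulate_catalogue(cfg)   # 12 studies, true allele OR = 1.3
syn <- run_synopsis(catalogue)
syn
#> synopsis: 1 associations (1 significant, 1 graded)
#>     variant   cancer  k or_pooled ci_low ci_high   p_value i_squared_pct model
#> 1 rsSIM0001 prostate 12     1.348  1.306    1.39 3.789e-78         26.18 fixed
#>   final_grade
#> 1      strong

syn$credibility[[1]]
#> Venice grades: amount A, replication B, bias A -> moderate
#> FPRP category <0.05 -> final grade: strong
#> rationale: AMOUNT_A:n=23597; REPL_B:I2=26.2;
#>   BIAS_A:or=1.348,harbord_p=0.799,stable=TRUE,gwas=FALSE;
#>   VENICE_MODERATE; UPGRADE_FPRP:moderate->strong
```

The pooled allele OR of 1.348 (95% CI 1.306–1.39) recovers the generating
OR of 1.3; I² of 26.2% puts replication in band B, giving an initial
moderate grade that the FPRP (far below 0.05 at the 0.05 prior) upgrades
to strong.  The mode of inheritance is recovered too:

```r
model_free_analysis(catalogue, n_boot = 1000, seed = 20)
#> model-free analysis over 12 studies
#>   OR1 1.336, OR2 1.834
#>   lambda 0.478 (95% CI 0.395-0.568): additive-codominant
```

Summary-mode grading on the published 8q24 catalogue:

```r
graded <- grade_summaries(load_8q24_synopsis())
table(graded$final_grade)
#> moderate   strong     weak
#>       13        6        4
```

`write_results(syn, "out/")` writes the results table, the per-study
forest table, the FPRP grid, the reject report and a JSON run manifest.
A thin command-line wrapper with `run`, `simulate`, `grade` and `fixture`
subcommands is installed at
`system.file("cli", "metacred.R", package = "metacred")`.

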