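# mcoFrontier

Multiple-criteria optimization for differential gene expression: find the
genes with the best balances of expression change across two to five
conflicting performance measures, as the Pareto-efficient frontier of a
minimization problem.

## The problem and the method

Ranking genes by a single statistic (one fold change, one p-value) forces an
arbitrary choice among imperfectly correlated measures of change. Casting
the selection as a multiple-criteria optimization (MCO) problem avoids that:
each gene *g<sub>i</sub>* carries *C* performance measures
*m<sub>i</sub><sup>1</sup>, …, m<sub>i</sub><sup>C</sup>* (here, negated
absolute differences of group means and/or medians between a "control" and a
"cancer" condition), and a gene is reported if **no other gene is at least
as good on every measure and strictly better on at least one** — i.e. if it
is Pareto-efficient. No normalization, thresholds, or distributional
assumptions are involved, so results are reproducible across analysts.

The frontier is found by an exact pairwise penalty scheme. For each
criterion *k* a comparison matrix is built:

    δᵏ_ij = −1  if m_iᵏ < m_jᵏ      (i better)
             0  if m_iᵏ = m_jᵏ      (tie)
             W  if m_iᵏ > m_jᵏ      (i worse; W = 1000 by default)

The matrices are summed (α = Σₖ δᵏ), penalized —
γ = (C/2)·W when α ∈ {0, W, …, (C−1)W}, γ = C·W when α = C·W, else 0 —
and row-summed into β. A gene is on the frontier exactly when
**β<sub>i</sub> < C·W**: with the diagonal self-term (C/2)·W included, any
single weak-dominance event pushes β to the cutoff. All arithmetic is
integer-exact.

Around that core the package provides:

- **tournament partitioning** (`tournament_frontier()`): block-wise local
  frontiers pooled and re-solved, provably identical to the direct result,
  bounding memory on probe sets of tens of thousands of rows;
- **frontier peeling** (`peel_frontiers()`): successive nondominated layers,
  recovering strong candidates pushed just behind the first frontier by
  experimental error;
- **criteria construction** (`build_criteria()`): mean/median group
  differences for single-study (C = 2) or meta-analysis (up to C = 5
  contrasts, no cross-experiment normalization needed);
- **GEO SOFT/GDS input** (`read_gds_soft()`) with sample-subset annotations
  (disease state, smoking status, gender) and annotation-filter sample
  selection;
- a **synthetic generator** (`generate_dataset()`) with planted large-effect
  genes and known ground truth;
- a **CLI** (`inst/scripts/mco_frontier.R`) for shell-driven runs.

## Worked example

The canonical six-gene instance (two criteria, already in minimization
sense) ships as `worked_example()`:

```r
library(mcoFrontier)
ct <- worked_example()     # g1(1,4) g2(3,4) g3(5,6) g4(7,5) g5(3,2) g6(4,1)
res <- pareto_frontier(ct, W = 1000)
res$frontier_ids
#> [1] "g1" "g5" "g6"
res$threshold
#> [1] 2000
res$beta
#>   g1   g2   g3   g4   g5   g6
#> 1000 3000 9000 9000 1000 1000
```

Genes g1, g5 and g6 are the nondominated balances of the two measures: their
β equals the self-term (C/2)·W = 1000, strictly below the cutoff
C·W = 2000. g2 is weakly dominated once (β = 3000); g3 and g4 are dominated
by four genes each (β = 9000). Peeling one more layer yields the next-best
candidate:

```r
lapply(peel_frontiers(ct, layers = 2), `[[`, "frontier_ids")
#> [[1]]
#> [1] "g1" "g5" "g6"
#> [[2]]
#> [1] "g2"
```

The same run from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "mco_frontier.R", package = "mcoFrontier"))') \
    frontier --criteria-tsv table.tsv --out report.tsv
```

For expression data, supply a SOFT file and annotation filters instead:

```sh
... frontier --input GDS3257.soft --format soft \
    --group-a "disease state=control" --group-a "stress=never smoked" \
    --group-b "disease state=lung cancer" --group-b "stress=never smoked" \
    --stats mean,median --out hns_vs_cns.tsv
```

Meta-analysis over several contrasts is driven by a YAML config
(`mco_frontier.R meta --config run.yml`); see `?run_meta`.

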