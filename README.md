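# grnda — natural decomposition of bacterial gene regulatory networks

Curated bacterial gene regulatory networks (GRNs) — directed graphs of
regulator → target interactions with activation/repression signs — share a
common functional architecture. `grnda` identifies its system-level
elements with the natural decomposition approach (NDA):

1. **Global regulators.** The mean local clustering coefficient of
   regulators decays with their out-connectivity as a power law,
   C(k<sub>out</sub>) = γ·k<sub>out</sub><sup>−α</sup>, fitted by robust
   least squares (IRLS with Tukey bisquare weights, or Theil–Sen). The
   **κ-value** is the out-connectivity where the fitted curve has slope
   −1; with k<sub>out</sub> normalized by its maximum,
   κ = (αγ)<sup>1/(α+1)</sup> · k<sub>out</sub><sup>max</sup>.
   Genes with k<sub>out</sub> > κ are the global regulators.
2. **Modules, basal machinery, intermodular genes.** Removing the globals
   and their interactions reveals the modules (remaining connected
   subgraphs of local regulators plus their structural targets) and the
   basal machinery (nodes left disconnected). Structural genes
   (k<sub>out</sub> = 0) regulated from two or more modules are
   intermodular: they integrate disparate physiological responses.
   Modules are locally independent — no cross-regulation between them.
3. **Concilions vs regulons.** A module whose local regulators interact
   with each other (a hierarchical "council" of regulators, feedback and
   cross-regulation included) is a *concilion*; otherwise it is a simple
   regulon (one regulator) or a complex regulon (shared targets only).
4. **Diamond hierarchy.** Globals form the coordination layer, modular
   plus basal genes the processing layer, intermodular genes the
   integration layer; per-layer gene fractions quantify the non-pyramidal,
   diamond-like shape.

A planted-structure synthetic generator (`synth_spec()`,
`generate_grn()`) and an incompleteness simulator (`degrade_grn()`,
`robustness_scan()`) make the whole pipeline testable end to end, with
ground-truth labels to recover.

The package is tidyverse-native: edge lists, class tables, curves and
reports are tibbles; fitted objects support `tidy()`/`glance()`; every
result type has an `autoplot()`.

## Worked example

The bundled 11-gene toy network `toy_t1()` has a hub `R0`, two local
modules, two hub-only targets and one gene wired from both modules. Small
networks cannot support the curve fit, so κ is supplied directly:

```r
library(grnda)
dec <- run_nda(toy_t1(), kappa_override = 5)
dec
#> <grnda_decomposition> of T1
#>   kappa used: 5
#>   global regulators: 1  modules: 2
#>   classes: basal=2 global=1 intermodular=1 modular=7
classify_modules(dec)[, 1:5]
#> # A tibble: 2 × 5
#>   module_id n_genes n_regulators n_structural verdict
#>       <int>   <int>        <int>        <int> <chr>
#> 1         1       4            2            2 concilion
#> 2         2       3            1            2 simple_regulon
layer_assignment(dec)
#> <grnda_hierarchy> diamond architecture
#>   coordination     1 genes    9.09%
#>   processing       9 genes   81.82%
#>   integration      1 genes    9.09%
#>   feedback edges: 0   cross-module violations: 0
```

`R0` alone exceeds κ = 5 (k<sub>out</sub> = 6); module 1 is a concilion
because its regulators interact (`A1 → A2`); the gene `X`, a sink
regulated from both modules, is intermodular; `H1`, `H2`, regulated only
by the hub, are basal machinery.

On a realistic synthetic network the κ threshold is fitted from the
clustering curve:

```r
sim <- generate_grn(synth_spec(seed = 7))
dec <- run_nda(sim$grn)
dec$provenance$fit
#> # A tibble: 1 × 8
#>   alpha  gamma kappa kout_max residual_scale n_points n_zero_dropped method
#>   <dbl>  <dbl> <dbl>    <int>          <dbl>    <int>          <int> <chr>
#> 1 0.829 0.0640  9.85       49          0.103        6              0 irls_bisqu…
glance(dec)
#> # A tibble: 1 × 8
#>   n_genes n_interactions n_global n_modular n_basal n_intermodular n_modules
#>     <int>          <int>    <int>     <int>   <int>          <int>     <int>
#> 1      59            153        2        43      10              4         6
```

κ ≈ 9.8 separates the two planted hubs (k<sub>out</sub> ≈ 45) from every
local regulator (k<sub>out</sub> ≤ 6), and all four planted classes are
recovered exactly.

Networks are read and written with `read_network()` / `write_network()`
(three-column TSV, SIF, and Abasy Atlas export dialects). A command-line
interface wrapping the same functions ships at `inst/cli/nda.R`:

```sh
NDA_CLI=$(Rscript -e 'cat(system.file("cli/nda.R", package = "grnda"))')
Rscript $NDA_CLI decompose --input network.tsv --outdir out/
Rscript $NDA_CLI simulate --seed 7 --outdir sim/
Rscript $NDA_CLI robustness --input network.tsv --fractions 0.1,0.2,0.3 --outdir rb/
```

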