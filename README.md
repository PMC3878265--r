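# reprodet

Reprogramming determinants from differential stability analysis of
Boolean gene regulatory networks.

Cell-fate conversions — differentiation, transdifferentiation,
dedifferentiation — are driven by surprisingly small sets of genes.
reprodet finds candidates for those sets computationally, with no prior
candidate list.  It models a gene regulatory network (GRN) as a signed
Boolean network, identifies its stable states (attractors) with the
phenotypes observed in expression data, and asks: which minimal gene
perturbations destabilize the initial attractor *and* stabilize the final
one?  It is aimed at systems-biology researchers designing reprogramming
experiments from a reconstructed GRN plus a pair of binarized expression
profiles.

## The method

States are 0/1 vectors over the genes, updated synchronously under an
inhibitor-dominant rule:

```
x_v' = (no inhibitor of v active) AND (some activator of v active,
                                       vacuously true if v has none)
```

Attractors are the fixed points of this map.  Multistability requires
**positive circuits** — elementary cycles with an even number of
inhibitions.  For an ordered attractor pair, a positive circuit is a
**differentially expressed positive circuit (DEPC)** when every one of
its genes changes state between the two attractors and its restricted
states are fixed points of the circuit in isolation; the DEPCs are the
stability elements holding the two phenotypes apart.  **Reprogramming
determinants (RDs)** are minimal gene sets, drawn from the DEPCs, whose
clamping to final-phenotype values verifiably drives the network from
the initial to the final attractor in simulation (clamps are transient:
held to a fixed point of the clamped system, then released — the final
phenotype must self-sustain).  Literature-derived networks can first be
*contextualized*: an evolutionary algorithm prunes interactions until
attractors match the observed profiles, and its score says how much of
the data the model explains.

## Worked example: the EMT switch

The bundled epithelial–mesenchymal transition network (reconstructed from
published interaction tables; see `?emt_network`) couples the
SNAI1/ZEB1/ZEB2 axis with the miR-200/miR-203/miR-34 families:

```r
library(reprodet)
emt <- emt_network()
emt
#> <grn> 4 genes + 3 miRNAs, 17 interactions (2 activations, 15 inhibitions)

attractors(emt)
#> # A tibble: 2 × 8
#>      id  CDH1 MIR200 MIR203 MIR34 SNAI1  ZEB1  ZEB2
#>   <int> <int>  <int>  <int> <int> <int> <int> <int>
#> 1     1     0      0      0     0     1     1     1
#> 2     2     1      1      1     1     0     0     0
```

Attractor 2 is the epithelial phenotype (E-cadherin and the miRNAs ON,
the EMT inducers OFF); attractor 1 is its mesenchymal mirror image.  The
full search, with the attractor pair chosen by matching the bundled
binarized profiles:

```r
rd <- find_reprogramming_determinants(emt, profiles = emt_profiles())
rd[, c("rd_id", "size", "perturbation", "validated")]
#> # A tibble: 1 × 4
#>   rd_id  size perturbation   validated
#>   <int> <int> <chr>          <lgl>
#> 1     1     1 activate SNAI1 TRUE

glance(rd)
#> # A tibble: 1 × 6
#>   n_combinations min_size max_size n_depcs n_attractors all_validated
#>            <int>    <int>    <int>   <int>        <int> <lgl>
#> 1              1        1        1      12            2 TRUE
```

Twelve positive circuits separate the two phenotypes (all twelve circuits
of this network are positive), and a single perturbation — sustained
activation of SNAI1 — flips all of them and lands the network in the
mesenchymal attractor, where it stays after the stimulus is released.
That is the experimentally validated trigger of EMT.

Every stage is also available on its own (`attractors()`, `circuits()`,
`detect_depcs()`, `verify_transition()`, `contextualize()`,
`run_insilico_study()`), results are tibbles that pipe into dplyr/ggplot2
(`autoplot()`, `plot_attractors()`, `tidy()`, `glance()`), and
`run_pipeline()` / `inst/scripts/reprodet.R` wrap the whole chain for
file-based use.

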