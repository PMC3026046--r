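# pdzome

Genome-wide prediction and analysis of PDZ domain binding in R.

PDZ domains recognise the extreme C-terminus of their partner proteins.
Scored against a whole proteome, many human PDZ domains are predicted to
bind dozens of C-termini, and that promiscuity traces largely to two
binding-pocket residues: a histidine at helix position αB1 and a valine
at αB5. `pdzome` is for computational biologists who want to run or
benchmark this kind of analysis: it scores binding pockets against
C-termini with an additive lookup-table model, calls binders at a fixed
threshold, and provides the downstream machinery — cross-reactivity
statistics, specific/promiscuous clustering, pocket residue enrichment,
in-silico mutation scans, interactome and GO-compartment context, and
multi-species PDZome catalog summaries — plus a seedable synthetic-data
module that emulates every input with planted structure.

## The model

A binding pocket is an 18-residue string (the 16 key contact residues of
the βB/βC strands and αB helix, plus two flanks; position 14 = αB1,
16 = αB5). A ligand is the last 5 residues of a protein, positions
0, −1, ..., −4 with 0 the C-terminus. The binding score is

```
psi(p, l) = c + Σ_{(i,j)} w_ij(p_i, l_j)
```

summed over the lookup table's contact pairs. Scores with
`psi ≥ θ = 0.798` are called binders (predicted Kd < 100 µM at a 6.27%
null false positive rate). Ligand classes follow the standard motifs:
class 1 `X-S/T-X-Φ`, class 2 `X-Φ-X-Φ`, class 3 `X-D/E-X-Φ`.

## Worked example

Generate a synthetic study (254 pockets, 42% promiscuous; 2000 proteins;
planted class-1 bonuses on the αB1/αB5 contacts), score it genome-wide,
and recover the planted structure:

```r
library(pdzome)

cfg      <- synth_config(seed = 1)
tab      <- gen_lookup_table(cfg)   # calibrated to 6.27% null FPR
pockets  <- gen_pockets(cfg)
proteome <- gen_proteome(cfg)

S  <- score_matrix(pockets, proteome$truth, tab)   # 254 x 2000 psi matrix
cl <- cluster_scores(S, k = 2, threshold = tab$threshold)
cl
#> PDZ score clustering (uncentered distance, average linkage, k = 2)
#>   group 1: 147 domains, mean 99.6 ligands at theta = 0.798
#>   group 2: 107 domains, mean 642.4 ligands at theta = 0.798
```

The two recovered groups are the ligand-specific cluster (group 1) and
the promiscuous cluster (group 2); their sizes match the planted
147/107 split exactly here. The promiscuous cluster shows the planted
pocket enrichment:

```r
promiscuous <- names(cl$labels)[cl$labels == 2]
enr <- pocket_enrichment(pockets$pocket,
                         ifelse(pockets$domain_id %in% promiscuous, "b", "a"))
round(c(H_at_alphaB1 = enr$fractions$b["H", "14"],
        V_at_alphaB5 = enr$fractions$b["V", "16"]), 3)
#> H_at_alphaB1 V_at_alphaB5
#>        0.813        0.682
```

i.e. 81% histidine at αB1 and 68% valine at αB5 against the planted
80%/70%. The table's null calibration checks out on fresh null pairs:

```r
estimate_fpr(tab, gen_null_pockets(cfg, 10000),
             gen_null_ligands(cfg, 10000))$fpr
#> [1] 0.0607
```

and an in-silico mutation scan shows the gain-of-binding pattern when a
specific pocket receives the two promiscuity determinants:

```r
panel <- setNames(proteome$truth$cterm[proteome$truth$class == "class1"][1:5],
                  paste0("pep", 1:5))
mutation_scan(pockets$pocket[pockets$group == "a"][1],
              list(HV = c("14" = "H", "16" = "V")), panel, tab)
#>   set ligand_id psi_before psi_after delta call_change
#> 1  HV      pep1     -1.032     0.845  1.88        gain
#> 2  HV      pep2     -1.107     0.604  1.71        none
#> 3  HV      pep3     -1.699     0.708  2.41        none
#> 4  HV      pep4     -0.425     1.684  2.11        gain
#> 5  HV      pep5     -1.119     1.098  2.22        gain
```

Every delta is positive (the planted bonuses are additive), and three of
the five class-1 peptides cross the binder threshold.

Real inputs use the same code paths: `read_lookup_table()`,
`read_pockets()`, `read_ctermini()` and `read_catalog()` ingest the
plain-text table formats, `Biostrings::readAAStringSet()` +
`extract_cterminus()` handle proteome FASTA, and `merge_databases()`
builds interactomes from edge lists. `simulate_bundle(cfg, dir)` writes
a complete synthetic input bundle in exactly those formats.

See `vignettes/pdz-binding-promiscuity.Rmd` for the model's assumptions,
the generator's design, and the numerical choices.

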