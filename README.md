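# frigg

Resistance gene-directed mining of fungal secondary metabolite gene
clusters.

## The problem

Filamentous fungi carry far more predicted secondary-metabolite
biosynthetic gene clusters (BGCs) than characterized compounds, and
experimental verification is slow. Many bioactive metabolites are toxins
that inhibit an essential enzyme of the producer itself; one documented
self-resistance mechanism is **target-gene duplication**: the BGC carries a
second, resistant copy of the target gene, while the susceptible
housekeeping copy sits elsewhere in the genome (known fungal examples
include the IMP-dehydrogenase copy in the mycophenolic acid cluster and the
proteasome-subunit gene *inpE* in the fellutamide B cluster). A cluster
built this way advertises both bioactivity and its mode of action.

`frigg` searches multi-genome data for exactly this architecture. Given,
for a set of genomes, (i) a protein catalog, (ii) predicted BGC membership
(e.g. from SMURF — cluster prediction is an upstream input, not
reimplemented) and (iii) homologous protein families (precomputed, or built
here by single-linkage clustering of bidirectional BLASTp hits with
identity ≥ 50% and query+subject coverage sum ≥ 130%), it selects clusters
where one gene is a duplicated copy of a conserved, normally single-copy
family.

## The selection model

For every cluster gene the pipeline counts, per organism, the family copy
number `n` (members of its protein family in that organism) and how many of
those copies lie inside predicted clusters. Then:

1. **Step 1 — homology counts** for all cluster genes.
2. **Step 2 — pattern selection.** *Strict*: a cluster is selected iff
   exactly one member has `n = 2` with the extra copy outside **all**
   predicted clusters, and every other member has `n = 1`. That member is
   the putative resistance gene; its free copy is the putative target.
   *Alternative*: members of families larger than `X · n_organisms`
   (user multiplier `X`, recommended ≥ 1.5) are exempt from the copy
   constraint — common tailoring functions (P450s, methyltransferases)
   stop vetoing clusters — but are ineligible as resistance genes.
3. **Step 3 (optional) — recurrence**: keep a candidate only if ≥ 2
   selected clusters share its resistance family (guards against cluster
   prediction errors).
4. **Step 4 — essentiality**: keep a candidate only if its resistance
   family has members in at least `essential_pct`% (typically 90–100%) of
   the organisms.
5. **Step 5 (optional) — single-copy majority**: drop families that are
   multi-copy in more than 50% of the genomes.

Runs over the standard 12-setting grid (strict / alternative X=2 / X=3 ×
step 3 on/off × 90%/98% essentiality) are combined into a per-family 0/1
presence matrix.

## Worked example

No downloads are needed: the package ships a deterministic generator that
plants all six resistance/decoy architectures with a ground-truth manifest.

```r
library(frigg)

gen <- generate_dataset(n_organisms = 8, seed = 7)
gen$dataset
#> frigg dataset:
#>   organisms: 8 (3 sections)
#>   proteins:  659
#>   clusters:  34 (316 cluster genes)
#>   families:  400

run_pipeline(gen$dataset, frigg_config(pattern = "alternative", x_input = 2))
#> frigg run [alt2|step3|90]
#>      step n_clusters n_families
#> 1:  step2          9          5
#> 2:  step3          8          4
#> 3:  step4          6          3
#> 4:  step5          4          2

runs <- run_grid(gen$dataset)
combined <- combine_runs(runs)
length(combined$families)   # 3 unique putative resistance families
length(combined$in_all_runs)  # 1 recovered by every setting

summarize_run_grid(runs)$table
#>      step strict   alt2   alt3
#> 1:      2      4      5      5
#> 2:      3      3      4      4
#> 3:      4    2/2    3/3    3/3
#> 4:     4*    3/3    4/4    4/4
#> 5:      5    1/1    2/2    2/2
#> 6:     5*    2/2    3/3    3/3
```

Reading the run summary: 9 of the 34 clusters match the alternative
selection pattern (5 distinct resistance families); the recurrence filter
removes the singleton case, essentiality and the single-copy majority
filters remove the planted decoys, leaving the clusters whose duplicated
family is conserved and single-copy across the set. The step-count table
has one column per selection setting and one row per step (`*` = step 3
skipped; step-4/5 cells pair the 90%/98% essentiality variants). Every
planted instance's fate can be checked against the manifest:

```r
observed_fate(runs[["strict|step3|90"]], gen$manifest$cluster_id[2])
#> "absent@step2"      # the MPA-like decoy fails step 2, as designed
```

Curation output — context-labelled per-family FASTA
(`organism|section|protein|copies|label` headers with labels
`StrictClust` / `Clust` / `0` / `outsideSC`), candidate tables, label and
presence matrices — is written by `export_run()`.

## Command line

```sh
FRIGG=$(Rscript -e 'cat(system.file("scripts/frigg", package = "frigg"))')
Rscript $FRIGG run   --proteins proteins.tsv --clusters clusters.tsv \
                     --families families.tsv --pattern alternative --x 2 \
                     --essential-pct 90 --out outdir
Rscript $FRIGG grid  --proteins ... --clusters ... --families ... --out outdir
Rscript $FRIGG counts --proteins ... --clusters ... --families ... --out outdir
```

`--hits hits.tsv` (BLAST outfmt-6 tabular, `organism~protein` ids) may
replace `--families` to build families in-process.

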