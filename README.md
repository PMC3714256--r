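# txwb — a transcriptome workbench for non-model organisms

txwb is an R package (plus a thin command-line front end) for analysing de
novo transcriptome projects: organisms without a reference genome, where
the data are assembled transcripts (or proteins with abundances) and
per-library read counts. It is aimed at labs that need a methodical,
scriptable path from FASTA + counts to a queryable, annotated project —
and at comparative projects that merge several such datasets and cluster
homologous sequences across species.

**Single-project path** — load sequences and replicate-grouped counts,
then compute:

* GC content and six-frame open reading frames;
* RPKM normalisation, RPKM = 10⁹·c/(N·L) on replicate-summed counts;
* the Poisson-based R statistic for cross-library heterogeneity,
  R = Σᵢ xᵢ ln(xᵢ/(Nᵢ f)) with f = Σxᵢ/ΣNᵢ and 0·ln 0 = 0 — a cheap
  whole-group ranking score (in nats) that is 0 exactly for proportional
  counts;
* SNP calls from pileup columns via the exact upper-tail binomial
  p-value P(X ≥ k), X ~ Binomial(n, e), under the errors-only null;
* annotation from BLAST tabular hits joined to UniProt-style flat-file
  records (descriptions, taxonomy tags, GO/KEGG/EC/Pfam cross-references)
  and a GO ontology with shortest-is_a-path levels;
* imported DE p-value columns, free-text remarks, and a filter/query
  layer with CSV / FASTA / correlation-matrix exports.

**Multi-project path** — merge projects (translating transcripts by
longest ORF), filter redundant near-twins within a dataset, cluster by
transitive closure of self-BLAST similarity (or import orthoMCL-style
cluster files), and assign each cluster the annotation hit shared by the
most members.

Everything lives in a plain-text project store (a directory of TSV
tables), and a seeded fixture generator can produce every input format
with a ground-truth manifest, so the full pipeline runs and is testable
offline.

## Worked example

Generate a complete demo project (three tissues × three replicates,
planted differential expression, annotation, pileups, remarks), build it,
and run the classic "differential in tip vs both root and stem" query:

```r
library(txwb)

dir <- file.path(tempdir(), "demo")
fx <- fixture_preset("demo-replicas", dir, seed = 101)
store <- build_project(fx$config)
print(store)
#> txwb project 'demo-replicas'
#>   sequences:             120
#>   libraries:             3
#>   replicates:            9
#>   total assigned reads:  209751
#>   p-value columns:       2
#>   annotation hits:       235
#>   GO terms:              50
#>   SNP calls:             34
#>   remarks:               20

hits <- query_sequences(store,
  filter_spec(pval_max = 1e-10,
              pval_columns = c("TiRo", "TiSt"), pval_mode = "all"),
  columns = c("length", "rpkm_Ti", "TiRo", "TiSt", "best_anno_desc"))
head(hits, 4)
#>   seq_id length   rpkm_Ti  TiRo  TiSt              best_anno_desc
#> 1  s0023    953  4715.475 1e-15 1e-15                 Expansin-A4
#> 2  s0044    936  2961.438 1e-15 1e-15 MYB transcription factor 12
#> 3  s0059    509 53880.290 1e-15 1e-15       Heat shock protein 70
#> 4  s0072    801  7060.933 1e-15 1e-15           Chalcone synthase
```

The query is the conjunction of both imported p-value columns at the
1e-10 cutoff ("all" mode); the returned rows are exactly the sequences the
fixture planted to pass both contrasts. `rpkm_Ti` is the tip library's
RPKM, and `best_anno_desc` is the best *informative* annotation — hits
described as "Uncharacterized protein" are never promoted to it.

Pairwise alignment is semi-global with affine gaps (free end gaps at the
longer sequence's ends):

```r
align_pair("ACGTTGCA", "ACGTGCA")
#> pairwise alignment: score 3.00, identity 87.5%, 1 gap column(s)
#> ACGTTGCA
#> ||| ||||
#> ACG-TGCA
```

The same operations are available from a shell via the thin CLI:

```sh
exec/txwb fixtures --preset demo-replicas --out demo --seed 101
exec/txwb build    --config demo/config.ini --out demo-project
exec/txwb query    --project demo-project \
                   --pval-cols TiRo,TiSt --pval-max 1e-10 --pval-mode all \
                   --out de-hits.csv
exec/txwb snps     --pileup demo/pileup.tsv --out snps.csv
```

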