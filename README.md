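# mgecompare

Comparative genomics of small circular mobile genetic elements in R.

Small circular replicons — archaeal plasmids of a few kilobases, and
the spindle-shaped viruses that share genes with them — are compared by
gene content rather than by sequence alignment of whole molecules.
`mgecompare` implements that workflow end to end:

* **ORF prediction on circular DNA** with the conventions usual for
  these replicons (minimum 39 codons counted start through last sense
  codon; starts ATG/GTG/TTG; stops TAA/TAG/TGA), including
  origin-spanning genes, with automated Shine-Dalgarno start selection
  (consensus `AGGAGG`, scanned 4–20 bp upstream of candidate starts).
* **Replication-origin prediction** from centred cumulative GC skew
  (increments +1 for G, −1 for C; minima of the closed circular walk
  mark candidate *ori* positions) matched against large intergenic
  regions, with maximal direct/inverted repeats as supporting evidence.
  Multi-valley profiles yield multiple ranked candidates and are never
  auto-resolved.
* **Gene families** from all-vs-all Smith–Waterman local alignment
  (BLOSUM62, affine gaps 11/1): full hits (identity ≥ 0.30, coverage of
  the shorter protein ≥ 0.70) are clustered by single linkage; partial
  hits (coverage 0.25–0.70) map domain-level, modular relationships but
  never merge families.
* **Pan-genome analysis**: binary presence/absence matrix over
  families, gene-content distances (Jaccard `d = 1 − |A∩B|/|A∪B|`, or
  `d = −ln(|A∩B|/min(|A|,|B|))`), neighbor-joining gene-content trees,
  two-way subfamily delineation, and conservation classes
  (core / semi-conserved / group-specific / singleton).
* **Cross-screening** of an external proteome (e.g. a virus) against
  the plasmid pan-genome, reporting mapped queries and orphans.
* **A synthetic replicon generator** that plants ground truth — gene
  families with subfamily sharing structure, SD motifs, a skew switch
  at a planted origin with nearby repeats — so the whole pipeline is
  testable without downloading anything.

## Worked example

Generate an eight-replicon plasmid set with planted truth and run the
full comparison:

```r
library(mgecompare)

set <- generate_set(synth_config(seed = 7))
dir.create("demo")
write_fasta(set$seqs, "demo/replicons.fasta")

report <- run_compare(run_config(fasta = "demo/replicons.fasta",
                                 out_dir = "demo/out"))
report$stats
#>     replicon length_bp cds coding_pct gc_pct
#> R01      R01      9248   7       78.2   44.1
#> R02      R02     10616   8       78.2   44.0
#> R03      R03      8794   9       93.0   44.1
#> R04      R04     10686   8       77.7   44.3
#> R05      R05     10680   9       74.9   44.0
#> R06      R06     10883   8       76.6   43.8
#> R07      R07     10354   8       74.0   43.8
#> R08      R08      8039   7       90.3   43.8
```

Each row is one replicon: its length, number of predicted genes, the
fraction of positions inside at least one gene, and G+C content — the
descriptive table that opens any small-plasmid comparison. On this
synthetic set the predicted gene complement equals the planted genes
exactly, so `cds` matches the truth gene counts.

```r
report$subfamilies
#> R01 R02 R03 R04 R05 R06 R07 R08
#>   1   1   1   1   2   2   2   2
table(report$conservation)
#> core  group_specific  semi_conserved  singleton
#>    2               8               3          2
cat(report$newick)
#> (R03:0.1386266511,((R05:0.07244607245,R07:0.03866503867):0.1347232628,
#>  (R06:0.0391988567,R08:0.0858011433):0.06111007049):0.4895937396,
#>  (R01:0.05611541237,(R02:0,R04:0):0.06888458763):0.05998445998);
```

The two planted subfamilies are recovered as the two-way split of the
gene-content tree; the two families present in every replicon (the
large replicase-cassette gene and the small regulator) come out as the
core class. Per-replicon origin candidates are in `report$ori`
(rank 1 = the intergenic region best supported by the skew minimum and
repeats). Artifacts (GFF3 gene calls, BED origin candidates, hit and
family tables, PHYLIP distances, newick tree, JSON report) are written
under `demo/out/`.

Real data enter the same way: FASTA (de novo gene calls) or GenBank
flat files, optionally with `trust_annotations = TRUE` to use the
deposited CDS annotations instead of de novo prediction. A thin command
line sits over the same functions:

```sh
inst/exec/mgecompare orfs replicons.fasta        # GFF3 on stdout
inst/exec/mgecompare run -o out replicons.fasta  # full pipeline
inst/exec/mgecompare synth --seed 1 -o synth_out # synthetic set
```

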