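# estssr — EST-SSR marker development toolkit

Microsatellites (simple sequence repeats, SSRs) mined from expressed
sequence tags are the workhorse markers of population and conservation
genetics for non-model organisms: because their flanks sit in transcribed,
conserved sequence, EST-SSRs amplify across related species far more
reliably than genomic SSRs. `estssr` is an R toolkit for the full
development workflow, written for researchers who have a transcript set
(and optionally genotyping, alignment, annotation or cross-species
amplification data) and want reproducible, inspectable markers rather
than a chain of external binaries:

* **Preprocessing** — terminal poly-A/T trimming, a strict < 100 bp length
  filter, local-alignment contaminant screening
  (vector/chloroplast/mitochondrial), and CD-HIT-style greedy clustering
  at 90% identity (matches over the shorter sequence), with conserved
  accounting of every removal.
* **SSR detection** — all maximal perfect tandem repeats of primitive
  motifs, periods 2–6, under three presets (`misa_default`: di ≥ 10,
  tri ≥ 6, tetra ≥ 5, penta ≥ 4, hexa ≥ 3 repeats; `cardle`: 7/5/4/3;
  `len20`: total length > 20 bp). Motifs are grouped into canonical
  classes invariant to rotation and strand (e.g. GA, TC → `AG/CT`);
  nearby loci (gap ≤ 100 bp) merge into compound SSRs.
* **Primer design** — exhaustive enumeration of flanking primer pairs
  under length/Tm/GC/product constraints with a documented penalty
  function, nearest-neighbor melting temperatures (SantaLucia 1998), the
  best three pairs per locus, and optional M13(−21) tailing.
* **Genome placement** — projection of loci through 12-column tabular
  alignment hits (identity > 0.8, strict) onto a reference genome, with
  largest-overlap classification into CDS / 5′UTR / 3′UTR / intergenic
  against GFF3 gene models.
* **Diversity statistics** — per-locus allele number N_A, expected
  heterozygosity H_E = 1 − ΣP²ᵢ (and unbiased uH_E), polymorphism
  information content (both the `1 − ΣP²ᵢ` form and Botstein's), and a
  logistic regression of polymorphism on repeat number with the
  point-biserial correlation reported alongside.
* **Transferability** — species × locus 1/0 amplification matrices to
  mismatch-proportion distances and a Saitou–Nei neighbor-joining tree
  with seeded bootstrap bipartition supports, written as Newick.
* **GO enrichment** — one-sided Fisher's exact test per term (log-space,
  exact) with Benjamini–Hochberg FDR control.
* **Synthetic fixtures** — seeded generators for every input with known
  ground truth (planted SSRs, duplicate maps, allele frequencies,
  generating trees, planted enrichment), so the whole pipeline is testable
  offline.

The methods vignette (`vignettes/estssr-methods.Rmd`) documents the
models, parameter defaults and design decisions in detail.

## Worked example

Everything below runs offline on a seeded synthetic EST set with three
contaminant records and three duplicated sequences spiked in:

```r
library(estssr)

fx  <- make_est_set(n_sequences = 12, duplicate_rate = 0.25,
                    n_contaminants = 3, seed = 42)
pre <- preprocess_ests(fx$sequences, fx$contaminant_refs)
pre$report
#> EST preprocessing report
#>   input sequences      : 18
#>   removed (< min len)  : 0
#>   removed (vector      ): 1
#>   removed (chloroplast ): 1
#>   removed (mitochondrial): 1
#>   valid sequences      : 15
#>   non-redundant        : 12
```

The three planted contaminants are caught by the alignment screen and the
three duplicates collapse in clustering (15 valid → 12 non-redundant).
Detection and summary:

```r
loci <- detect_ssrs(pre$sequences)
head(loci[, c("seq_id", "motif", "canonical_class", "repeat_count",
              "start", "end")], 5)
#>   seq_id  motif canonical_class repeat_count start end
#> 4 est001     CA           AC/GT           12   199 222
#> 1 est002    TGC         AGC/GCT            8    73  96
#> 2 est003   GGTT       AACC/GGTT            6   214 237
#> 3 est004  ACAGC     ACAGC/GCTGT            5   135 159
#> 5 est005 CTAAGT   AAGTCT/AGACTT            4   199 222

s <- summarize_ssrs(loci, merge_compound(loci, builtin_presets()$misa_default),
                    total_bases = sum(nchar(pre$sequences)),
                    n_sequences = length(pre$sequences))
sprintf("loci: %d | density: %.2f kb/SSR | SSR-containing: %.1f%%",
        s$n_loci, s$density_kb_per_ssr, s$frequency_pct)
#> "loci: 5 | density: 1.19 kb/SSR | SSR-containing: 41.7%"
```

Each detected locus is the exact planted repeat: the motif column shows
the observed phase, the canonical class its rotation/strand-invariant
label, and density is searched kilobases per locus. Primer design keeps
the three lowest-penalty pairs per locus; the rank-1 pairs:

```r
primers <- design_primers_all(pre$sequences, loci)
head(primers$primers[primers$primers$rank == 1,
     c("locus_id", "forward", "reverse", "tm_forward", "tm_reverse",
       "product_size")], 3)
#>         locus_id              forward              reverse tm_forward tm_reverse product_size
#> 1 est001:199-222 TGAACCCCCTGCACGCCCTA GTCCTTGCGCAGGGGTCGTT   59.82149   59.62686          267
#> 4   est002:73-96 GGCTAGCAAACGCGCGGTTT TTGGCGCTTACGCGCTCGAT   59.16887   59.84198          269
#> 7 est003:214-237 GCCCAACAGCTTGGCCGGAT ATGCACCCGTTAAGCGGGGC   59.96962   60.04126          218
```

Melting temperatures sit near the 60 °C optimum and every product spans
its SSR. `run_pipeline(pipeline_config(...))` chains all stages (adding
mapping, diversity, enrichment and the transferability tree when their
inputs are configured) and writes per-stage TSVs, a joined marker table, a
summary JSON and a run log; `export_marker_db()` emits the flat-file
marker database. A thin command-line interface with per-stage subcommands
is installed as `exec/estssr`.

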