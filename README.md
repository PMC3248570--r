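# agnc — standardized genetic nomenclature for *Anolis* lizards

With the green anole (*Anolis carolinensis*) genome available, non-avian
reptilian genes can finally be compared to mammalian, avian, amphibian
and teleost homologs — but only if the community agrees on how genes,
species, and repeat elements are named. `agnc` implements the *Anolis*
community nomenclature standards as a validated R library and
command-line tool, for genome annotators, comparative genomicists, and
anyone curating anole sequence resources:

* **Species codes** — four-character abbreviations (`A` + three
  lowercase letters from the epithet: *A. sagrei* → `Asag`), generated
  with fallback-letter collision resolution and precedence by
  publication date, plus the canonical frozen registry of 378 published
  codes.
* **Gene/protein symbols** — anole symbols as lowercase copies of the
  human ortholog symbol (`GENE2` → `gene2`, `NKX3-1` → `nkx3-1`),
  duplication suffixes (`gene2a`/`gene2b`, `gene4aa`/`gene4ab`),
  uppercase protein symbols, interspecies tags (`gene2-Asag`), and name
  screening (no provisional `KIAA#`/`C#orf#` sources, no homology
  parentheticals, no molecular weights).
* **Transcript evidence score** — the additive confidence score over
  four evidence categories, `score = 1·EST + 2·protein + 4·prediction +
  8·cDNA` ∈ [0, 15], with exact bit-field decomposition.
* **Evolutionary character code (ECC)** — the per-gene summary string
  `gene:span:prot,nuc:relation:score:up,down:expr`, e.g.
  `gene2:chordates:80,55:1-1:5:3,4:TS`, with the orthology relation
  classifier (1-1 / 1-n / n-1 / n-n), the taxonomic-span ladder, a
  parser, and a table pipeline.
* **Synteny flank conservation** — counts of sequentially ordered
  reference orthologs on each flank of a focal gene, and the minimal
  orthology-recognition rule (≥ 2 on a single flank).
* **Element names** — conserved sequences (`Acar1000l1SMB`), short
  tandem repeats (`Acar_str_8`, with a minimal perfect-repeat scanner
  and persistable registry), and transposable elements
  (`Helitron-1N1_Acar`, `hAT-HT1_Acar`) with bidirectional grammars.

## Worked example

Assign codes to three species whose names all begin *gra-*; precedence
(publication order) decides who keeps the default third letter:

```r
library(agnc)
assign_codes(c("grahami", "gracilipes", "granuliceps"))
#> Anolis species registry: 3 record(s)
#>      epithet code precedence_rank
#>      grahami Agra               1
#>   gracilipes Agrc               2
#>  granuliceps Agrn               3
```

*grahami* (earliest) takes `Agra`; *gracilipes* finds `Agra` taken and
scans its own letters to `Agrc`; *granuliceps* lands on `Agrn`.

Score a transcript supported by a consistent gene prediction (4 points)
and EST alignment (1 point), then assemble the full evolutionary
character code for the worked hypothetical "gene2":

```r
evidence_score(evidence_set(est_aligned = TRUE, prediction_consistent = TRUE))
#> [1] 5

ecc_record("gene2", "chordates", 80, 55, copies_query = 1,
           copies_reference = 1, evidence_score = 5,
           synteny_up = 3, synteny_down = 4, expression_code = "TS")
#> ECC record: gene2:chordates:80,55:1-1:5:3,4:TS
```

Read: orthology detected only within chordates; 80% protein / 55%
nucleotide identity; one copy in both query and reference (no
paralogs); evidence score 5; 3 upstream and 4 downstream genes with
conserved synteny against the reference; tissue-specific expression.

Scan a sequence for perfect tandem repeats and name the loci:

```r
scan_strs("AAAATTTTTTACACACAC", min_copies = 3)
#>   unit unit_length copies start end
#> 1    A           1      4     0   4
#> 2    T           1      6     4  10
#> 3   AC           2      4    10  18
str_name("Acar", 8)
#> [1] "Acar_str_8"
```

Or from the shell:

```sh
agnc species validate Asag        # ok, maps to sagrei
agnc gene derive NKX3-1           # nkx3-1
agnc ecc parse gene2:chordates:80,55:1-1:5:3,4:TS
agnc te parse Helitron-1N1_Acar --format json
```

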