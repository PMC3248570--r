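---
title: "Anolis nomenclature standards: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anolis nomenclature standards: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agnc)
```

## Why a nomenclature toolkit

The green anole, *Anolis carolinensis*, was the first non-avian reptile
with a sequenced genome, and the genus *Anolis* — over 350 described
species — is one of the most species-rich tetrapod clades. Comparative
work across anoles, birds, mammals, amphibians and fish needs three
things a model-organism community usually standardizes early: a species
abbreviation vocabulary, gene/protein symbol conventions tied to
orthology, and stable identifiers for non-genic sequence classes
(conserved elements, microsatellites, transposons). This package
implements those community standards as validated, testable code: every
grammar has a generator and a parser, every rule has an error class, and
every published worked example is a unit test.

## Species abbreviation codes

A code is the capital genus letter `A` plus three lowercase letters from
the species epithet: the first two letters, then an identifying third
letter. The default third letter is the epithet's third letter; on a
clash, the scan moves to the next letter of the epithet (position 4, 5,
...) that yields an unused code, skipping letters already tried.
Precedence between species competing for the same code goes to the
earlier publication — `assign_codes()` therefore takes explicit
precedence ranks (publication dates are not bundled; the caller supplies
ranks, ties falling back to input order).

```{r}
assign_codes(c("grahami", "gracilipes", "granuliceps"))$code
```

Two deliberate boundaries:

* The packaged canonical registry of 378 published codes is
  **authoritative, not regenerated**. A handful of its entries predate
  the strict greedy rule (e.g. *baracoae* → `Abao`, where the scan would
  first try `Abar`), so `resolve_code()` always consults the registry
  first and only generates codes for unregistered names, avoiding every
  registered code. The registry is frozen; its entries are exempt from
  the "code letters come from the epithet" invariant that generated
  codes must satisfy.
* When an epithet's letters are exhausted without finding a free code,
  `generate_code()` raises a collision-exhaustion error rather than
  silently drawing letters from outside the name — an abbreviation with
  foreign letters would defeat the mnemonic purpose.

Epithets shorter than three letters are rejected (none exist among
published anole names). Normalization strips a genus prefix (`Anolis` /
`A.`), case-folds, and drops non-letters (hyphens, diacritics).

## Gene and protein symbols

Anole gene symbols are all-lowercase copies of the established (usually
human) ortholog symbol, so the species can be read off the casing alone
(`GENE2` human/chicken, `Gene2` mouse, `gene2` anole/frog/zebrafish).
`derive_symbol()` enforces the character set (ASCII letters, digits,
dash; dash only when the source carries it), rejects provisional source
identifiers (`KIAA#`, `C#orf#`), and is idempotent. Protein symbols are
the uppercase twin. Duplicated anole copies of one mammalian ortholog
take alphabetic suffixes (`gene2a`, `gene2b`; an existing suffix letter
gains a second: `gene4aa`, `gene4ab`); a single round of suffixing is
capped at 26 copies, for which there is no biological precedent at this
scale. Cross-species comparisons append the species code:
`gene2-Asag`.

Where human and mouse symbols disagree the committee asks to be
contacted; as software must do *something* deterministic, validation
reports the conflict and the human symbol wins by default. The
proper/commercial-name screen in `validate_gene_name()` is a
capitalized-token heuristic, off by default: it is too subjective to
hard-fail and would flag legitimate eponymous names.

## The transcript evidence score

Each transcript is scored additively over four evidence categories with
power-of-two weights: 1 (aligned EST), 2 (exon intersects aligned
protein similarity, self-similarity excluded), 4 (a fully consistent
gene prediction), 8 (a fully consistent aligned cDNA). The weights make
the score a bit field, so `evidence_decompose()` recovers the exact
evidence combination from the number — the property suite checks the
two directions are mutually inverse over all 16 cases.

The range is 0–15 although the scheme is described as a single octal
digit. We keep the plain sum: the worked example (EST + prediction = 5)
is consistent with summation, and clamping at 7 would silently merge
distinct evidence states. Batch scoring instead carries an
`octal_overflow` flag for scores above 7. The four flags are
caller-supplied booleans; deciding "fully consistent" from raw
alignments is upstream annotation work with no prescribed algorithm,
and is out of scope.

## The evolutionary character code

The ECC is one colon-separated string of seven fields per gene:

```{r}
ecc_serialize(ecc_record("gene2", "chordates", 80, 55,
                         copies_query = 1, copies_reference = 1,
                         evidence_score = 5, synteny_up = 3,
                         synteny_down = 4, expression_code = "TS"))
```

Design choices that were genuinely open:

* **Clade ladder.** The comparison set (mammals; birds; non-avian
  reptiles; amphibians; teleosts; non-vertebrate chordates) implies a
  nesting but no explicit vocabulary. We fixed the ladder `squamates <
  reptiles < amniotes < tetrapods < vertebrates < chordates` (most
  nested first) and map each comparison taxon to the smallest clade
  containing it together with the anole: a mammalian alignment forces at
  least amniotes, amphibian tetrapods, teleost vertebrates, chordate
  chordates; bird or non-avian-reptile hits stay within reptiles.
  `assign_span()` returns the ladder maximum over the present taxa, is
  monotone in the presence map, and returns `NA` (a distinct no-homolog
  signal, not an error) when nothing aligns. The ladder is a function
  argument, so a different vocabulary file can replace it.
* **Relation field.** Copy-number relations print as `1-1`, `1-n`,
  `n-1`, `n-n` with a dash, since the colon is the field separator.
  Counts above one are not retained in the string, so parsing returns
  the canonical marker `"n"`; round-trip identity holds on canonical
  records. A zero copy count is rejected — absence of an ortholog is a
  span question, not a relation.
* **dN/dS mode.** Identity metrics may be percent identities or
  dN/dS rates. Nothing in a bare `0.8,1.2` distinguishes the two, so
  rate mode serializes with an explicit `dnds=` prefix on the metric
  field. Metrics are validated (percents in 0–100, rates non-negative)
  but never computed here — alignment and codon-model estimation belong
  to external programs.
* **Expression field.** Only tissue-specific (`TS`) expression appears
  in the worked example; we complete the vocabulary with `CE` (conserved
  expression) and `ND` (no data) as configurable plumbing. Scoring
  expression divergence itself is explicitly future committee work and
  is a validated token here, nothing more.

## Synteny flank conservation

Minimal orthology recognition requires at least 2 orthologous genes, in
sequential order, on the 5' or the 3' flank (reference: chicken by
default; any gene order table is accepted). `flank_conservation()`
walks one flank nearest-first and counts the longest prefix whose genes
all map to reference orthologs occupying strictly monotonic,
consecutive ordinal ranks in the reference order; the first unmapped
gene or broken step ends the walk.

Numerical conventions: reference positions are reduced to ordinal ranks
(raw coordinates may be basepairs or indices; ties are an input error),
so only order matters; the run's direction (increasing or decreasing
reference coordinates) is set by its first step, making counts
invariant under reversing the reference coordinate axis; gene
orientation/strand is ignored. Whether "sequential order" tolerates a
reference-only gene interrupting the run is not prescribed; the default
is strict (gap 0), with a `max_gap` parameter allowing `g` intervening
reference genes per step for users who want robustness to small
reference insertions.

The counter is verified against an exhaustive oracle that tests every
prefix of every flank explicitly, on more than a thousand random
contexts of up to 12 genes per flank.

## Conserved sequences, STRs, transposable elements

**CS names** concatenate species code, an arbitrary 1-indexed number, a
length class (`s` ≤ 99 bp, `m` 100–499 bp, `l` ≥ 500 bp), a
conservation class (`1` 95–100%, `2` 90–94%, `3` 85–89%), and taxon
letters always serialized in the canonical order S (Sauropsida), M
(Mammalia), B (Batrachia), G (Gymnophiona): `Acar1000l1SMB`. Fractional
percents fall between the integer class bounds, so values are rounded
half-up to an integer percent before classing (94.5% → class 1,
94.4% → class 2). Below 85% a sequence is out of class and naming
fails. Since the name encodes classes, not values, `cs_parse()` returns
intervals rather than fabricating point values. Which taxa a CS is
shared with is caller-supplied: the toolkit names elements, it does not
discover them from whole-genome alignments.

**STR names** are `<SpeciesCode>_str_<index>` with 1-indexed discovery
order; everything else about a locus (unit, copy number, coordinates)
lives in a sidecar table keyed by the name, mirroring the
separate-database design for locus metadata. The bundled scanner
(`scan_strs()`) exists to exercise this plumbing end to end and is
deliberately minimal: perfect repeats only, unit lengths 1–6, whole
copies only (a trailing partial copy is not counted), overlaps resolved
longest-first, then leftmost, then smallest unit, `N` treated as an
ordinary letter. It is checked against a quadratic brute-force
enumerator on random sequences; it is not a competitor to dedicated
repeat finders (no mismatches, no indels, no composite repeats).

**TE names** follow
`<lineage>-[HT]<family>[N<id>]_<SpeciesCode>`: `Helitron-1_Acar`
(autonomous family 1), `Helitron-1N1_Acar` (non-autonomous family
amplified by it), `hAT-HT1_Acar` (horizontally transferred). Lineage
tokens are free-form validated identifiers — below-superfamily clade
names like `hobo` are preferred where the diversity is well
characterized, but no controlled superfamily list is enforced, because
transposon classification is openly a work in progress. Choosing
replacement names for families shared across distant taxa (the
*Heligloria* style) is editorial, not algorithmic, and out of scope.

## Synthetic fixtures and what passing means

`make_species_fixture(n, collision_rate, seed)` draws random epithets
and forces a chosen fraction to share a 3-letter prefix with an earlier
name, so code assignment must exercise the fallback scan. Forced
collisions are feasibility-checked during construction: a shared-prefix
name is only kept if the scan can still resolve it, because random
prefix clusters can otherwise exceed the distinct-letter capacity of a
short epithet — a dead end the real species table does not contain.
`make_synteny_fixture(up, down, flank_len, seed)` builds a flank
context whose conserved-prefix counts are exactly the requested pair,
breaking each flank immediately after the prefix with either an
unmapped gene or a rank gap (the gap occupied by reference-only filler
genes, since ranks are ordinal). Both generators restore the session
RNG state and are bit-identical under a fixed seed.

These fixtures emulate the *combinatorics* of the standards — prefix
collisions, order conservation, evidence combinations — not the biology
that produces them: no sequence evolution, no real gene density or
rearrangement rates, no annotation noise. Passing the property suite
shows the rules are implemented exactly as specified, not that the
rules are easy to apply to noisy real annotations; the evidence flags,
identity metrics, and ortholog maps consumed here are upstream calls
with their own error rates.

Problem sizes used by the test suite: 1,100 random synteny contexts
(≤ 12 genes per flank) against the exhaustive prefix oracle, 1,000
collision-heavy species lists of 5–25 names, 35 random sequences of up
to 500 bp against the quadratic repeat enumerator, and a few hundred
randomized ECC/CS/TE round trips — sizes at which the brute-force
oracles are unambiguous and the whole suite runs in well under a
minute.

## Known limitations

* Sub-species and geographic-race designations are deliberately
  unsupported (the community is still gathering proposals), as is
  taxonomic synonymy resolution.
* The human-vs-mouse symbol conflict policy (report + prefer human) is
  a software default, not a committee ruling; genes whose human *and*
  mouse names are both provisional are reported as unresolvable.
* How a gene with no detectable homolog should serialize as an ECC is
  not prescribed; `assign_span()` signals the case distinctly and the
  pipeline reports such genes instead of inventing a token.
* The weighted, committee-curated orthology point system is announced
  future work and not implemented here.
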