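#' Gene and protein symbols
#'
#' *Anolis* gene symbols are written all-lowercase (italicized in print) and,
#' where orthology has been established, mirror the human symbol: human
#' `GENE2` becomes anole `gene2`. Punctuation is carried over only when the
#' source symbol contains it (`NKX3-1` -> `nkx3-1`). Protein symbols are the
#' same token in uppercase, without italics. The all-lowercase convention
#' matches *Xenopus* and zebrafish styling so the species can be inferred
#' from the symbol's case alone.
#'
#' @name gene-symbols
NULL

STYLED_SPECIES <- c("human", "mouse", "chicken", "xenopus", "zebrafish",
                    "anolis")

# Provisional identifiers (KIAA0101, C9orf72, ...) must not seed a name.
is_provisional_symbol <- function(x) {
  grepl("^KIAA[0-9]+$", x, ignore.case = TRUE) |
    grepl("^C[0-9]+orf[0-9]+$", x, ignore.case = TRUE)
}

#' Derive an Anolis gene symbol from an ortholog's symbol
#'
#' @param source_symbol Published ortholog symbol (e.g. the human symbol).
#' @param source_species Species the symbol comes from; one of
#'   `"human"`, `"mouse"`, `"chicken"`, `"xenopus"`, `"zebrafish"`.
#' @return The lowercase Anolis symbol.
#' @examples
#' derive_symbol("GENE2")   # "gene2"
#' derive_symbol("NKX3-1")  # "nkx3-1"
#' derive_symbol("ACTB")    # "actb"
#' @export
derive_symbol <- function(source_symbol, source_species = "human") {
  agnc_assert(is_string(source_symbol) && nzchar(source_symbol),
              "source_symbol must be a non-empty string", "invalid_symbol")
  source_species <- match.arg(source_species, STYLED_SPECIES)
  agnc_assert(!grepl("[^\x01-\x7f]", source_symbol),
              sprintf("'%s' contains non-ASCII characters", source_symbol),
              "invalid_symbol")
  if (is_provisional_symbol(source_symbol))
    agnc_stop(sprintf(
      "'%s' is a provisional identifier (KIAA#/C#orf#) and cannot seed an Anolis symbol",
      source_symbol), "provisional_name")
  agnc_assert(grepl("^[A-Za-z0-9-]+$", source_symbol),
              sprintf(
                "'%s' contains disallowed punctuation (only letters, digits, dash permitted)",
                source_symbol), "invalid_symbol")
  tolower(source_symbol)
}

#' Symbols for duplicated gene copies
#'
#' Lineage-specific duplication of a single mammalian ortholog is marked by
#' appending `a`, `b`, ... to the base symbol. A base that already carries a
#' duplication letter simply gains a second one: `gene4a` -> `gene4aa`,
#' `gene4ab`.
#'
#' @param base_symbol Valid Anolis symbol.
#' @param copy_count Number of duplicate copies (2..26 per round).
#' @return Character vector of `copy_count` suffixed symbols.
#' @examples
#' suffix_duplicates("gene2", 2)   # gene2a gene2b
#' suffix_duplicates("gene4a", 2)  # gene4aa gene4ab
#' @export
suffix_duplicates <- function(base_symbol, copy_count) {
  agnc_assert(is_string(base_symbol) &&
                grepl("^[a-z0-9-]+$", base_symbol),
              "base_symbol must be a valid lowercase Anolis symbol",
              "invalid_symbol")
  agnc_assert(is_count(copy_count, min = 2L),
              "copy_count must be an integer >= 2", "unsupported_count")
  agnc_assert(copy_count <= 26L,
              "more than 26 duplicates in one round is unsupported",
              "unsupported_count")
  paste0(base_symbol, letters[seq_len(copy_count)])
}

#' Protein symbol for a gene symbol
#'
#' @param gene_symbol Valid Anolis gene symbol.
#' @return The symbol in uppercase (protein symbols are not italicized).
#' @examples
#' protein_symbol("gene2")  # "GENE2"
#' @export
protein_symbol <- function(gene_symbol) {
  agnc_assert(is_string(gene_symbol) && grepl("^[a-z0-9-]+$", gene_symbol),
              "gene_symbol must be a valid lowercase Anolis symbol",
              "invalid_symbol")
  toupper(gene_symbol)
}

#' Style a symbol for a given species' convention
#'
#' Case conventions let the reader infer the species from the symbol alone:
#' human and chicken symbols are all-caps, mouse capitalizes the first
#' letter only, and *Xenopus*, zebrafish, and *Anolis* are all-lowercase.
#' Gene symbols are italicized in all of these conventions.
#'
#' @param symbol Gene symbol (any case; restyled).
#' @param species One of `"human"`, `"mouse"`, `"chicken"`, `"xenopus"`,
#'   `"zebrafish"`, `"anolis"`.
#' @return List with `symbol` (styled), `case_class` (`"upper"`,
#'   `"title"`, or `"lower"`), and `italic` (always `TRUE` for gene
#'   symbols).
#' @examples
#' style_for_species("gene2", "mouse")$symbol    # "Gene2"
#' style_for_species("gene2", "chicken")$symbol  # "GENE2"
#' @export
style_for_species <- function(symbol, species) {
  agnc_assert(is_string(symbol) && grepl("^[A-Za-z0-9-]+$", symbol),
              "symbol must contain only letters, digits, dash",
              "invalid_symbol")
  agnc_assert(is_string(species) && species %in% STYLED_SPECIES,
              sprintf("unknown species '%s'; expected one of %s",
                      as.character(species)[1],
                      paste(STYLED_SPECIES, collapse = ", ")),
              "unsupported_species")
  case_class <- switch(species,
                       human = , chicken = "upper",
                       mouse = "title",
                       "lower")
  styled <- switch(case_class,
                   upper = toupper(symbol),
                   lower = tolower(symbol),
                   title = paste0(toupper(substr(symbol, 1L, 1L)),
                                  tolower(substring(symbol, 2L))))
  list(symbol = styled, case_class = case_class, italic = TRUE)
}

#' Tag a gene symbol with a species code for cross-species comparison
#'
#' In comparative analyses the four-letter species abbreviation is appended
#' as a suffix, e.g. `gene2-Asag` for the *A. sagrei* ortholog of `gene2`.
#'
#' @param symbol Valid Anolis gene symbol.
#' @param species_code Four-character species code (pattern-validated).
#' @return The suffixed token.
#' @examples
#' interspecies_suffix("gene2", "Asag")  # "gene2-Asag"
#' @export
interspecies_suffix <- function(symbol, species_code) {
  agnc_assert(is_string(symbol) && grepl("^[a-z0-9-]+$", symbol),
              "symbol must be a valid lowercase Anolis symbol",
              "invalid_symbol")
  chk <- validate_code(species_code)
  agnc_assert(chk$ok,
              sprintf("invalid species code '%s': %s",
                      as.character(species_code)[1],
                      paste(chk$findings, collapse = "; ")),
              "code_format")
  paste0(symbol, "-", species_code)
}

#' Validate a full gene name against naming guidelines
#'
#' Screens a free-text gene name for patterns the guidelines exclude:
#' homology parentheticals ("delta-like 1 (Drosophila)"), provisional
#' identifiers (KIAA#, C#orf#), and molecular-weight references (p35,
#' "35 kDal protein"). An optional proper-name heuristic flags capitalized
#' tokens; it is off by default because it is too subjective to hard-fail.
#'
#' @param name Free-text gene name.
#' @param check_proper_names Enable the warning-only capitalized-token
#'   heuristic.
#' @return List with `ok`, `findings` (character), and `suggested` (name
#'   with homology parentheticals stripped; equals `name` when clean).
#' @examples
#' validate_gene_name("delta-like 1 (Drosophila)")
#' validate_gene_name("yolk expressed protein 1")  # ok
#' @export
validate_gene_name <- function(name, check_proper_names = FALSE) {
  agnc_assert(is_string(name) && nzchar(trimws(name)),
              "name must be a non-empty string", "invalid_symbol")
  findings <- character()
  suggested <- name
  if (grepl("\\([^)]*\\)", name)) {
    findings <- c(findings,
                  "homology/disease parenthetical should be omitted")
    suggested <- trimws(gsub("\\s*\\([^)]*\\)", "", name))
  }
  tokens <- strsplit(name, "[ ,;]+")[[1]]
  if (any(is_provisional_symbol(tokens)))
    findings <- c(findings,
                  "provisional identifier (KIAA#/C#orf#) should not seed a gene name")
  if (grepl("(^|[ (])p[0-9]+($|[ ,;)])", name) ||
      grepl("[0-9]+\\s*kDa?l?\\b", name, ignore.case = TRUE))
    findings <- c(findings,
                  "molecular-weight reference should be avoided")
  if (check_proper_names) {
    inner <- tokens[-1][grepl("^[A-Z][a-z]+$", tokens[-1])]
    if (length(inner))
      findings <- c(findings, sprintf(
        "possible proper/commercial name: %s", paste(inner, collapse = ", ")))
  }
  list(ok = length(findings) == 0L, findings = findings,
       suggested = suggested)
}

#' Validate an Anolis gene symbol
#'
#' Format checks (lowercase; letters, digits, dash only) plus the
#' species-prefix rule: a symbol must not begin with "a"/"ac" as an
#' *Anolis carolinensis* abbreviation — those leading letters are only
#' acceptable when the source ortholog symbol itself begins with them
#' (e.g. \code{actb}).
#'
#' @param symbol Candidate Anolis symbol.
#' @param source_symbol Ortholog symbol the Anolis symbol was derived from,
#'   when known; enables the species-prefix check.
#' @return List with `ok` and `findings`.
#' @examples
#' validate_gene_symbol("gene2")                      # ok
#' validate_gene_symbol("acgene2", "GENE2")           # species-prefix finding
#' validate_gene_symbol("actb", "ACTB")               # ok
#' @export
validate_gene_symbol <- function(symbol, source_symbol = NULL) {
  findings <- character()
  if (!is_string(symbol) || !nzchar(symbol)) {
    findings <- "symbol must be a non-empty string"
  } else {
    if (grepl("[A-Z]", symbol))
      findings <- c(findings, "symbol must be entirely lowercase")
    if (!grepl("^[A-Za-z0-9-]+$", symbol))
      findings <- c(findings,
                    "symbol may contain only letters, digits, dash")
    if (!is.null(source_symbol) && is_string(source_symbol)) {
      src <- tolower(source_symbol)
      if (grepl("-", symbol, fixed = TRUE) &&
          !grepl("-", src, fixed = TRUE))
        findings <- c(findings,
                      "dash present but absent from the source symbol")
      pfx <- if (startsWith(tolower(symbol), "ac")) "ac"
             else if (startsWith(tolower(symbol), "a")) "a"
             else NA_character_
      if (!is.na(pfx) && !startsWith(src, pfx))
        findings <- c(findings, sprintf(
          "symbol must not start with '%s' as a species abbreviation (source '%s' does not)",
          pfx, source_symbol))
    }
  }
  list(ok = length(findings) == 0L, findings = findings)
}
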