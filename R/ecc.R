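#' The evolutionary character code (ECC)
#'
#' The ECC condenses a gene's evolutionary annotation into one
#' colon-separated string of seven fields:
#'
#' ```
#' <gene>:<span>:<protein>,<nucleotide>:<relation>:<score>:<up>,<down>:<expression>
#' ```
#'
#' e.g. `gene2:chordates:80,55:1-1:5:3,4:TS` — orthology detected only
#' within chordates; 80% protein and 55% nucleotide identity; no paralogs
#' within or between species (1-1); transcript evidence score 5 (gene
#' prediction + EST); 3 upstream and 4 downstream genes with conserved
#' synteny against the reference; tissue-specific expression. dN/dS may
#' replace percent identities, written with a `dnds=` prefix on the metric
#' field so the two modes are unambiguous. The code is descriptive metadata
#' linked to a gene: it changes as the input data change.
#'
#' @name ecc
NULL

#' Default taxonomic-span ladder, most-nested clade first
#' @export
DEFAULT_CLADE_LADDER <- c("squamates", "reptiles", "amniotes",
                          "tetrapods", "vertebrates", "chordates")

#' Default expression-code vocabulary
#'
#' `TS` tissue-specific (cross-species comparison), `CE` conserved
#' expression, `ND` no data.
#' @export
DEFAULT_EXPRESSION_CODES <- c("TS", "CE", "ND")

# Comparison-taxon vocabulary and the most-nested ladder rung that a shared
# gene with each taxon implies (anoles being squamates).
COMPARISON_TAXA <- c(mammals = "amniotes",
                     birds = "reptiles",
                     non_avian_reptiles = "reptiles",
                     amphibians = "tetrapods",
                     teleosts = "vertebrates",
                     non_vertebrate_chordates = "chordates")

RELATION_TOKENS <- c("1-1", "1-n", "n-1", "n-n")

#' Classify an orthology/paralogy relation from copy counts
#'
#' Copy-number relations between the query (Anolis) gene and a reference
#' genome are classed as `1-1`, `1-n`, `n-1`, or `n-n`, where n stands for
#' any count above one. A zero count means no ortholog at all, which is a
#' taxonomic-span question, not a relation, and is rejected.
#'
#' @param copies_query Copy count in the query genome (>= 1).
#' @param copies_reference Copy count in the reference genome (>= 1).
#' @return One of `"1-1"`, `"1-n"`, `"n-1"`, `"n-n"`.
#' @examples
#' classify_relation(1, 1)  # "1-1"
#' classify_relation(1, 4)  # "1-n"
#' @export
classify_relation <- function(copies_query, copies_reference) {
  agnc_assert(is_count(copies_query, 1L) && is_count(copies_reference, 1L),
              "copy counts must be integers >= 1 (0 means no ortholog, which is span/absence, not a relation)",
              "domain")
  paste0(if (copies_query == 1L) "1" else "n", "-",
         if (copies_reference == 1L) "1" else "n")
}

#' Assign the taxonomic span of homology from alignment presence
#'
#' Given which comparison taxa yield a reliable alignment, returns the most
#' inclusive clade required to cover all of them together with *Anolis*
#' (a squamate): a mammalian hit forces at least amniotes, an amphibian hit
#' tetrapods, a teleost hit vertebrates, a non-vertebrate chordate hit
#' chordates; hits restricted to birds or non-avian reptiles stay within
#' reptiles.
#'
#' @param alignment_presence Named logical vector; names drawn from
#'   `mammals`, `birds`, `non_avian_reptiles`, `amphibians`, `teleosts`,
#'   `non_vertebrate_chordates`.
#' @param ladder Span vocabulary, most-nested first.
#' @return A span token, or `NA_character_` when no taxon has a reliable
#'   alignment (no detectable homolog — a signal, not an error).
#' @examples
#' assign_span(c(mammals = TRUE, birds = TRUE, non_avian_reptiles = TRUE,
#'               amphibians = TRUE, teleosts = TRUE,
#'               non_vertebrate_chordates = TRUE))  # "chordates"
#' assign_span(c(non_avian_reptiles = TRUE))        # "reptiles"
#' @export
assign_span <- function(alignment_presence, ladder = DEFAULT_CLADE_LADDER) {
  agnc_assert(is.logical(alignment_presence) && !anyNA(alignment_presence),
              "alignment_presence must be a named logical vector without NA",
              "vocabulary")
  keys <- names(alignment_presence)
  agnc_assert(!is.null(keys) && all(keys %in% names(COMPARISON_TAXA)),
              sprintf("unknown comparison taxa: %s (valid: %s)",
                      paste(setdiff(keys, names(COMPARISON_TAXA)),
                            collapse = ", "),
                      paste(names(COMPARISON_TAXA), collapse = ", ")),
              "vocabulary")
  agnc_assert(all(COMPARISON_TAXA %in% ladder),
              "ladder must contain all spans implied by the comparison taxa",
              "vocabulary")
  present <- keys[alignment_presence]
  if (!length(present)) return(NA_character_)
  ladder[max(match(COMPARISON_TAXA[present], ladder))]
}

#' Construct an ECC record
#'
#' Validates and bundles the seven ECC fields. Copy counts may be given as
#' actual integers (canonicalized to `1`/`"n"` in the serialized relation)
#' or as the `"n"` marker directly.
#'
#' @param gene_id Anolis gene symbol (lowercase; letters, digits, dash).
#' @param taxonomic_span Token from the clade ladder.
#' @param protein_metric Percent protein identity in 0..100, or dN >= 0 when
#'   `identity_mode = "dn_ds"`.
#' @param nucleotide_metric Percent nucleotide identity in 0..100, or
#'   dS >= 0.
#' @param copies_query,copies_reference Positive integer or `"n"`.
#' @param evidence_score Integer 0..15 (see [evidence_score()]).
#' @param synteny_up,synteny_down Non-negative conserved-flank counts.
#' @param expression_code Token from the expression vocabulary.
#' @param identity_mode `"percent_identity"` (default) or `"dn_ds"`.
#' @param ladder,expression_codes Vocabulary overrides.
#' @return An object of class `ecc_record`.
#' @examples
#' r <- ecc_record("gene2", "chordates", 80, 55, 1, 1, 5, 3, 4, "TS")
#' ecc_serialize(r)  # "gene2:chordates:80,55:1-1:5:3,4:TS"
#' @export
ecc_record <- function(gene_id, taxonomic_span, protein_metric,
                       nucleotide_metric, copies_query, copies_reference,
                       evidence_score, synteny_up, synteny_down,
                       expression_code,
                       identity_mode = c("percent_identity", "dn_ds"),
                       ladder = DEFAULT_CLADE_LADDER,
                       expression_codes = DEFAULT_EXPRESSION_CODES) {
  identity_mode <- match.arg(identity_mode)
  agnc_assert(is_string(gene_id) && grepl("^[a-z0-9-]+$", gene_id),
              "gene_id must be a valid lowercase Anolis symbol",
              "invalid_symbol")
  agnc_assert(is_string(taxonomic_span) && taxonomic_span %in% ladder,
              sprintf("unknown taxonomic span '%s' (valid: %s)",
                      as.character(taxonomic_span)[1],
                      paste(ladder, collapse = ", ")), "vocabulary")
  chk_metric <- function(x, what) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
      (identity_mode == "dn_ds" || x <= 100)
    agnc_assert(ok, sprintf(
      "%s must be %s (got %s)", what,
      if (identity_mode == "dn_ds") "a non-negative rate"
      else "a percent in 0..100",
      as.character(x)[1]), "domain")
    as.numeric(x)
  }
  chk_copies <- function(x, what) {
    if (identical(x, "n")) return("n")
    agnc_assert(is_count(x, 1L),
                sprintf("%s must be a positive integer or the marker 'n'",
                        what), "domain")
    as.integer(x)
  }
  agnc_assert(is_count(evidence_score) && evidence_score <= 15L,
              "evidence_score must be an integer in 0..15", "domain")
  agnc_assert(is_count(synteny_up) && is_count(synteny_down),
              "synteny counts must be non-negative integers", "domain")
  agnc_assert(is_string(expression_code) &&
                expression_code %in% expression_codes,
              sprintf("unknown expression code '%s' (valid: %s)",
                      as.character(expression_code)[1],
                      paste(expression_codes, collapse = ", ")),
              "vocabulary")
  structure(list(
    gene_id = gene_id,
    taxonomic_span = taxonomic_span,
    identity_mode = identity_mode,
    protein_metric = chk_metric(protein_metric, "protein_metric"),
    nucleotide_metric = chk_metric(nucleotide_metric, "nucleotide_metric"),
    copies_query = chk_copies(copies_query, "copies_query"),
    copies_reference = chk_copies(copies_reference, "copies_reference"),
    evidence_score = as.integer(evidence_score),
    synteny_up = as.integer(synteny_up),
    synteny_down = as.integer(synteny_down),
    expression_code = expression_code
  ), class = "ecc_record")
}

#' @export
print.ecc_record <- function(x, ...) {
  cat("ECC record:", ecc_serialize(x), "\n")
  invisible(x)
}

# numbers rendered without trailing zeros, no scientific notation
fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Serialize an ECC record to its string form
#'
#' @param record An `ecc_record`.
#' @return The colon-separated ECC string (7 fields).
#' @export
ecc_serialize <- function(record) {
  agnc_assert(inherits(record, "ecc_record"),
              "record must be an ecc_record", "domain")
  metric <- paste0(if (record$identity_mode == "dn_ds") "dnds=" else "",
                   fmt_num(record$protein_metric), ",",
                   fmt_num(record$nucleotide_metric))
  relation <- paste0(
    if (identical(record$copies_query, "n") || record$copies_query > 1L)
      "n" else "1",
    "-",
    if (identical(record$copies_reference, "n") ||
        record$copies_reference > 1L) "n" else "1")
  paste(record$gene_id, record$taxonomic_span, metric, relation,
        record$evidence_score,
        paste0(record$synteny_up, ",", record$synteny_down),
        record$expression_code, sep = ":")
}

#' Parse an ECC string
#'
#' Inverse of [ecc_serialize()]. Copy counts are recovered in canonical
#' form (`1` or the `"n"` marker) since the relation field does not retain
#' exact counts above one. The identity mode is percent identity unless the
#' metric field carries the `dnds=` prefix.
#'
#' @param ecc_string A 7-field colon-separated ECC string.
#' @param ladder,expression_codes Vocabulary overrides.
#' @return An `ecc_record`.
#' @examples
#' ecc_parse("gene2:chordates:80,55:1-1:5:3,4:TS")
#' @export
ecc_parse <- function(ecc_string, ladder = DEFAULT_CLADE_LADDER,
                      expression_codes = DEFAULT_EXPRESSION_CODES) {
  agnc_assert(is_string(ecc_string), "ecc_string must be a single string",
              "structure")
  fields <- strsplit(ecc_string, ":", fixed = TRUE)[[1]]
  agnc_assert(length(fields) == 7L,
              sprintf("ECC string must have exactly 7 colon-separated fields (got %d)",
                      length(fields)), "structure")
  metric_field <- fields[3L]
  identity_mode <- "percent_identity"
  if (startsWith(metric_field, "dnds=")) {
    identity_mode <- "dn_ds"
    metric_field <- substring(metric_field, 6L)
  }
  metrics <- strsplit(metric_field, ",", fixed = TRUE)[[1]]
  agnc_assert(length(metrics) == 2L,
              "metric field must be '<protein>,<nucleotide>'", "structure")
  metrics <- suppressWarnings(as.numeric(metrics))
  agnc_assert(!anyNA(metrics), "metric field values must be numeric",
              "value")
  agnc_assert(fields[4L] %in% RELATION_TOKENS,
              sprintf("relation field must be one of %s (got '%s')",
                      paste(RELATION_TOKENS, collapse = ", "), fields[4L]),
              "value")
  rel <- strsplit(fields[4L], "-", fixed = TRUE)[[1]]
  score <- suppressWarnings(as.integer(fields[5L]))
  agnc_assert(!is.na(score) && identical(as.character(score), fields[5L]),
              "evidence-score field must be an integer", "value")
  syn <- strsplit(fields[6L], ",", fixed = TRUE)[[1]]
  agnc_assert(length(syn) == 2L && all(grepl("^[0-9]+$", syn)),
              "synteny field must be '<up>,<down>' with integer counts",
              "value")
  ecc_record(
    gene_id = fields[1L], taxonomic_span = fields[2L],
    protein_metric = metrics[1L], nucleotide_metric = metrics[2L],
    copies_query = if (rel[1L] == "1") 1L else "n",
    copies_reference = if (rel[2L] == "1") 1L else "n",
    evidence_score = score,
    synteny_up = as.integer(syn[1L]), synteny_down = as.integer(syn[2L]),
    expression_code = fields[7L], identity_mode = identity_mode,
    ladder = ladder, expression_codes = expression_codes)
}
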