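#' Species abbreviation codes
#'
#' Every *Anolis* species carries a four-character abbreviation: the capital
#' letter `A` (for the genus) followed by three lowercase letters drawn from
#' the species epithet. The default code takes the first two letters of the
#' epithet plus its third letter; when that code is already taken, the third
#' letter is replaced by the next letter of the epithet that yields a unique
#' code. Precedence between species competing for the same code goes to the
#' earlier-published name.
#'
#' @name species-codes
NULL

CODE_PATTERN <- "^A[a-z]{3}$"

#' Normalize a species name to a bare epithet
#'
#' Strips an optional genus prefix (`"Anolis "` or `"A. "`), lowercases, and
#' drops every character that is not an ASCII letter (hyphens, diacritics,
#' digits). The result is the canonical lookup key used throughout the
#' registry.
#'
#' @param raw_name Species name, with or without genus prefix.
#' @return Lowercase epithet containing only letters.
#' @examples
#' normalize_epithet("Anolis sagrei")   # "sagrei"
#' normalize_epithet("A. Carolinensis") # "carolinensis"
#' @export
normalize_epithet <- function(raw_name) {
  agnc_assert(is_string(raw_name), "raw_name must be a single string",
              "malformed_name")
  x <- trimws(raw_name)
  x <- sub("^(Anolis|A\\.)[ _]+", "", x, ignore.case = TRUE)
  # transliterate diacritics where the locale allows, then keep letters only
  x <- tryCatch(iconv(x, to = "ASCII//TRANSLIT"), error = function(e) x)
  if (is.na(x)) x <- raw_name
  x <- tolower(gsub("[^A-Za-z]", "", x))
  agnc_assert(nzchar(x),
              sprintf("'%s' contains no letters after normalization", raw_name),
              "malformed_name")
  x
}

#' Generate a unique four-character species code
#'
#' The candidate code is `A` + the first two epithet letters + a third letter.
#' The third letter is scanned from epithet position 3 onward; letters that
#' repeat an already-tried candidate are skipped. The first candidate absent
#' from `taken_codes` wins.
#'
#' @param epithet Normalized species epithet (see [normalize_epithet()]),
#'   at least 3 letters.
#' @param taken_codes Character vector of codes already in use.
#' @return A four-character code unique against `taken_codes`.
#' @examples
#' generate_code("grahami")                          # "Agra"
#' generate_code("gracilipes", "Agra")               # "Agrc"
#' generate_code("granuliceps", c("Agra", "Agrc"))   # "Agrn"
#' @export
generate_code <- function(epithet, taken_codes = character()) {
  agnc_assert(is_string(epithet) && grepl("^[a-z]+$", epithet),
              "epithet must be a normalized lowercase-letter string",
              "malformed_name")
  agnc_assert(nchar(epithet) >= 3L,
              sprintf("epithet '%s' has fewer than 3 letters", epithet),
              "malformed_name")
  agnc_assert(all(grepl(CODE_PATTERN, taken_codes)),
              "taken_codes contains malformed codes", "code_format")
  chars <- strsplit(epithet, "")[[1]]
  prefix <- paste0("A", chars[1L], chars[2L])
  # candidate third letters: epithet positions 3, 4, ... with duplicates
  # collapsed to their first occurrence
  candidates <- unique(chars[-(1:2)])
  for (third in candidates) {
    code <- paste0(prefix, third)
    if (!code %in% taken_codes) return(code)
  }
  agnc_stop(sprintf(
    "cannot derive a unique code for '%s': all candidate letters exhausted",
    epithet), "collision_exhaustion", epithet = epithet)
}

#' Assign codes to an ordered list of species
#'
#' Codes are assigned greedily in ascending precedence order (earlier
#' publication first; ties resolved by input order), each against the set of
#' codes already assigned.
#'
#' @param epithets Character vector of species names (normalized internally).
#' @param precedence_rank Optional numeric vector, lower = earlier
#'   publication. Defaults to input order.
#' @return A `species_registry`: data frame with columns `epithet`, `code`,
#'   `precedence_rank`, rows in input order.
#' @examples
#' assign_codes(c("grahami", "gracilipes", "granuliceps"))
#' @export
assign_codes <- function(epithets, precedence_rank = seq_along(epithets)) {
  agnc_assert(is.character(epithets) && length(epithets) > 0L,
              "epithets must be a non-empty character vector",
              "malformed_name")
  agnc_assert(is.numeric(precedence_rank) &&
                length(precedence_rank) == length(epithets) &&
                !anyNA(precedence_rank) && all(precedence_rank >= 0),
              "precedence_rank must be non-negative and match epithets",
              "malformed_name")
  eps <- vapply(epithets, normalize_epithet, character(1), USE.NAMES = FALSE)
  agnc_assert(!anyDuplicated(eps),
              sprintf("duplicate epithet(s) after normalization: %s",
                      paste(unique(eps[duplicated(eps)]), collapse = ", ")),
              "duplicate_epithet")
  ord <- order(precedence_rank)  # stable: ties keep input order
  codes <- character(length(eps))
  taken <- character()
  for (i in ord) {
    codes[i] <- generate_code(eps[i], taken)
    taken <- c(taken, codes[i])
  }
  new_species_registry(eps, codes, precedence_rank)
}

new_species_registry <- function(epithet, code, precedence_rank,
                                 frozen = FALSE) {
  reg <- data.frame(epithet = epithet, code = code,
                    precedence_rank = as.integer(precedence_rank),
                    stringsAsFactors = FALSE)
  structure(reg, class = c("species_registry", "data.frame"),
            frozen = frozen)
}

#' @export
print.species_registry <- function(x, ...) {
  cat(sprintf("Anolis species registry: %d record(s)%s\n", nrow(x),
              if (isTRUE(attr(x, "frozen"))) " [canonical, frozen]" else ""))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Validate a species abbreviation code
#'
#' Checks the four-character format (`A` + three lowercase letters) and,
#' when a registry is supplied, membership. Findings are reported, never
#' thrown.
#'
#' @param code Candidate code string.
#' @param registry Optional `species_registry` to check membership against.
#' @return A list with `ok` (logical), `findings` (character vector of
#'   problems, empty when clean), and `epithet` (matched species when the
#'   code is registered, otherwise `NA`).
#' @examples
#' validate_code("Asag", load_canonical_registry())
#' validate_code("asag")  # leading letter must be uppercase 'A'
#' @export
validate_code <- function(code, registry = NULL) {
  findings <- character()
  epithet <- NA_character_
  if (!is_string(code)) {
    findings <- "code must be a single character string"
  } else {
    if (nchar(code) != 4L)
      findings <- c(findings, sprintf(
        "code must be exactly 4 characters (got %d)", nchar(code)))
    if (nchar(code) >= 1L && substr(code, 1L, 1L) != "A")
      findings <- c(findings,
                    "code must begin with the capital genus letter 'A'")
    if (nchar(code) == 4L && substr(code, 1L, 1L) == "A" &&
        !grepl(CODE_PATTERN, code))
      findings <- c(findings,
                    "characters 2-4 must be lowercase Latin letters")
    if (!length(findings) && !is.null(registry)) {
      stopifnot(inherits(registry, "species_registry"))
      hit <- match(code, registry$code)
      if (is.na(hit)) {
        findings <- c(findings, "code is not registered")
      } else {
        epithet <- registry$epithet[hit]
      }
    }
  }
  list(ok = length(findings) == 0L, findings = findings, epithet = epithet)
}

#' Load the canonical species-code registry
#'
#' Returns the frozen registry of 378 published *Anolis* abbreviations
#' shipped with the package. The canonical registry is authoritative: a few
#' of its entries predate (and deviate from) the greedy third-letter rule,
#' so codes are looked up here first and only generated for species the
#' registry does not cover.
#'
#' @return A frozen `species_registry` with 378 records.
#' @examples
#' reg <- load_canonical_registry()
#' registry_lookup(reg, "carolinensis")  # "Acar"
#' @export
load_canonical_registry <- function() {
  path <- system.file("extdata", "anolis_species_codes.tsv",
                      package = "agnc", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  agnc_assert(identical(names(tab), c("epithet", "code")),
              "registry file must have columns epithet, code", "integrity")
  agnc_assert(!anyDuplicated(tab$epithet) && !anyDuplicated(tab$code),
              "registry file contains duplicate epithets or codes",
              "integrity")
  agnc_assert(all(grepl(CODE_PATTERN, tab$code)),
              "registry file contains pattern-invalid codes", "integrity")
  new_species_registry(tab$epithet, tab$code,
                       seq_len(nrow(tab)) - 1L, frozen = TRUE)
}

#' Look up a species code by epithet
#'
#' @param registry A `species_registry`.
#' @param name Species name (normalized internally).
#' @return The code, or `NA_character_` when the species is not registered.
#' @export
registry_lookup <- function(registry, name) {
  stopifnot(inherits(registry, "species_registry"))
  registry$code[match(normalize_epithet(name), registry$epithet)]
}

#' Resolve a species code, preferring the canonical registry
#'
#' Registered species keep their published code; unregistered species get a
#' freshly generated code unique against the registry plus `extra_taken`.
#'
#' @inheritParams registry_lookup
#' @param extra_taken Additional codes to avoid when generating.
#' @return A four-character code.
#' @export
resolve_code <- function(name, registry = load_canonical_registry(),
                         extra_taken = character()) {
  epithet <- normalize_epithet(name)
  hit <- registry$code[match(epithet, registry$epithet)]
  if (!is.na(hit)) return(hit)
  generate_code(epithet, c(registry$code, extra_taken))
}
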