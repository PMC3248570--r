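#' Conserved-sequence, STR, and transposable-element names
#'
#' Three compact grammars for non-genic sequence classes:
#'
#' * Conserved sequences (CSs): species code + 1-indexed number + length
#'   class (`s` <= 99 bp, `m` 100-499 bp, `l` >= 500 bp) + conservation
#'   class (`1` 95-100%, `2` 90-94%, `3` 85-89%) + taxon letters in the
#'   canonical order S (Sauropsida), M (Mammalia), B (Batrachia),
#'   G (Gymnophiona). Example: the 1000th CS, 600 bp, 100% conserved and
#'   shared with sauropsids, mammals and batrachians, is `Acar1000l1SMB`.
#' * Short tandem repeats: `<SpeciesCode>_str_<index>`, e.g. `Acar_str_8`;
#'   locus detail (unit, copies, coordinates) lives in a sidecar table
#'   keyed by the name.
#' * Transposable elements: `<lineage>-[HT]<family>[N<id>]_<SpeciesCode>`,
#'   e.g. `Helitron-1_Acar` (autonomous family 1), `Helitron-1N1_Acar`
#'   (non-autonomous family amplified by it), `hAT-HT1_Acar` (horizontally
#'   transferred). Lineage tokens below the superfamily (e.g. `hobo` within
#'   hAT) are preferred where the diversity is well characterized.
#'
#' @name element-names
NULL

CS_TAXA <- c("S", "M", "B", "G")

cs_length_class <- function(length_bp) {
  if (length_bp <= 99) "s" else if (length_bp <= 499) "m" else "l"
}

cs_conservation_class <- function(conservation_pct) {
  # classes are printed as integer percents; round half-up before classing
  pct <- floor(conservation_pct + 0.5)
  if (pct >= 95) "1" else if (pct >= 90) "2" else "3"
}

#' Name a conserved sequence
#'
#' @param species_code Four-character species code.
#' @param index Unique 1-indexed CS number (arbitrary assignment).
#' @param length_bp Sequence length in bp.
#' @param conservation_pct Percent conservation to the reference species,
#'   85-100 (values are rounded half-up to an integer percent before
#'   classing; below 85 is out of class).
#' @param taxa Non-empty subset of `c("S", "M", "B", "G")`: Sauropsida,
#'   Mammalia, Batrachia, Gymnophiona. Serialized in that canonical order
#'   regardless of input order.
#' @return The CS name string.
#' @examples
#' cs_name("Acar", 1000, 600, 100, c("S", "M", "B"))  # "Acar1000l1SMB"
#' @export
cs_name <- function(species_code, index, length_bp, conservation_pct,
                    taxa) {
  chk <- validate_code(species_code)
  agnc_assert(chk$ok, sprintf("invalid species code '%s': %s",
                              as.character(species_code)[1],
                              paste(chk$findings, collapse = "; ")),
              "code_format")
  agnc_assert(is_count(index, 1L), "index must be a positive integer",
              "domain")
  agnc_assert(is_count(length_bp, 1L),
              "length_bp must be a positive integer", "domain")
  agnc_assert(is.numeric(conservation_pct) &&
                length(conservation_pct) == 1L &&
                !is.na(conservation_pct) && conservation_pct <= 100,
              "conservation_pct must be a single percent <= 100", "domain")
  agnc_assert(floor(conservation_pct + 0.5) >= 85,
              sprintf("conservation %s%% is below the lowest class (85-89%%)",
                      as.character(conservation_pct)[1]), "out_of_class")
  agnc_assert(is.character(taxa) && length(taxa) >= 1L &&
                all(taxa %in% CS_TAXA) && !anyDuplicated(taxa),
              sprintf("taxa must be a non-empty subset of %s",
                      paste(CS_TAXA, collapse = ", ")), "domain")
  paste0(species_code, index, cs_length_class(length_bp),
         cs_conservation_class(conservation_pct),
         paste(CS_TAXA[CS_TAXA %in% taxa], collapse = ""))
}

#' Parse a conserved-sequence name
#'
#' The name encodes classes, not exact values, so the parse reports the
#' class intervals rather than fabricating point values.
#'
#' @param name A CS name such as `"Acar1000l1SMB"`.
#' @return List with `species_code`, `index`, `length_class`,
#'   `length_range` (bp; upper bound `Inf` for class `l`),
#'   `conservation_class`, `conservation_range` (percent), `taxa`.
#' @examples
#' cs_parse("Acar1000l1SMB")
#' @export
cs_parse <- function(name) {
  agnc_assert(is_string(name), "name must be a single string", "grammar")
  m <- regmatches(name,
                  regexec("^(A[a-z]{3})([0-9]+)([sml])([123])([SMBG]+)$",
                          name))[[1]]
  agnc_assert(length(m) == 6L,
              sprintf("'%s' is not a valid CS name (expect <Code><index><s|m|l><1|2|3><taxa S,M,B,G>)",
                      name), "grammar")
  taxa <- strsplit(m[6L], "")[[1]]
  agnc_assert(!anyDuplicated(taxa) &&
                identical(taxa, CS_TAXA[CS_TAXA %in% taxa]),
              sprintf("taxon letters in '%s' must be unique and in canonical order S,M,B,G",
                      name), "grammar")
  length_range <- switch(m[4L], s = c(1, 99), m = c(100, 499),
                         l = c(500, Inf))
  conservation_range <- switch(m[5L], "1" = c(95, 100), "2" = c(90, 94),
                               "3" = c(85, 89))
  list(species_code = m[2L], index = as.integer(m[3L]),
       length_class = m[4L], length_range = length_range,
       conservation_class = as.integer(m[5L]),
       conservation_range = conservation_range, taxa = taxa)
}

#' Name a short tandem repeat
#'
#' @param species_code Four-character species code of the organism of
#'   origin.
#' @param index Unique 1-indexed STR identification number.
#' @return `<code>_str_<index>`.
#' @examples
#' str_name("Acar", 8)  # "Acar_str_8"
#' @export
str_name <- function(species_code, index) {
  chk <- validate_code(species_code)
  agnc_assert(chk$ok, sprintf("invalid species code '%s': %s",
                              as.character(species_code)[1],
                              paste(chk$findings, collapse = "; ")),
              "code_format")
  agnc_assert(is_count(index, 1L), "index must be a positive integer >= 1",
              "domain")
  paste0(species_code, "_str_", format(index, scientific = FALSE))
}

#' Parse an STR name
#'
#' @param name A name like `"Acar_str_8"`.
#' @return List with `species_code` and `index`.
#' @export
str_parse <- function(name) {
  agnc_assert(is_string(name), "name must be a single string", "grammar")
  m <- regmatches(name, regexec("^(A[a-z]{3})_str_([0-9]+)$", name))[[1]]
  agnc_assert(length(m) == 3L && !startsWith(m[3L], "0"),
              sprintf("'%s' is not a valid STR name (expect <Code>_str_<index>)",
                      name), "grammar")
  list(species_code = m[2L], index = as.integer(m[3L]))
}

#' Name a transposable-element family
#'
#' @param lineage Superfamily or (preferred, where known) clade token,
#'   e.g. `"Helitron"`, `"hAT"`, `"hobo"`. No dash or underscore.
#' @param family_id Positive integer family number.
#' @param species_code Four-character species code.
#' @param nonautonomous_id Positive integer for a non-autonomous family
#'   amplified by the autonomous `family_id`, or `NULL`.
#' @param horizontal `TRUE` marks a horizontally transferred family
#'   (`HT` prefix on the number).
#' @return The TE name string.
#' @examples
#' te_name("Helitron", 1, "Acar")                        # "Helitron-1_Acar"
#' te_name("Helitron", 1, "Acar", nonautonomous_id = 1)  # "Helitron-1N1_Acar"
#' te_name("hAT", 1, "Acar", horizontal = TRUE)          # "hAT-HT1_Acar"
#' @export
te_name <- function(lineage, family_id, species_code,
                    nonautonomous_id = NULL, horizontal = FALSE) {
  agnc_assert(is_string(lineage) && grepl("^[A-Za-z][A-Za-z0-9]*$", lineage),
              "lineage must be alphanumeric with no dash/underscore",
              "grammar")
  agnc_assert(is_count(family_id, 1L),
              "family_id must be a positive integer", "domain")
  chk <- validate_code(species_code)
  agnc_assert(chk$ok, sprintf("invalid species code '%s': %s",
                              as.character(species_code)[1],
                              paste(chk$findings, collapse = "; ")),
              "code_format")
  agnc_assert(is.logical(horizontal) && length(horizontal) == 1L &&
                !is.na(horizontal), "horizontal must be TRUE or FALSE",
              "domain")
  agnc_assert(is.null(nonautonomous_id) || is_count(nonautonomous_id, 1L),
              "nonautonomous_id must be NULL or a positive integer",
              "domain")
  paste0(lineage, "-", if (horizontal) "HT" else "", family_id,
         if (!is.null(nonautonomous_id)) paste0("N", nonautonomous_id)
         else "",
         "_", species_code)
}

#' Parse a transposable-element name
#'
#' @param name A TE name such as `"Helitron-1N1_Acar"`.
#' @return List with `lineage`, `family_id`, `nonautonomous_id` (`NA` when
#'   autonomous), `horizontal`, `species_code`.
#' @examples
#' te_parse("hobo-1_Acar")
#' @export
te_parse <- function(name) {
  agnc_assert(is_string(name), "name must be a single string", "grammar")
  m <- regmatches(name, regexec(
    "^([A-Za-z][A-Za-z0-9]*)-(HT)?([0-9]+)(N([0-9]+))?_(A[a-z]{3})$",
    name))[[1]]
  agnc_assert(length(m) == 7L,
              sprintf("'%s' is not a valid TE name (expect <lineage>-[HT]<family>[N<id>]_<Code>)",
                      name), "grammar")
  list(lineage = m[2L],
       family_id = as.integer(m[4L]),
       nonautonomous_id = if (nzchar(m[6L])) as.integer(m[6L])
                          else NA_integer_,
       horizontal = m[3L] == "HT",
       species_code = m[7L])
}
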