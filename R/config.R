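#' Tool configuration
#'
#' A validated bundle of the knobs the toolkit exposes: vocabulary
#' overrides (clade ladder, expression codes), the synteny gap tolerance,
#' STR scanner bounds, registry file paths, output format, and the fixture
#' seed. Loadable from YAML; unknown keys are rejected rather than
#' silently ignored.
#'
#' @param clade_ladder Span vocabulary, most-nested first.
#' @param expression_codes Expression-token vocabulary.
#' @param synteny_max_gap Intervening reference genes tolerated between
#'   consecutive orthologs (default 0: strictly sequential).
#' @param str_min_unit,str_max_unit,str_min_copies STR scanner bounds.
#' @param registry_path Species-registry TSV override (`NULL` = packaged
#'   canonical registry).
#' @param output_format `"tsv"` or `"json"`.
#' @param seed Fixture seed.
#' @return A validated list of class `agnc_config`.
#' @export
agnc_config <- function(clade_ladder = DEFAULT_CLADE_LADDER,
                        expression_codes = DEFAULT_EXPRESSION_CODES,
                        synteny_max_gap = 0L,
                        str_min_unit = 1L, str_max_unit = 6L,
                        str_min_copies = 3,
                        registry_path = NULL,
                        output_format = c("tsv", "json"),
                        seed = 1L) {
  output_format <- match.arg(output_format)
  agnc_assert(is.character(clade_ladder) && length(clade_ladder) >= 1L &&
                !anyDuplicated(clade_ladder),
              "clade_ladder must be unique span tokens", "config")
  agnc_assert(is.character(expression_codes) &&
                length(expression_codes) >= 1L &&
                !anyDuplicated(expression_codes),
              "expression_codes must be unique tokens", "config")
  agnc_assert(is_count(synteny_max_gap),
              "synteny_max_gap must be a non-negative integer", "config")
  agnc_assert(is_count(str_min_unit, 1L) && is_count(str_max_unit, 1L) &&
                str_min_unit <= str_max_unit,
              "need 1 <= str_min_unit <= str_max_unit", "config")
  agnc_assert(is.numeric(str_min_copies) && str_min_copies >= 2,
              "str_min_copies must be >= 2", "config")
  agnc_assert(is.null(registry_path) || is_string(registry_path),
              "registry_path must be NULL or a path", "config")
  agnc_assert(is_count(seed), "seed must be a non-negative integer",
              "config")
  structure(list(clade_ladder = clade_ladder,
                 expression_codes = expression_codes,
                 synteny_max_gap = as.integer(synteny_max_gap),
                 str_min_unit = as.integer(str_min_unit),
                 str_max_unit = as.integer(str_max_unit),
                 str_min_copies = str_min_copies,
                 registry_path = registry_path,
                 output_format = output_format,
                 seed = as.integer(seed)),
            class = "agnc_config")
}

#' Load configuration from a YAML file
#'
#' @param path YAML file whose keys are the arguments of [agnc_config()].
#' @return An `agnc_config`.
#' @export
load_config <- function(path) {
  agnc_assert(file.exists(path), sprintf("config file '%s' not found", path),
              "config")
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(agnc_config))
  unknown <- setdiff(names(vals), known)
  agnc_assert(length(unknown) == 0L,
              sprintf("unknown config key(s): %s (valid: %s)",
                      paste(unknown, collapse = ", "),
                      paste(known, collapse = ", ")), "config")
  do.call(agnc_config, vals)
}
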