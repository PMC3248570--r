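#' Build per-gene ECC strings from annotation tables
#'
#' Joins the per-gene inputs — alignment presence across the comparison
#' taxa, sequence-identity metrics, copy counts, transcript evidence flags,
#' and synteny flank contexts — and serializes one ECC string per gene.
#' Genes missing from any input table are reported in the `excluded`
#' attribute (with the reason), never silently dropped.
#'
#' @param genes Data frame with columns `gene_id`, `protein_metric`,
#'   `nucleotide_metric`, and optionally `expression_code` (default
#'   `"ND"`) and `identity_mode` (default `"percent_identity"`).
#' @param evidence Data frame `transcript_id`, `est`, `protein`,
#'   `prediction`, `cdna` (one transcript per gene, keyed by gene id; see
#'   [score_evidence_table()]).
#' @param orthologs Data frame `gene_id`, `copies_query`,
#'   `copies_reference`.
#' @param presence Data frame with `gene_id` plus one logical column per
#'   comparison taxon (`mammals`, `birds`, `non_avian_reptiles`,
#'   `amphibians`, `teleosts`, `non_vertebrate_chordates`).
#' @param contexts Named list of [flank_context()] objects keyed by gene
#'   id, or a data frame `gene_id`, `synteny_up`, `synteny_down` with
#'   precomputed counts.
#' @param ladder,expression_codes Vocabulary overrides.
#' @return Data frame `gene_id`, `ecc`; attribute `excluded` is a data
#'   frame `gene_id`, `reason` for genes that could not be coded.
#' @examples
#' \donttest{
#' genes <- data.frame(gene_id = "gene2", protein_metric = 80,
#'                     nucleotide_metric = 55, expression_code = "TS")
#' }
#' @export
ecc_pipeline <- function(genes, evidence, orthologs, presence, contexts,
                         ladder = DEFAULT_CLADE_LADDER,
                         expression_codes = DEFAULT_EXPRESSION_CODES) {
  agnc_assert(is.data.frame(genes) &&
                all(c("gene_id", "protein_metric", "nucleotide_metric")
                    %in% names(genes)),
              "genes needs columns gene_id, protein_metric, nucleotide_metric",
              "malformed_input")
  if (is.null(genes$expression_code)) genes$expression_code <- "ND"
  if (is.null(genes$identity_mode))
    genes$identity_mode <- "percent_identity"
  scores <- score_evidence_table(evidence)
  agnc_assert(is.data.frame(orthologs) &&
                all(c("gene_id", "copies_query", "copies_reference")
                    %in% names(orthologs)),
              "orthologs needs gene_id, copies_query, copies_reference",
              "malformed_input")
  taxa <- names(COMPARISON_TAXA)
  agnc_assert(is.data.frame(presence) &&
                all(c("gene_id", taxa) %in% names(presence)),
              sprintf("presence needs gene_id plus taxon columns: %s",
                      paste(taxa, collapse = ", ")), "malformed_input")
  syn_table <- NULL
  if (is.data.frame(contexts)) {
    agnc_assert(all(c("gene_id", "synteny_up", "synteny_down")
                    %in% names(contexts)),
                "precomputed synteny table needs gene_id, synteny_up, synteny_down",
                "malformed_input")
    syn_table <- contexts
  }

  out_id <- character(); out_ecc <- character()
  ex_id <- character(); ex_reason <- character()
  exclude <- function(id, why) {
    ex_id <<- c(ex_id, id); ex_reason <<- c(ex_reason, why)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    sc <- scores$score[match(g, scores$transcript_id)]
    if (is.na(sc)) { exclude(g, "no evidence record"); next }
    oi <- match(g, orthologs$gene_id)
    if (is.na(oi)) { exclude(g, "no ortholog record"); next }
    pi <- match(g, presence$gene_id)
    if (is.na(pi)) { exclude(g, "no alignment-presence record"); next }
    pres <- unlist(presence[pi, taxa])
    span <- assign_span(stats::setNames(as.logical(pres), taxa),
                        ladder = ladder)
    if (is.na(span)) { exclude(g, "no detectable homolog in any taxon"); next }
    if (!is.null(syn_table)) {
      si <- match(g, syn_table$gene_id)
      if (is.na(si)) { exclude(g, "no synteny record"); next }
      syn <- c(up = syn_table$synteny_up[si],
               down = syn_table$synteny_down[si])
    } else {
      ctx <- contexts[[g]]
      if (is.null(ctx)) { exclude(g, "no synteny context"); next }
      syn <- ecc_synteny_fields(ctx)
    }
    rec <- tryCatch(
      ecc_record(gene_id = g, taxonomic_span = span,
                 protein_metric = genes$protein_metric[i],
                 nucleotide_metric = genes$nucleotide_metric[i],
                 copies_query = orthologs$copies_query[oi],
                 copies_reference = orthologs$copies_reference[oi],
                 evidence_score = sc,
                 synteny_up = syn[["up"]], synteny_down = syn[["down"]],
                 expression_code = genes$expression_code[i],
                 identity_mode = genes$identity_mode[i],
                 ladder = ladder, expression_codes = expression_codes),
      agnc_error = function(e)
        agnc_stop(sprintf("gene '%s': %s", g, conditionMessage(e)),
                  "pipeline"))
    out_id <- c(out_id, g)
    out_ecc <- c(out_ecc, ecc_serialize(rec))
  }
  res <- data.frame(gene_id = out_id, ecc = out_ecc,
                    stringsAsFactors = FALSE)
  attr(res, "excluded") <- data.frame(gene_id = ex_id, reason = ex_reason,
                                      stringsAsFactors = FALSE)
  if (length(ex_id))
    warning(sprintf("%d gene(s) excluded from ECC output: %s",
                    length(ex_id),
                    paste0(ex_id, " (", ex_reason, ")", collapse = ", ")),
            call. = FALSE)
  res
}

#' Serialize a batch ECC table
#'
#' Row-wise wrapper over [ecc_record()] + [ecc_serialize()] for tables
#' that already carry every ECC field (one gene per row).
#'
#' @param table Data frame with columns `gene_id`, `taxonomic_span`,
#'   `protein_metric`, `nucleotide_metric`, `copies_query`,
#'   `copies_reference`, `evidence_score`, `synteny_up`, `synteny_down`,
#'   `expression_code`, and optionally `identity_mode`.
#' @return Character vector of ECC strings, one per row.
#' @export
ecc_build_table <- function(table) {
  need <- c("gene_id", "taxonomic_span", "protein_metric",
            "nucleotide_metric", "copies_query", "copies_reference",
            "evidence_score", "synteny_up", "synteny_down",
            "expression_code")
  agnc_assert(is.data.frame(table) && all(need %in% names(table)),
              sprintf("ECC table needs columns: %s",
                      paste(need, collapse = ", ")), "malformed_input")
  if (is.null(table$identity_mode))
    table$identity_mode <- "percent_identity"
  vapply(seq_len(nrow(table)), function(i) {
    ecc_serialize(ecc_record(
      gene_id = table$gene_id[i],
      taxonomic_span = table$taxonomic_span[i],
      protein_metric = table$protein_metric[i],
      nucleotide_metric = table$nucleotide_metric[i],
      copies_query = if (identical(table$copies_query[i], "n")) "n"
                     else as.integer(table$copies_query[i]),
      copies_reference = if (identical(table$copies_reference[i], "n")) "n"
                         else as.integer(table$copies_reference[i]),
      evidence_score = table$evidence_score[i],
      synteny_up = table$synteny_up[i],
      synteny_down = table$synteny_down[i],
      expression_code = table$expression_code[i],
      identity_mode = table$identity_mode[i]))
  }, character(1))
}
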