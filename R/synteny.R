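#' Synteny flank conservation
#'
#' Orthology can be corroborated by conserved gene order: minimally, by the
#' presence of at least two orthologous genes, in sequential order, on
#' either the 5' or the 3' flank of the focal gene (the reference genome
#' being chicken by default, though any reference order is accepted).
#' Confidence grows with additional conserved genes on one flank or with
#' conservation on both flanks. The counting walks each flank nearest-first
#' and measures the longest prefix whose genes all map to reference
#' orthologs occupying strictly monotonic, consecutive rank positions in
#' the reference order. Gene orientation is ignored; only order matters.
#'
#' @name synteny
NULL

#' Construct a flank context for one focal gene
#'
#' @param focal_gene Identifier of the gene under evaluation.
#' @param upstream_genes 5' flank gene identifiers, nearest-first; no
#'   duplicates, must not contain the focal gene.
#' @param downstream_genes 3' flank, same conventions.
#' @param ortholog_map Named character vector: query gene -> reference gene.
#'   Genes absent from the map have no recognized ortholog.
#' @param reference_order Named numeric vector: reference gene -> position
#'   on its reference sequence. Positions must be unique; they are reduced
#'   to ordinal ranks internally, so raw coordinates are fine.
#' @return An object of class `flank_context`.
#' @export
flank_context <- function(focal_gene, upstream_genes, downstream_genes,
                          ortholog_map, reference_order) {
  agnc_assert(is_string(focal_gene), "focal_gene must be a single id",
              "malformed_input")
  chk_flank <- function(x, what) {
    if (is.null(x)) x <- character()
    agnc_assert(is.character(x) && !anyNA(x),
                sprintf("%s must be a character vector", what),
                "malformed_input")
    agnc_assert(!anyDuplicated(x),
                sprintf("%s contains duplicate genes", what),
                "malformed_input")
    agnc_assert(!focal_gene %in% x,
                sprintf("focal gene must not appear in %s", what),
                "malformed_input")
    x
  }
  upstream_genes <- chk_flank(upstream_genes, "upstream_genes")
  downstream_genes <- chk_flank(downstream_genes, "downstream_genes")
  agnc_assert(is.character(ortholog_map) &&
                (length(ortholog_map) == 0L || !is.null(names(ortholog_map))),
              "ortholog_map must be a named character vector", "malformed_input")
  agnc_assert(is.numeric(reference_order) &&
                (length(reference_order) == 0L ||
                   !is.null(names(reference_order))),
              "reference_order must be a named numeric vector",
              "malformed_input")
  agnc_assert(!anyDuplicated(reference_order),
              "reference positions must be unique (ties in raw coordinates)",
              "malformed_input")
  # raw coordinates -> ordinal ranks among the reference genes
  ranks <- rank(reference_order)
  structure(list(focal_gene = focal_gene,
                 upstream_genes = upstream_genes,
                 downstream_genes = downstream_genes,
                 ortholog_map = ortholog_map,
                 reference_rank = ranks),
            class = "flank_context")
}

#' @export
print.flank_context <- function(x, ...) {
  cat(sprintf("Flank context for '%s': %d upstream, %d downstream, %d ortholog pair(s)\n",
              x$focal_gene, length(x$upstream_genes),
              length(x$downstream_genes), length(x$ortholog_map)))
  invisible(x)
}

#' Conserved-prefix length of one flank
#'
#' Walks the chosen flank nearest-first and returns the length of the
#' longest prefix in which (a) every gene has a reference ortholog and
#' (b) the orthologs' reference ranks are strictly monotonic — increasing
#' or decreasing, the direction set by the first step — with consecutive
#' steps no larger than `1 + max_gap`. The first unmapped gene or broken
#' step terminates the walk. A single mapped nearest gene counts 1.
#'
#' @param context A [flank_context()].
#' @param flank `"up"` (5') or `"down"` (3').
#' @param max_gap Number of intervening reference genes tolerated between
#'   consecutive orthologs; 0 (default) demands strictly sequential order.
#' @return Non-negative integer count.
#' @examples
#' ctx <- flank_context("g0", c("g1", "g2", "g3"), character(),
#'                      c(g1 = "r1", g2 = "r2", g3 = "r3"),
#'                      c(r1 = 10, r2 = 11, r3 = 12))
#' flank_conservation(ctx, "up")  # 3
#' @export
flank_conservation <- function(context, flank = c("up", "down"),
                               max_gap = 0L) {
  agnc_assert(inherits(context, "flank_context"),
              "context must be a flank_context", "malformed_input")
  flank <- match.arg(flank)
  agnc_assert(is_count(max_gap), "max_gap must be a non-negative integer",
              "malformed_input")
  genes <- if (flank == "up") context$upstream_genes
           else context$downstream_genes
  max_step <- 1L + as.integer(max_gap)
  count <- 0L
  prev_rank <- NA_real_
  direction <- 0L
  for (g in genes) {
    ref <- context$ortholog_map[g]
    if (is.na(ref) || !ref %in% names(context$reference_rank)) break
    r <- unname(context$reference_rank[[ref]])
    if (count >= 1L) {
      step <- r - prev_rank
      if (step == 0) break
      if (direction == 0L) direction <- sign(step)
      if (sign(step) != direction || abs(step) > max_step) break
    }
    count <- count + 1L
    prev_rank <- r
  }
  count
}

#' Minimal orthology-recognition rule
#'
#' Orthology is minimally recognized when at least 2 orthologous genes, in
#' sequential order, flank the focal gene on a single side (5' or 3').
#'
#' @inheritParams flank_conservation
#' @return List with `met` (logical), `up`, and `down` counts.
#' @examples
#' ctx <- flank_context("g0", c("g1", "g2"), character(),
#'                      c(g1 = "r1", g2 = "r2"), c(r1 = 1, r2 = 2))
#' minimal_orthology_met(ctx)$met  # TRUE
#' @export
minimal_orthology_met <- function(context, max_gap = 0L) {
  up <- flank_conservation(context, "up", max_gap)
  down <- flank_conservation(context, "down", max_gap)
  list(met = up >= 2L || down >= 2L, up = up, down = down)
}

#' Synteny counts for the ECC
#'
#' @inheritParams flank_conservation
#' @return Named integer vector `c(up = ..., down = ...)`, the pair that
#'   fills the ECC synteny field.
#' @export
ecc_synteny_fields <- function(context, max_gap = 0L) {
  c(up = flank_conservation(context, "up", max_gap),
    down = flank_conservation(context, "down", max_gap))
}

#' Read a gene-order table
#'
#' Accepts either a TSV with columns `gene_id`, `seq_id`, `position`
#' (raw coordinates; reduced to ranks downstream) or a BED file (0-based
#' half-open; the `name` column carries the gene id, `chromStart` the
#' position).
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return Named numeric vector gene -> position, with a `seq_id`
#'   attribute; input restricted to a single reference sequence per call.
#' @export
read_gene_order <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "seq_id", "position")
    agnc_assert(all(need %in% names(tab)),
                sprintf("gene-order TSV needs columns: %s",
                        paste(need, collapse = ", ")), "malformed_input")
  } else {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    agnc_assert(ncol(bed) >= 4L,
                "BED input needs at least 4 columns (chrom, start, end, name)",
                "malformed_input")
    tab <- data.frame(gene_id = bed[[4L]], seq_id = bed[[1L]],
                      position = bed[[2L]], stringsAsFactors = FALSE)
  }
  agnc_assert(length(unique(tab$seq_id)) <= 1L,
              "gene-order input must cover a single reference sequence",
              "malformed_input")
  agnc_assert(!anyDuplicated(tab$gene_id),
              "duplicate gene ids in gene-order input", "malformed_input")
  agnc_assert(!anyDuplicated(tab$position),
              "tied positions in gene-order input", "malformed_input")
  out <- stats::setNames(as.numeric(tab$position), tab$gene_id)
  attr(out, "seq_id") <- if (nrow(tab)) tab$seq_id[1L] else NA_character_
  out
}

#' Read an ortholog map
#'
#' @param path TSV with columns `query_gene`, `reference_gene`.
#' @return Named character vector query -> reference.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_gene", "reference_gene")
  agnc_assert(all(need %in% names(tab)),
              sprintf("ortholog map needs columns: %s",
                      paste(need, collapse = ", ")), "malformed_input")
  agnc_assert(!anyDuplicated(tab$query_gene),
              "duplicate query genes in ortholog map", "malformed_input")
  stats::setNames(tab$reference_gene, tab$query_gene)
}

#' Build a flank context from gene-order tables
#'
#' Slices the query order around the focal gene into nearest-first flanks
#' and pairs it with the reference order and ortholog map.
#'
#' @param focal_gene Focal gene id, present in `query_order`.
#' @param query_order Named numeric vector gene -> position for the query
#'   genome (see [read_gene_order()]).
#' @param reference_order Same for the reference genome.
#' @param ortholog_map Named character vector query -> reference.
#' @param flank_size Maximum genes kept per flank.
#' @return A [flank_context()].
#' @export
context_from_orders <- function(focal_gene, query_order, reference_order,
                                ortholog_map, flank_size = 10L) {
  agnc_assert(focal_gene %in% names(query_order),
              sprintf("focal gene '%s' absent from query order", focal_gene),
              "malformed_input")
  ord <- names(sort(query_order))
  i <- match(focal_gene, ord)
  up <- rev(ord[seq_len(i - 1L)])           # nearest-first toward 5'
  down <- ord[seq_along(ord) > i]           # nearest-first toward 3'
  flank_context(focal_gene,
                utils::head(up, flank_size),
                utils::head(down, flank_size),
                ortholog_map, reference_order)
}
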