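# Independent brute-force oracles. These deliberately re-derive the
# quantities from their definitions (exhaustive prefix checks, substring
# comparisons) rather than reusing any package internals.

# Longest nearest-first flank prefix whose genes are all mapped and whose
# reference ranks are strictly monotone with steps <= 1 + max_gap:
# test every prefix length explicitly and keep the largest valid one.
oracle_flank <- function(genes, ortholog_map, reference_order,
                         max_gap = 0L) {
  ranks_all <- rank(reference_order)
  best <- 0L
  for (k in seq_along(genes)) {
    refs <- unname(ortholog_map[genes[seq_len(k)]])
    if (anyNA(refs) || !all(refs %in% names(ranks_all))) next
    r <- unname(ranks_all[refs])
    ok <- if (k == 1L) TRUE else {
      d <- diff(r)
      all(d >= 1 & d <= 1 + max_gap) || all(d <= -1 & d >= -(1 + max_gap))
    }
    if (ok) best <- max(best, k)
  }
  best
}

# Random flank context: genes mapped to reference genes with probability
# p_mapped; reference positions drawn without replacement so runs of
# consecutive ranks arise by chance.
random_context <- function(max_flank = 12L, p_mapped = 0.7) {
  n_up <- sample(0:max_flank, 1L)
  n_down <- sample(0:max_flank, 1L)
  up <- if (n_up) paste0("u", seq_len(n_up)) else character()
  down <- if (n_down) paste0("d", seq_len(n_down)) else character()
  genes <- c(up, down)
  n_ref <- max(4L, length(genes) + sample(0:4, 1L))
  refs <- paste0("r", seq_len(n_ref))
  ref_pos <- setNames(sample(1000L, n_ref), refs)
  mapped <- genes[runif(length(genes)) < p_mapped]
  # small reference pool so several query genes can hit adjacent ranks
  ortho <- setNames(sample(refs, length(mapped), replace = TRUE), mapped)
  list(ctx = flank_context("focal", up, down, ortho, ref_pos),
       up = up, down = down, ortho = ortho, ref_pos = ref_pos)
}

# Exhaustive perfect-tandem-repeat enumerator built on substring
# comparison, with the same resolution rule (longest, then leftmost, then
# smallest unit) applied by explicit sorting.
oracle_scan <- function(seq, min_unit = 1L, max_unit = 6L,
                        min_copies = 3) {
  seq <- toupper(seq)
  n <- nchar(seq)
  cand <- data.frame(start = integer(), len = integer(), u = integer(),
                     copies = integer())
  for (u in seq.int(min_unit, max_unit)) {
    if (2L * u > n) break
    for (i in seq_len(n - 2L * u + 1L)) {
      unit <- substring(seq, i, i + u - 1L)
      copies <- 1L
      while (i + (copies + 1L) * u - 1L <= n &&
             substring(seq, i + copies * u,
                       i + (copies + 1L) * u - 1L) == unit)
        copies <- copies + 1L
      if (copies >= min_copies)
        cand <- rbind(cand, data.frame(start = i, len = copies * u,
                                       u = u, copies = copies))
    }
  }
  if (!nrow(cand)) return(cand)
  cand <- cand[order(-cand$len, cand$start, cand$u), ]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- seq.int(cand$start[i], length.out = cand$len[i])
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, ]
  cand[order(cand$start), ]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Random valid ECC record with canonical copy markers and one-decimal
# metrics (exactly representable through the serialized decimal string).
random_ecc_record <- function() {
  mode <- sample(c("percent_identity", "dn_ds"), 1L)
  ecc_record(
    gene_id = paste0("g", sample(9999L, 1L)),
    taxonomic_span = sample(DEFAULT_CLADE_LADDER, 1L),
    protein_metric = round(runif(1) * if (mode == "dn_ds") 3 else 100, 1L),
    nucleotide_metric = round(runif(1) * if (mode == "dn_ds") 3 else 100, 1L),
    copies_query = sample(list(1L, "n"), 1L)[[1L]],
    copies_reference = sample(list(1L, "n"), 1L)[[1L]],
    evidence_score = sample(0:15, 1L),
    synteny_up = sample(0:9, 1L),
    synteny_down = sample(0:9, 1L),
    expression_code = sample(DEFAULT_EXPRESSION_CODES, 1L),
    identity_mode = mode)
}
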