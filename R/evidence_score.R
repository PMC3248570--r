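#' Transcript evidence score
#'
#' Each annotated transcript receives an additive confidence score over four
#' independent evidence categories, with power-of-two weights so the score
#' doubles as a bit field:
#'
#' * 1 point — one or more aligned ESTs align to the transcript
#' * 2 points — an annotated exon intersects a region of aligned protein
#'   similarity (self-similarity excluded)
#' * 4 points — some gene prediction is fully consistent with the transcript
#' * 8 points — one or more aligned cDNAs are fully consistent
#'
#' The flags are caller-supplied booleans; deciding "fully consistent" from
#' raw alignments is upstream work. The full range is 0-15. Scores above 7
#' no longer fit a single octal digit; [score_evidence_table()] marks such
#' rows rather than clamping, since clamping would destroy information.
#'
#' @name evidence-score
NULL

EVIDENCE_WEIGHTS <- c(est_aligned = 1L, protein_overlap = 2L,
                      prediction_consistent = 4L, cdna_consistent = 8L)

#' Evidence set constructor
#'
#' @param est_aligned At least one EST aligns to the transcript.
#' @param protein_overlap An annotated exon intersects aligned protein
#'   similarity (excluding self-similarity).
#' @param prediction_consistent Some gene prediction is fully consistent
#'   with the annotated transcript.
#' @param cdna_consistent At least one aligned cDNA is fully consistent.
#' @return A named logical vector of the four flags.
#' @export
evidence_set <- function(est_aligned = FALSE, protein_overlap = FALSE,
                         prediction_consistent = FALSE,
                         cdna_consistent = FALSE) {
  flags <- c(est_aligned = est_aligned, protein_overlap = protein_overlap,
             prediction_consistent = prediction_consistent,
             cdna_consistent = cdna_consistent)
  agnc_assert(is.logical(flags) && !anyNA(flags),
              "all four evidence flags must be TRUE or FALSE (no NA)",
              "domain")
  flags
}

#' Score a transcript's evidence
#'
#' @param evidence A logical vector as returned by [evidence_set()], or the
#'   four flags given individually via `...`.
#' @param ... Passed to [evidence_set()] when `evidence` is missing.
#' @return Integer score in 0..15.
#' @examples
#' evidence_score(evidence_set(est_aligned = TRUE,
#'                             prediction_consistent = TRUE))  # 5
#' evidence_score(evidence_set(cdna_consistent = TRUE))        # 8
#' @export
evidence_score <- function(evidence = evidence_set(...), ...) {
  evidence <- evidence_set(evidence["est_aligned"],
                           evidence["protein_overlap"],
                           evidence["prediction_consistent"],
                           evidence["cdna_consistent"])
  sum(EVIDENCE_WEIGHTS[evidence])
}

#' Recover the evidence flags from a score
#'
#' The power-of-two weighting makes every score in 0..15 a unique
#' combination of flags, so the score decomposes exactly.
#'
#' @param score Integer in 0..15.
#' @return A named logical vector (see [evidence_set()]).
#' @examples
#' evidence_decompose(5)  # EST + gene prediction
#' @export
evidence_decompose <- function(score) {
  agnc_assert(is_count(score) && score <= 15L,
              sprintf("score must be an integer in 0..15 (got %s)",
                      as.character(score)[1]), "domain")
  flags <- bitwAnd(as.integer(score), EVIDENCE_WEIGHTS) > 0L
  names(flags) <- names(EVIDENCE_WEIGHTS)
  flags
}

#' Score a batch evidence table
#'
#' @param table Data frame with columns `transcript_id`, `est`, `protein`,
#'   `prediction`, `cdna` (logical or 0/1).
#' @return Data frame `transcript_id`, `score`, `octal_overflow` (TRUE when
#'   the score exceeds a single octal digit, i.e. > 7).
#' @export
score_evidence_table <- function(table) {
  need <- c("transcript_id", "est", "protein", "prediction", "cdna")
  agnc_assert(is.data.frame(table) && all(need %in% names(table)),
              sprintf("evidence table must have columns: %s",
                      paste(need, collapse = ", ")), "malformed_input")
  flag <- function(col) {
    v <- table[[col]]
    if (is.numeric(v)) v <- v != 0
    agnc_assert(is.logical(v) && !anyNA(v),
                sprintf("column '%s' must be logical or 0/1 with no NA", col),
                "malformed_input")
    v
  }
  score <- 1L * flag("est") + 2L * flag("protein") +
    4L * flag("prediction") + 8L * flag("cdna")
  data.frame(transcript_id = table$transcript_id, score = score,
             octal_overflow = score > 7L, stringsAsFactors = FALSE)
}
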