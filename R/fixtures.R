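#' Seed-deterministic fixture generators
#'
#' Synthetic inputs for exercising every module without external data. Both
#' generators restore the caller's RNG state, so they are bit-identical
#' across reruns with the same seed and never perturb the surrounding
#' session.
#'
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a species list that stresses collision resolution
#'
#' Draws `n` random epithets (5-10 lowercase letters) and forces
#' approximately `collision_rate * n` of them to share their first three
#' letters with another name in the list, so that code assignment must fall
#' back past the default third letter.
#'
#' @param n Number of species (>= 1).
#' @param collision_rate Fraction of names sharing a 3-letter prefix with
#'   another name, in 0..1.
#' @param seed Integer seed; same seed, same output.
#' @return Data frame `epithet`, `precedence_rank` (0-based, input order).
#' @export
make_species_fixture <- function(n, collision_rate = 0.3, seed = 1L) {
  agnc_assert(is_count(n, 1L), "n must be a positive integer", "domain")
  agnc_assert(is.numeric(collision_rate) && length(collision_rate) == 1L &&
                collision_rate >= 0 && collision_rate <= 1,
              "collision_rate must be in 0..1", "domain")
  with_seed(seed, {
    rand_word <- function(len) paste(sample(letters, len, replace = TRUE),
                                     collapse = "")
    n_coll <- round(collision_rate * n)
    eps <- character(n)
    taken <- character(n)
    default_code <- function(w) paste0("A", substr(w, 1L, 3L))
    for (i in seq_len(n)) {
      w <- NULL
      if (i > n - n_coll && i > 1L) {
        # force a shared 3-letter prefix with an earlier name, but only
        # where the fallback scan can still find a free letter (the point
        # is to exercise resolution, not to manufacture dead ends)
        for (attempt in 1:25) {
          donor <- eps[sample.int(i - 1L, 1L)]
          cand <- paste0(substr(donor, 1L, 3L), rand_word(sample(3:7, 1L)))
          if (cand %in% eps[seq_len(i - 1L)]) next
          code <- tryCatch(generate_code(cand, taken[seq_len(i - 1L)]),
                           agnc_error = function(e) NULL)
          if (!is.null(code)) { w <- cand; break }
        }
      }
      if (is.null(w)) {
        repeat {
          cand <- rand_word(sample(5:10, 1L))
          # non-collision names must resolve at the first try
          if (!cand %in% eps[seq_len(i - 1L)] &&
              !default_code(cand) %in% taken[seq_len(i - 1L)]) {
            w <- cand
            code <- default_code(cand)
            break
          }
        }
      }
      eps[i] <- w
      taken[i] <- code
    }
    data.frame(epithet = eps, precedence_rank = seq_len(n) - 1L,
               stringsAsFactors = FALSE)
  })
}

#' Generate a flank context with known conservation counts
#'
#' Builds a [flank_context()] whose flanks carry exactly `up_conserved`
#' and `down_conserved` sequentially ordered reference orthologs
#' nearest-first, followed by a break (an unmapped gene or a reference
#' rank gap, chosen at random) and then arbitrarily placed genes out to
#' `flank_len`.
#'
#' @param up_conserved,down_conserved Desired conserved-prefix lengths
#'   (each <= `flank_len`).
#' @param flank_len Genes per flank.
#' @param seed Integer seed.
#' @return A [flank_context()] for focal gene `"focal"`.
#' @export
make_synteny_fixture <- function(up_conserved, down_conserved,
                                 flank_len = 8L, seed = 1L) {
  agnc_assert(is_count(up_conserved) && is_count(down_conserved) &&
                is_count(flank_len, 1L),
              "counts must be non-negative integers", "domain")
  agnc_assert(up_conserved <= flank_len && down_conserved <= flank_len,
              "conserved counts must not exceed flank_len", "domain")
  with_seed(seed, {
    ortho <- character(0)
    ref_pos <- numeric(0)
    next_rank <- 0L
    build_flank <- function(side, conserved) {
      genes <- paste0(side, seq_len(flank_len))
      dir <- sample(c(-1L, 1L), 1L)       # reference strand direction
      base <- next_rank + 100L * match(side, c("u", "d"))
      ranks <- base + dir * seq_len(conserved)
      if (conserved > 0L) {
        refs <- paste0("ref_", side, seq_len(conserved))
        ortho[genes[seq_len(conserved)]] <<- refs
        ref_pos[refs] <<- ranks
      }
      if (conserved < flank_len) {
        # break immediately after the conserved prefix; with an empty
        # prefix the first gene must stay unmapped (any mapped gene
        # would count 1)
        brk <- genes[conserved + 1L]
        if (conserved > 0L && stats::runif(1) < 0.5) {
          # rank gap: mapped, but 3 ranks away in the same direction,
          # with unmapped reference-only genes filling the skipped ranks
          # (ranks are ordinal among reference genes, so the gap must be
          # occupied to survive rank compression)
          ref <- paste0("ref_gap_", side)
          fill <- paste0("ref_fill_", side, 1:2)
          ortho[brk] <<- ref
          ref_pos[fill] <<- ranks[conserved] + dir * (1:2)
          ref_pos[ref] <<- ranks[conserved] + dir * 3L
        }                                  # else: leave brk unmapped
        # remaining genes unmapped
      }
      genes
    }
    up <- build_flank("u", up_conserved)
    down <- build_flank("d", down_conserved)
    flank_context("focal", up, down, ortho, ref_pos)
  })
}
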