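#' Minimal STR scanner and registry
#'
#' A deliberately small detector of perfect tandem repeats, provided so STR
#' naming and registry bookkeeping can be exercised end to end; it does not
#' aim to compete with dedicated repeat finders (no mismatches, unit sizes
#' 1-6 by default, integer copy counts only).
#'
#' A candidate repeat is a run of `c >= min_copies` exact copies of a unit
#' of length `min_unit..max_unit`, extended to the largest whole number of
#' copies. Overlapping candidates are resolved longest-first, then
#' leftmost, then smallest unit (so an `AC` dinucleotide run is reported
#' once with unit `AC`, not again as `ACAC`). Accepted repeats are
#' reported leftmost-first and indexed 1, 2, ... in scan order. The unit is
#' normalized to its lexicographically minimal rotation.
#'
#' @name str-scan
NULL

min_rotation <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(unit)
  rots <- vapply(seq_len(n) - 1L, function(k)
    paste0(substring(unit, k + 1L, n), substring(unit, 1L, k)),
    character(1))
  sort(rots)[1L]
}

#' Scan a sequence for perfect tandem repeats
#'
#' @param sequence Nucleotide sequence over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive; `N` is treated as an ordinary letter).
#' @param min_unit,max_unit Repeat-unit length bounds (1..6 by default).
#' @param min_copies Minimum whole copies required (>= 2; default 3).
#' @return Data frame with columns `unit` (minimal rotation), `unit_length`,
#'   `copies`, `start`, `end` (0-based half-open), ordered leftmost-first.
#' @examples
#' scan_strs("ACACACAC", min_copies = 3)
#' @export
scan_strs <- function(sequence, min_unit = 1L, max_unit = 6L,
                      min_copies = 3) {
  agnc_assert(is_string(sequence), "sequence must be a single string",
              "sequence")
  sequence <- toupper(sequence)
  agnc_assert(grepl("^[ACGTN]*$", sequence),
              "sequence may contain only A, C, G, T, N", "sequence")
  agnc_assert(is_count(min_unit, 1L) && is_count(max_unit, 1L) &&
                min_unit <= max_unit,
              "need 1 <= min_unit <= max_unit", "domain")
  agnc_assert(is.numeric(min_copies) && length(min_copies) == 1L &&
                !is.na(min_copies) && min_copies >= 2,
              "min_copies must be >= 2", "domain")
  empty <- data.frame(unit = character(), unit_length = integer(),
                      copies = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < 2L * min_unit) return(empty)
  ch <- strsplit(sequence, "")[[1]]
  cand <- list()
  for (u in seq.int(min_unit, min(max_unit, n %/% 2L))) {
    eq <- ch[seq_len(n - u)] == ch[seq.int(u + 1L, n)]
    # run[i]: length of the TRUE run in eq starting at i
    run <- integer(n - u + 1L)          # sentinel 0 at n - u + 1
    for (i in seq.int(n - u, 1L)) run[i] <- if (eq[i]) run[i + 1L] + 1L else 0L
    for (i in seq_len(n - 2L * u + 1L)) {
      copies <- 1L + run[i] %/% u
      if (copies >= min_copies) {
        cand[[length(cand) + 1L]] <-
          c(start = i, len = copies * u, u = u, copies = copies)
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  ord <- order(-cand[, "len"], cand[, "start"], cand[, "u"])
  cand <- cand[ord, , drop = FALSE]
  taken <- logical(n)
  picked <- list()
  for (i in seq_len(nrow(cand))) {
    span <- seq.int(cand[i, "start"], length.out = cand[i, "len"])
    if (!any(taken[span])) {
      taken[span] <- TRUE
      picked[[length(picked) + 1L]] <- cand[i, ]
    }
  }
  picked <- do.call(rbind, picked)
  picked <- picked[order(picked[, "start"]), , drop = FALSE]
  data.frame(
    unit = vapply(seq_len(nrow(picked)), function(i)
      min_rotation(substring(sequence, picked[i, "start"],
                             picked[i, "start"] + picked[i, "u"] - 1L)),
      character(1)),
    unit_length = as.integer(picked[, "u"]),
    copies = as.integer(picked[, "copies"]),
    start = as.integer(picked[, "start"] - 1L),
    end = as.integer(picked[, "start"] - 1L + picked[, "len"]),
    stringsAsFactors = FALSE)
}

#' Scan FASTA sequences and build a named STR registry
#'
#' Runs [scan_strs()] over every record of a FASTA file (or a named
#' character vector of sequences) and assigns registry names
#' `<code>_str_<i>` with indices strictly increasing, gap-free, in scan
#' order (sequences in input order, repeats leftmost-first within each).
#'
#' @param x Path to a FASTA file (read with `Biostrings` when available,
#'   otherwise a plain parser) or a named character vector of sequences.
#' @param species_code Species code for the names.
#' @param ... Passed to [scan_strs()].
#' @return Data frame `name`, `unit`, `copies`, `seq_id`, `start`, `end`
#'   (0-based half-open), the persistable sidecar that holds per-locus
#'   detail the name itself does not encode.
#' @export
str_registry <- function(x, species_code = "Acar", ...) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      seqs <- Biostrings::readDNAStringSet(x)
      x <- stats::setNames(as.character(seqs),
                           vapply(strsplit(names(seqs), "\\s+"), `[`,
                                  character(1), 1L))
    } else {
      x <- read_fasta_plain(x)
    }
  }
  agnc_assert(is.character(x) && !is.null(names(x)) && all(nzchar(names(x))),
              "x must be a FASTA path or a named character vector of sequences",
              "sequence")
  hits <- lapply(names(x), function(id) {
    h <- scan_strs(x[[id]], ...)
    if (nrow(h)) h$seq_id <- id
    h
  })
  hits <- do.call(rbind, hits[vapply(hits, nrow, integer(1)) > 0L])
  if (is.null(hits))
    return(data.frame(name = character(), unit = character(),
                      copies = integer(), seq_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  data.frame(name = vapply(seq_len(nrow(hits)), function(i)
               str_name(species_code, i), character(1)),
             unit = hits$unit, copies = hits$copies, seq_id = hits$seq_id,
             start = hits$start, end = hits$end, stringsAsFactors = FALSE)
}

read_fasta_plain <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  agnc_assert(any(hdr) && hdr[1L], "not a FASTA file", "sequence")
  id <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(toupper(gsub("\\s", "", seqs)), id)
}

#' Persist / reload an STR registry
#'
#' @param registry Data frame from [str_registry()].
#' @param path TSV file path.
#' @return `read_str_registry` returns the registry data frame;
#'   `write_str_registry` returns `path` invisibly.
#' @export
write_str_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_str_registry
#' @export
read_str_registry <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "unit", "copies", "seq_id", "start", "end")
  agnc_assert(all(need %in% names(tab)),
              sprintf("STR registry needs columns: %s",
                      paste(need, collapse = ", ")), "malformed_input")
  idx <- vapply(tab$name, function(nm) str_parse(nm)$index, integer(1))
  agnc_assert(identical(unname(idx), seq_len(nrow(tab))),
              "STR registry indices must be 1..n, gap-free, in order",
              "integrity")
  tab
}
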