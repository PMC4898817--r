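#' Validate a small RNA sequence
#'
#' Upper-cases and checks the alphabet; `T` is converted to `U` with a
#' warning so DNA-written inputs are accepted.
#'
#' @param seq Small RNA sequence, 5'->3', at least 7 nt.
#' @return The normalized RNA sequence (character).
#' @export
as_rna_seq <- function(seq) {
  s <- toupper(as.character(seq))
  if (length(s) != 1L || nchar(s) < 7L)
    stop("small RNA must be a single sequence of at least 7 nt")
  if (grepl("T", s, fixed = TRUE)) {
    warning("'T' converted to 'U' in small RNA sequence")
    s <- chartr("T", "U", s)
  }
  if (grepl("[^ACGU]", s))
    stop("small RNA alphabet must be {A,C,G,U}")
  s
}

#' Enumerate candidate 7-nt seed windows
#'
#' Slides a 7-nt window along the small RNA: windows start at positions
#' 1..L-6 (1-based), so a sequence of length L yields L-6 windows. The
#' window starting at position 2 (nucleotides 2-8 from the 5' end) is the
#' classic miR seed. Each window carries its DNA seed-match pattern, the
#' reverse complement of the 7-mer written 5'->3'.
#'
#' @param rna Small RNA sequence (passed through [as_rna_seq()]).
#' @return A data.frame with columns `start`, `rna7`, `pattern`, class
#'   `seed_windows`.
#' @examples
#' seed_windows("CUGUACCAGAUAACGUCGGA")
#' @export
seed_windows <- function(rna) {
  s <- as_rna_seq(rna)
  L <- nchar(s)
  starts <- seq_len(L - 6L)
  rna7 <- substring(s, starts, starts + 6L)
  out <- data.frame(start = starts, rna7 = rna7,
                    pattern = vapply(rna7, seed_match_pattern, character(1),
                                     USE.NAMES = FALSE))
  structure(out, class = c("seed_windows", "data.frame"))
}

#' DNA seed-match pattern of a seed window
#'
#' The sequence a target 3'UTR must contain for exact seed pairing: the DNA
#' reverse complement of the RNA 7-mer, written 5'->3'.
#'
#' @param rna7 An RNA 7-mer.
#' @return A DNA 7-mer (character).
#' @examples
#' seed_match_pattern("UGUACCA")  # "TGGTACA"
#' @export
seed_match_pattern <- function(rna7) {
  s <- toupper(as.character(rna7))
  s <- chartr("U", "T", s)
  if (nchar(s) != 7L || grepl("[^ACGT]", s))
    stop("seed window must be a 7-mer over {A,C,G,U}")
  as.character(reverseComplement(DNAString(s)))
}

#' Scan 3'UTRs for exact seed matches
#'
#' Exact substring search for a seed-match 7-mer on the sense strand of each
#' UTR. A gene is a hit when it carries at least one occurrence; all match
#' offsets are recorded. `N` bases never match.
#'
#' @param pattern DNA 7-mer, e.g. from [seed_match_pattern()].
#' @param utrs A named [Biostrings::DNAStringSet] (one record per gene, name
#'   = gene id) or a named character vector.
#' @param window_start Optional window start bookkeeping for reports.
#' @return A `target_set`: list with elements `pattern`, `window_start`, and
#'   `hits`, a named list mapping each hit gene to its 1-based match offsets.
#' @export
scan_utrs <- function(pattern, utrs, window_start = NA_integer_) {
  pattern <- toupper(as.character(pattern))
  if (nchar(pattern) != 7L || grepl("[^ACGT]", pattern))
    stop("pattern must be a DNA 7-mer")
  if (!is(utrs, "DNAStringSet"))
    utrs <- DNAStringSet(toupper(unlist(as.list(utrs))))
  if (length(utrs) == 0L)
    return(structure(list(pattern = pattern, window_start = window_start,
                          hits = setNames(list(), character(0))),
                     class = "target_set"))
  ids <- names(utrs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every UTR record needs a gene id")
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- vmatchPattern(pattern, utrs, fixed = TRUE)
  st <- Biostrings::startIndex(m)
  hit <- lengths(st) > 0L
  structure(list(pattern = pattern,
                 window_start = window_start,
                 hits = setNames(lapply(st[hit], as.integer), ids[hit])),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("target_set: pattern ", x$pattern,
      if (!is.na(x$window_start)) paste0(" (window start ", x$window_start, ")"),
      ", ", length(x$hits), " gene(s) with ",
      sum(lengths(x$hits)), " site(s)\n", sep = "")
  invisible(x)
}

#' Genes hit by a target set
#'
#' @param x A `target_set` from [scan_utrs()].
#' @return Character vector of gene ids with at least one seed match.
#' @export
target_genes <- function(x) {
  stopifnot(inherits(x, "target_set"))
  names(x$hits)
}

#' Write a target set as TSV
#'
#' Columns: `window_start`, `pattern`, `gene`, `n_sites`, `offsets`
#' (comma-separated 1-based match positions). Missing values are written as
#' `.`.
#'
#' @param x A `target_set` (or list of them) from [scan_utrs()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_target_tsv <- function(x, file) {
  if (inherits(x, "target_set")) x <- list(x)
  rows <- lapply(x, function(ts) {
    if (length(ts$hits) == 0L) return(NULL)
    data.frame(window_start = if (is.na(ts$window_start)) "."
               else ts$window_start,
               pattern = ts$pattern,
               gene = names(ts$hits),
               n_sites = lengths(ts$hits),
               offsets = vapply(ts$hits, paste, character(1), collapse = ","))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(window_start = character(0), pattern = character(0),
                      gene = character(0), n_sites = integer(0),
                      offsets = character(0))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
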