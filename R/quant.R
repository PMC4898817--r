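#' Trim 3' adapter sequence from reads
#'
#' Removes the adapter from each read by exact matching: the read is cut
#' before the leftmost position where the adapter matches exactly, either
#' over its full length or as a terminal partial prefix of at least
#' `min_overlap` bases running to the read's 3' end. Reads without a match
#' are returned unchanged.
#'
#' @param reads Character vector of read sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param adapter Adapter sequence, length >= `min_overlap`.
#' @param min_overlap Minimum matched adapter prefix length (default 6).
#' @return Character vector of insert sequences.
#' @examples
#' trim_adapter(c("ACGTACGTTGGAATTC", "ACGTACGT"), "TGGAATTCTCGG")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  reads <- toupper(as.character(reads))
  adapter <- toupper(as.character(adapter))
  if (any(!nzchar(reads)) || length(reads) == 0L)
    stop("empty read sequence")
  if (nchar(adapter) < min_overlap)
    stop("adapter shorter than min_overlap")
  seedk <- substr(adapter, 1L, min_overlap)
  vapply(reads, function(r) {
    n <- nchar(r)
    # candidate positions: occurrences of the adapter's first min_overlap bases
    pos <- gregexpr(seedk, r, fixed = TRUE)[[1L]]
    if (pos[1L] == -1L) return(r)
    for (i in pos) {
      len <- min(nchar(adapter), n - i + 1L)
      if (substr(r, i, i + len - 1L) == substr(adapter, 1L, len))
        return(substr(r, 1L, i - 1L))
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

#' Keep inserts long enough to map
#'
#' @param inserts Character vector of insert sequences.
#' @param params A [quant_params]; inserts of at least `min_insert` nt
#'   (default 14, i.e. longer than 13 bases) are kept.
#' @return Logical vector, `TRUE` for inserts to keep.
#' @export
filter_insert <- function(inserts, params = quant_params()) {
  nchar(as.character(inserts)) >= params$min_insert
}

#' Candidate pri-miR loci for aligned segments
#'
#' For each aligned segment, the pri-miR loci on the same chromosome and
#' strand whose interval lies within `locus_distance` nt (gap distance,
#' boundary inclusive; overlap counts as distance 0).
#'
#' @param segments A [GenomicRanges::GRanges] of read alignments.
#' @param index A [build_locus_index()] result.
#' @param params A [quant_params].
#' @return List of character vectors of locus ids, one per segment.
#' @export
find_candidate_loci <- function(segments, index, params = quant_params()) {
  query_loci(index, segments, max_gap = params$locus_distance)
}

#' Allot a read evenly among candidate loci
#'
#' A read near several pri-miR loci is split evenly: each candidate locus
#' receives weight `1/k`. A read with no candidates yields no assignment and
#' is excluded from all denominators.
#'
#' @param read_id Read identifier (single string).
#' @param candidates Character vector of candidate locus ids.
#' @return A data.frame with columns `read_id`, `locus_id`, `weight`.
#' @examples
#' allot_weights("r1", c("locA", "locB"))
#' @export
allot_weights <- function(read_id, candidates) {
  candidates <- unique(candidates)
  k <- length(candidates)
  if (k == 0L)
    return(data.frame(read_id = character(0), locus_id = character(0),
                      weight = numeric(0)))
  data.frame(read_id = read_id, locus_id = candidates, weight = 1 / k)
}

#' Classify aligned segments against a locus's windows
#'
#' A segment is assigned the first category (in the order `MIR5P`, `MIR3P`,
#' `MOR5P`, `MOR3P`) whose window entirely contains it on the same
#' chromosome and strand; segments contained in no window (or on the wrong
#' strand/chromosome) are `UNASSIGNED`.
#'
#' @param segments A [GenomicRanges::GRanges] of read alignments.
#' @param regions Windows from [derive_regions()]; if they span several loci
#'   supply `locus_id` to select one.
#' @param locus_id Optional locus id to classify against.
#' @return Factor of categories (levels [CATEGORIES]), one per segment.
#' @export
classify_reads <- function(segments, regions, locus_id = NULL) {
  stopifnot(is(segments, "GRanges"))
  if (!is.null(locus_id))
    regions <- regions[mcols(regions)$locus_id == locus_id]
  cat_int <- rep.int(5L, length(segments))
  if (length(regions)) {
    hits <- findOverlaps(segments, regions, type = "within",
                         ignore.strand = FALSE)
    if (length(hits)) {
      ci <- as.integer(mcols(regions)$category)[subjectHits(hits)]
      best <- tapply(ci, queryHits(hits), min)
      cat_int[as.integer(names(best))] <- as.integer(best)
    }
  }
  factor(CATEGORIES[cat_int], levels = CATEGORIES)
}

#' Tabulate weighted category counts per locus
#'
#' Sums assignment weights by locus and category. `UNASSIGNED` pairs
#' contribute nothing, to either the counts or (downstream) the RPMR
#' denominator.
#'
#' @param assignments A data.frame with columns `read_id`, `locus_id`,
#'   `weight` and `category`.
#' @param library_id Library label for the table.
#' @return A `count_table`: data.frame with columns `library`, `locus`,
#'   `category`, `count`.
#' @export
tabulate_counts <- function(assignments, library_id = "lib1") {
  keep <- assignments$category != "UNASSIGNED"
  a <- assignments[keep, , drop = FALSE]
  if (nrow(a) == 0L) {
    out <- data.frame(library = character(0), locus = character(0),
                      category = character(0), count = numeric(0))
  } else {
    agg <- stats::aggregate(weight ~ locus_id + category, data = a, FUN = sum)
    out <- data.frame(library = library_id, locus = agg$locus_id,
                      category = as.character(agg$category),
                      count = agg$weight)
    out <- out[order(out$locus, match(out$category, CATEGORIES)), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("count_table", "data.frame"))
}

#' Normalize counts to reads per million region-mapped reads
#'
#' Each count is divided by the library's total region-assigned count in
#' millions, so RPMR values sum to 1e6 per library.
#'
#' @param counts A `count_table` from [tabulate_counts()].
#' @return The table with an added `rpmr` column.
#' @export
normalize_rpmr <- function(counts) {
  stopifnot(inherits(counts, "count_table") || is.data.frame(counts))
  out <- counts
  out$rpmr <- rep(NA_real_, nrow(out))
  for (lib in unique(out$library)) {
    i <- out$library == lib
    total <- sum(out$count[i])
    if (total <= 0)
      stop("no region-mapped reads in library ", lib)
    out$rpmr[i] <- out$count[i] / (total / 1e6)
  }
  structure(out, class = c("rpmr_table", class(counts)))
}

#' Quantify miR and moR reads over an annotation
#'
#' Full classification pipeline: candidate loci are found within
#' `locus_distance` nt of each alignment (same strand); each read's weight
#' is split evenly over the union of candidate loci across its alignment
#' records; each read-locus pair is classified against the locus's four
#' windows; weighted counts are tabulated and RPMR-normalized.
#'
#' @param reads A [GenomicRanges::GRanges] of alignments with a `read_id`
#'   metadata column (multiple records per read allowed).
#' @param loci A [mir_loci] annotation.
#' @param params A [quant_params].
#' @param library_id Library label.
#' @return A list with elements `counts` (RPMR-normalized `count_table`),
#'   `assignments` (per read-locus pair: weight and category) and `summary`
#'   (totals per category, fraction of reads region-assigned).
#' @export
quantify_smallrna <- function(reads, loci, params = quant_params(),
                              library_id = "lib1") {
  stopifnot(is(reads, "GRanges"))
  if (is.null(mcols(reads)$read_id))
    stop("reads need a read_id metadata column")
  index <- build_locus_index(loci)
  regions <- derive_regions(loci, params)
  cand <- find_candidate_loci(reads, index, params)
  ni <- lengths(cand)
  pair <- data.frame(
    aln = rep(seq_along(reads), ni),
    read_id = rep(mcols(reads)$read_id, ni),
    locus_id = unlist(cand, use.names = FALSE))

  # category of each (alignment, locus) pair by window containment
  pair$cat <- 5L
  hits <- findOverlaps(reads, regions, type = "within",
                       ignore.strand = FALSE)
  if (length(hits)) {
    hk <- paste(queryHits(hits),
                mcols(regions)$locus_id[subjectHits(hits)], sep = "\r")
    hc <- as.integer(mcols(regions)$category)[subjectHits(hits)]
    best <- tapply(hc, hk, min)
    m <- match(paste(pair$aln, pair$locus_id, sep = "\r"), names(best))
    pair$cat[!is.na(m)] <- as.integer(best[m[!is.na(m)]])
  }

  # collapse alignment records to read-locus pairs (best category wins),
  # then allot each read's unit weight evenly over its candidate loci
  rl <- paste(pair$read_id, pair$locus_id, sep = "\r")
  bestc <- tapply(pair$cat, rl, min)
  assign <- pair[!duplicated(rl), c("read_id", "locus_id")]
  assign$category <- factor(CATEGORIES[as.integer(bestc[rl[!duplicated(rl)]])],
                            levels = CATEGORIES)
  nl <- table(assign$read_id)
  assign$weight <- 1 / as.integer(nl[assign$read_id])
  rownames(assign) <- NULL

  counts <- tabulate_counts(assign, library_id)
  n_reads <- length(unique(mcols(reads)$read_id))
  assigned <- sum(assign$weight[assign$category != "UNASSIGNED"])
  summary <- list(
    library = library_id,
    n_reads = n_reads,
    total_assigned = assigned,
    frac_assigned = if (n_reads > 0) assigned / n_reads else NA_real_,
    by_category = vapply(setdiff(CATEGORIES, "UNASSIGNED"), function(cc)
      sum(assign$weight[assign$category == cc]), numeric(1)))
  rpmr <- if (assigned > 0) normalize_rpmr(counts) else counts
  list(counts = rpmr, assignments = assign, summary = summary)
}
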