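#' Pri-miR loci with mature arms
#'
#' Container tying each pri-miR (primary transcript) interval to its mature
#' 5p/3p arm coordinates. Coordinates are 1-based closed [`GRanges`]
#' throughout the package; GFF3 input and BED output are converted at the
#' I/O boundary only.
#'
#' @param pri A [GenomicRanges::GRanges] of pri-miR intervals, one per locus,
#'   with names giving unique locus ids (or an `ID` metadata column).
#' @param mature A [GenomicRanges::GRanges] of mature miRs with metadata
#'   columns `locus_id` (matching a name of `pri`), `arm` (`"5p"` or `"3p"`)
#'   and optionally `name`.
#' @return An object of class `mir_loci` with elements `pri` and `mature`.
#' @details Mature arms must lie within their pri-miR interval and share its
#'   chromosome and strand; each locus must carry at least one arm. Mature
#'   lengths outside 15-30 nt raise a warning (not an error): annotated
#'   mature miRs are typically 18-26 nt.
#' @seealso [read_mirbase_gff()] to build one from a miRBase-style GFF3,
#'   [derive_regions()] for the classification windows.
#' @export
mir_loci <- function(pri, mature) {
  stopifnot(is(pri, "GRanges"), is(mature, "GRanges"))
  if (length(pri) == 0L && length(mature) == 0L)
    return(structure(list(pri = setNames(pri, character(0)),
                          mature = mature),
                     class = "mir_loci"))
  if (is.null(names(pri)) && !is.null(mcols(pri)$ID))
    names(pri) <- mcols(pri)$ID
  if (is.null(names(pri)) || anyNA(names(pri)) || any(names(pri) == ""))
    stop("every pri-miR locus needs an id (names of 'pri' or an ID column)")
  if (anyDuplicated(names(pri)))
    stop("duplicate locus ids: ",
         paste(unique(names(pri)[duplicated(names(pri))]), collapse = ", "))
  md <- mcols(mature)
  if (is.null(md$locus_id) || is.null(md$arm))
    stop("'mature' needs locus_id and arm metadata columns")
  if (!all(md$arm %in% c("5p", "3p")))
    stop("mature arm must be '5p' or '3p'")
  bad <- setdiff(md$locus_id, names(pri))
  if (length(bad))
    stop("mature arms reference unknown loci: ", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(md$locus_id, md$arm)))
    stop("a locus may carry at most one mature arm of each kind")
  idx <- match(md$locus_id, names(pri))
  same <- as.character(seqnames(mature)) == as.character(seqnames(pri))[idx] &
    as.character(strand(mature)) == as.character(strand(pri))[idx]
  inside <- start(mature) >= start(pri)[idx] & end(mature) <= end(pri)[idx]
  if (!all(same & inside))
    stop("mature arms must lie within their pri-miR and share chrom/strand")
  if (!all(names(pri) %in% md$locus_id))
    stop("every locus needs at least one mature arm")
  wl <- width(mature)
  if (any(wl < 15L | wl > 30L))
    warning("mature arm length outside 15-30 nt for: ",
            paste(if (is.null(md$name)) md$locus_id else md$name,
                  collapse = ", "))
  structure(list(pri = pri, mature = mature), class = "mir_loci")
}

#' @export
print.mir_loci <- function(x, ...) {
  cat("mir_loci: ", length(x$pri), " pri-miR loci, ",
      sum(mcols(x$mature)$arm == "5p"), " x 5p and ",
      sum(mcols(x$mature)$arm == "3p"), " x 3p mature arms\n", sep = "")
  invisible(x)
}

#' @export
length.mir_loci <- function(x) length(x$pri)

#' Read a miRBase-style GFF3 annotation
#'
#' Parses `miRNA_primary_transcript` features and their `miRNA` children
#' (linked by `Derives_from` or `Parent`) into a [mir_loci] object. Arms are
#' taken from a `-5p`/`-3p` suffix on the mature name when present; matures
#' without a suffix are assigned by transcript orientation, the 5'-most
#' mature being the 5p arm.
#'
#' @param file Path to a GFF3 file (1-based inclusive coordinates).
#' @return A [mir_loci] object.
#' @details Non-comment lines with other than nine tab-separated fields stop
#'   parsing with the offending line number. Mature records whose parent
#'   cannot be resolved are skipped with a warning.
#' @export
read_mirbase_gff <- function(file) {
  lines <- readLines(file, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    ln <- which(body)[which(nf != 9L)[1L]]
    stop("malformed GFF3 line ", ln, ": expected 9 tab-separated fields, got ",
         nf[which(nf != 9L)[1L]])
  }
  gr <- rtracklayer::import(file, format = "gff3")
  pri <- gr[gr$type == "miRNA_primary_transcript"]
  mat <- gr[gr$type == "miRNA"]
  if (length(pri) == 0L)
    stop("no miRNA_primary_transcript records found")
  names(pri) <- if (!is.null(pri$ID)) pri$ID else pri$Name
  parent_of <- function(m) {
    p <- mcols(m)$Derives_from
    if (is.null(p)) p <- mcols(m)$Parent
    if (is(p, "List")) p <- vapply(p, function(v)
      if (length(v)) v[[1L]] else NA_character_, character(1))
    as.character(p)
  }
  par <- if (length(mat)) parent_of(mat) else character(0)
  known <- par %in% names(pri)
  if (any(!known)) {
    warning(sum(!known), " mature miRNA record(s) with no resolvable ",
            "parent skipped")
    mat <- mat[known]
    par <- par[known]
  }
  mname <- if (!is.null(mat$Name)) as.character(mat$Name)
           else as.character(mat$ID)
  arm <- ifelse(grepl("[-_]5p$", mname, ignore.case = TRUE), "5p",
         ifelse(grepl("[-_]3p$", mname, ignore.case = TRUE), "3p", NA))
  # fall back to transcript-orientation order: 5'-most mature is the 5p arm
  for (lid in unique(par[is.na(arm)])) {
    i <- which(par == lid)
    minus <- as.character(strand(pri[lid])) == "-"
    ord <- order(if (minus) -end(mat)[i] else start(mat)[i])
    arm[i[ord]] <- c("5p", "3p")[seq_along(i)]
  }
  mature <- granges(mat)
  mcols(mature) <- S4Vectors::DataFrame(locus_id = par, arm = arm,
                                        name = mname)
  mir_loci(granges(pri), mature)
}

#' Derive the four read-classification windows of a locus
#'
#' For each mature arm the miR window extends the arm by `mir_slack` nt on
#' both sides. The moR window sits on the offset side of the arm, in
#' transcript orientation: for a 5p arm it runs from `mor_extent` nt upstream
#' of the arm's first (5') base to `mir_slack` nt inside the arm; for a 3p
#' arm, from `mir_slack` nt inside the arm to `mor_extent` nt downstream of
#' its last (3') base. With defaults every moR window is
#' `mor_extent + mir_slack + 1` = 39 nt long and overlaps its same-arm miR
#' window by exactly `2 * mir_slack + 1` = 7 nt, so no read of
#' `min_insert` nt or more can be contained in both. Windows may extend
#' beyond the pri-miR interval; they are clipped at position 1.
#'
#' @param loci A [mir_loci] object.
#' @param params A [quant_params] object.
#' @return A [GenomicRanges::GRanges] of windows with metadata columns
#'   `locus_id` and `category` (one of `MIR5P`, `MIR3P`, `MOR5P`, `MOR3P`).
#'   Loci lacking an arm simply lack the corresponding windows.
#' @examples
#' pri <- GenomicRanges::GRanges("chr1", IRanges::IRanges(995, 1090), "+")
#' names(pri) <- "locA"
#' mat <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1001, 1061), c(1022, 1082)), "+",
#'   locus_id = "locA", arm = c("5p", "3p"))
#' derive_regions(mir_loci(pri, mat), quant_params())
#' @export
derive_regions <- function(loci, params = quant_params()) {
  stopifnot(inherits(loci, "mir_loci"), inherits(params, "quant_params"))
  m <- loci$mature
  if (length(m) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(
      locus_id = character(0),
      category = factor(character(0), levels = CATEGORIES))
    return(gr)
  }
  slack <- params$mir_slack
  ext <- params$mor_extent
  s <- start(m); e <- end(m)
  minus <- as.character(strand(m)) == "-"
  arm <- mcols(m)$arm
  # miR window: arm plus slack on both sides (strand-symmetric)
  mir <- GRanges(seqnames(m), IRanges(s - slack, e + slack), strand(m),
                 locus_id = mcols(m)$locus_id,
                 category = ifelse(arm == "5p", "MIR5P", "MIR3P"))
  # moR window: anchored at the arm's offset-side terminal base
  # (5' base for a 5p arm, 3' base for a 3p arm, in transcript orientation)
  five <- arm == "5p"
  anchor <- ifelse(five,
                   ifelse(minus, e, s),   # first base of the arm
                   ifelse(minus, s, e))   # last base of the arm
  outward <- xor(five, minus)  # TRUE: window extends to lower coordinates
  mor_s <- ifelse(outward, anchor - ext, anchor - slack)
  mor_e <- ifelse(outward, anchor + slack, anchor + ext)
  mor <- GRanges(seqnames(m), IRanges(mor_s, mor_e), strand(m),
                 locus_id = mcols(m)$locus_id,
                 category = ifelse(five, "MOR5P", "MOR3P"))
  win <- c(mir, mor)
  start(win) <- pmax(start(win), 1L)
  mcols(win)$category <- factor(mcols(win)$category, levels = CATEGORIES)
  ord <- order(mcols(win)$locus_id, as.integer(mcols(win)$category))
  win[ord]
}

#' Region categories
#'
#' The closed set of read categories: 5p/3p miR windows, 5p/3p moR windows,
#' and `UNASSIGNED` for reads contained in no window.
#' @format Character vector of length 5.
#' @export
CATEGORIES <- c("MIR5P", "MIR3P", "MOR5P", "MOR3P", "UNASSIGNED")

#' Build a queryable index over pri-miR loci
#'
#' Wraps the pri-miR intervals in a nested containment list so that
#' "all loci within D nt of a query interval" queries run in logarithmic
#' rather than linear time over the annotation.
#'
#' @param loci A [mir_loci] object (unique locus ids enforced).
#' @return An object of class `locus_index`.
#' @seealso [query_loci()]
#' @export
build_locus_index <- function(loci) {
  stopifnot(inherits(loci, "mir_loci"))
  if (anyDuplicated(names(loci$pri)))
    stop("duplicate locus ids in index")
  structure(list(pri = loci$pri,
                 nclist = GenomicRanges::GNCList(loci$pri)),
            class = "locus_index")
}

#' Query loci near an interval
#'
#' Returns, for each query range, the ids of indexed pri-miR loci on the same
#' chromosome and strand whose interval lies within `max_gap` nt (gap
#' distance: 0 when overlapping or adjacent; the bound is inclusive).
#'
#' @param index A [build_locus_index()] result.
#' @param query A [GenomicRanges::GRanges] of query intervals.
#' @param max_gap Maximum gap in nt (default 50).
#' @return A list of character vectors of locus ids, one per query range.
#'   Queries on chromosomes absent from the index warn and return empty.
#' @export
query_loci <- function(index, query, max_gap = 50L) {
  stopifnot(inherits(index, "locus_index"), is(query, "GRanges"))
  unknown <- !(as.character(seqnames(query)) %in%
                 as.character(seqlevels(index$pri)))
  if (any(unknown))
    warning("query chromosome(s) not in index: ",
            paste(unique(as.character(seqnames(query))[unknown]),
                  collapse = ", "))
  hits <- findOverlaps(query, index$nclist, maxgap = max_gap,
                       ignore.strand = FALSE)
  ids <- split(names(index$pri)[subjectHits(hits)],
               factor(queryHits(hits), levels = seq_along(query)))
  lapply(ids, unique)
}

#' Write classification windows as BED6
#'
#' Exports the windows from [derive_regions()] in BED format (0-based
#' half-open), with `name = <locus_id>:<category>`.
#'
#' @param regions Windows from [derive_regions()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, file) {
  gr <- regions
  names(gr) <- NULL
  mcols(gr) <- S4Vectors::DataFrame(
    name = paste0(mcols(regions)$locus_id, ":", mcols(regions)$category),
    score = 0L)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
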