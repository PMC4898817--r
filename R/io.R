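#' Read aligned small-RNA segments
#'
#' Loads alignments from SAM, BAM or BED6 into the [GenomicRanges::GRanges]
#' the quantification pipeline consumes. SAM files are converted through
#' [Rsamtools::asBam()]; reference spans come from the CIGAR. BED input
#' (0-based half-open) is converted to 1-based closed coordinates with the
#' record name as read id. Unmapped records are dropped.
#'
#' @param file Path to a `.sam`, `.bam` or `.bed` file.
#' @param format One of `"auto"` (by extension), `"sam"`, `"bam"`, `"bed"`.
#' @return A [GenomicRanges::GRanges] with a `read_id` metadata column; a
#'   read aligned to several places appears as several records.
#' @export
read_alignments <- function(file, format = c("auto", "sam", "bam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- switch(ext, sam = "sam", bam = "bam", bed = "bed",
                     stop("cannot guess alignment format from '.", ext,
                          "'; pass format="))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(file, format = "BED")
    out <- granges(gr)
    mcols(out)$read_id <- if (!is.null(gr$name)) as.character(gr$name)
                          else paste0("read", seq_along(gr))
    return(out)
  }
  bam <- if (format == "sam")
    Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  else file
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  out <- granges(ga)
  mcols(out)$read_id <- names(ga)
  names(out) <- NULL
  out
}

#' Write aligned segments as SAM
#'
#' Emits minimal single-end SAM records (flag 0/16 by strand, MAPQ 255,
#' all-match CIGAR) for simulated reads. Sequence is taken from `genome`
#' when supplied, else written as `*`.
#'
#' @param reads A [GenomicRanges::GRanges] with a `read_id` column.
#' @param file Output path.
#' @param genome Optional named [Biostrings::DNAStringSet] of reference
#'   sequences.
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, file, genome = NULL) {
  stopifnot(is(reads, "GRanges"), !is.null(mcols(reads)$read_id))
  lens <- if (!is.null(genome)) setNames(Biostrings::width(genome),
                                         names(genome))
          else setNames(vapply(split(end(reads),
                                     as.character(seqnames(reads))),
                               max, numeric(1)),
                        unique(as.character(seqnames(reads))))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(lens), "\tLN:", lens))
  seqstr <- if (!is.null(genome)) {
    as.character(Biostrings::subseq(
      genome[as.character(seqnames(reads))], start(reads), end(reads)))
  } else rep("*", length(reads))
  rec <- paste(mcols(reads)$read_id,
               ifelse(as.character(strand(reads)) == "-", 16L, 0L),
               as.character(seqnames(reads)),
               start(reads), 255L, paste0(width(reads), "M"),
               "*", 0L, 0L, seqstr, "*", sep = "\t")
  writeLines(c(hdr, rec), file)
  invisible(file)
}

#' Write a miRBase-style GFF3 annotation
#'
#' Emits `miRNA_primary_transcript` records and `miRNA` children linked by
#' `Derives_from`, with 1-based inclusive coordinates.
#'
#' @param loci A [mir_loci] object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_mirbase_gff <- function(loci, file) {
  stopifnot(inherits(loci, "mir_loci"))
  pri <- loci$pri
  mat <- loci$mature
  att_p <- paste0("ID=", names(pri), ";Name=", names(pri))
  mname <- if (!is.null(mcols(mat)$name)) mcols(mat)$name
           else paste0(mcols(mat)$locus_id, "-", mcols(mat)$arm)
  att_m <- paste0("ID=", mname, ";Name=", mname,
                  ";Derives_from=", mcols(mat)$locus_id)
  fmt <- function(gr, type, att)
    paste(as.character(seqnames(gr)), "morna", type, start(gr), end(gr),
          ".", as.character(strand(gr)), ".", att, sep = "\t")
  writeLines(c("##gff-version 3",
               fmt(pri, "miRNA_primary_transcript", att_p),
               fmt(mat, "miRNA", att_m)),
             file)
  invisible(file)
}

#' Read 3'UTR sequences from FASTA
#'
#' One record per gene; the record id (first word of the header) is the
#' gene id, the rest of the description is ignored.
#'
#' @param file FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_utr_fasta <- function(file) {
  utrs <- readDNAStringSet(file)
  names(utrs) <- sub("\\s.*$", "", names(utrs))
  if (anyDuplicated(names(utrs)))
    stop("duplicate gene ids in UTR FASTA")
  utrs
}

#' Read a differential-expression table
#'
#' Headered TSV with columns `gene`, `fold_change` (signed magnitude
#' convention), `adj_p` and `detected`; `.` denotes missing values.
#'
#' @param file TSV path.
#' @return A data.frame suitable for [classify_de()].
#' @export
read_de_table <- function(file) {
  de <- read.delim(file, na.strings = c("NA", "."),
                   stringsAsFactors = FALSE)
  need <- c("gene", "fold_change", "adj_p", "detected")
  miss <- setdiff(need, names(de))
  if (length(miss))
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  de$fold_change <- as.numeric(de$fold_change)
  de$adj_p <- as.numeric(de$adj_p)
  de$detected <- as.logical(de$detected)
  de
}

#' Write a differential-expression table
#'
#' @param de DE data.frame (see [read_de_table()]).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_de_table <- function(de, file) {
  out <- de
  out[] <- lapply(out, function(x) ifelse(is.na(x), ".", as.character(x)))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a count/RPMR table as TSV
#'
#' Columns `library`, `locus`, `category`, `count` and, when present,
#' `rpmr`; `.` for missing values.
#'
#' @param counts A `count_table` (see [tabulate_counts()],
#'   [normalize_rpmr()]).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_count_table <- function(counts, file) {
  out <- as.data.frame(counts)
  out[] <- lapply(out, function(x) ifelse(is.na(x), ".", as.character(x)))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a per-library quantification summary as JSON
#'
#' @param summary The `summary` element of a [quantify_smallrna()] result.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(summary, file) {
  jsonlite::write_json(c(list(schema_version = 1L), summary), file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Write an enrichment table as TSV
#'
#' @param results An `enrichment_table` from [enrich_windows()] or
#'   [rank_windows()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_enrichment_tsv <- function(results, file) {
  write.table(as.data.frame(results), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
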