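#' Bulged sponge binding-site model
#'
#' A sponge decoy site pairs a small RNA at both ends but leaves an
#' unpairable bulge opposite its central nucleotides, preventing
#' Ago2-mediated endonucleolytic cleavage while retaining binding. In DNA
#' the site reads `anchor5 + bulge + anchor3` where `anchor5` is the reverse
#' complement of the small RNA's 3'-terminal `m` nt (default m = 6),
#' `anchor3` the reverse complement of its nucleotides 1-8, and the bulge
#' any `bulge_len` bases.
#'
#' @param rna Small RNA sequence (see [as_rna_seq()]), length >= 14.
#' @param tail_anchor Number of 3'-terminal nt anchored (default 6).
#' @param bulge_len Bulge length in nt (default 3).
#' @return An object of class `sponge_site_model` with elements `anchor5`,
#'   `anchor3`, `bulge_len` and `rna`.
#' @examples
#' sponge_site_model("CUGUACCAGAUAACGUCGGA")
#' @export
sponge_site_model <- function(rna, tail_anchor = 6L, bulge_len = 3L) {
  s <- as_rna_seq(rna)
  L <- nchar(s)
  if (L < 8L + tail_anchor)
    stop("small RNA too short for a ", tail_anchor, "+8 nt anchored site")
  dna <- chartr("U", "T", s)
  anchor3 <- as.character(reverseComplement(DNAString(substr(dna, 1L, 8L))))
  anchor5 <- as.character(reverseComplement(
    DNAString(substr(dna, L - tail_anchor + 1L, L))))
  structure(list(anchor5 = anchor5, anchor3 = anchor3,
                 bulge_len = as.integer(bulge_len), rna = s),
            class = "sponge_site_model")
}

#' @export
print.sponge_site_model <- function(x, ...) {
  cat("sponge_site_model: ", x$anchor5, " + N{", x$bulge_len, "} + ",
      x$anchor3, "\n", sep = "")
  invisible(x)
}

#' Count bulged binding sites in a sequence
#'
#' Counts non-overlapping occurrences of `anchor5` + `bulge_len` arbitrary
#' bases + `anchor3`, scanning left to right (case-insensitive).
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param model A [sponge_site_model()], or `NULL` to supply anchors
#'   directly.
#' @param anchor5,anchor3,bulge_len Site components, used when `model` is
#'   `NULL`.
#' @return Integer count of sites.
#' @examples
#' count_sponge_sites("TCCGACAAATGGTACAG",
#'                    anchor5 = "TCCGAC", anchor3 = "TGGTACAG")
#' @export
count_sponge_sites <- function(seq, model = NULL, anchor5 = NULL,
                               anchor3 = NULL, bulge_len = 3L) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "sponge_site_model"))
    anchor5 <- model$anchor5
    anchor3 <- model$anchor3
    bulge_len <- model$bulge_len
  }
  if (is.null(anchor5) || is.null(anchor3) || !nzchar(anchor5) ||
      !nzchar(anchor3))
    stop("site anchors must be non-empty")
  s <- toupper(as.character(seq))
  pat <- paste0(anchor5, strrep(".", bulge_len), anchor3)
  m <- gregexpr(pat, s)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Assemble a bulged sponge construct
#'
#' Concatenates `flank5 + site1 + linker1 + ... + siteN + flank3`, each site
#' built from the small RNA per [sponge_site_model()]. The default flanks
#' carry XhoI (`CTCGAG`) and ApaI (`GGGCCC`) sites for cloning. A bulge that
#' restores perfect complementarity to the small RNA opposite the bulge
#' (which would permit cleavage) raises a warning.
#'
#' @param rna Small RNA sequence.
#' @param n_sites Number of tandem sites (default 7).
#' @param bulges Character vector of `n_sites` bulge sequences (default: a
#'   fixed trinucleotide cycle, recycled as needed).
#' @param linkers Character vector of `n_sites - 1` linkers (default: a
#'   fixed tetranucleotide cycle).
#' @param flank5,flank3 Flanking sequences; defaults carry the XhoI/ApaI
#'   cloning sites.
#' @param tail_anchor,bulge_len Passed to [sponge_site_model()].
#' @return The construct DNA sequence (character, upper case), with the
#'   model attached as attribute `model`.
#' @examples
#' sp <- build_sponge("CUGUACCAGAUAACGUCGGA", n_sites = 3)
#' count_sponge_sites(sp, attr(sp, "model"))
#' @export
build_sponge <- function(rna, n_sites = 7L,
                         bulges = NULL, linkers = NULL,
                         flank5 = "ACTAGCACTCGAGCCGA",
                         flank3 = "ACGGATCGCGGGCCCTAATATC",
                         tail_anchor = 6L, bulge_len = 3L) {
  model <- sponge_site_model(rna, tail_anchor, bulge_len)
  default_bulges <- c("TCC", "GTA", "CAT", "GTC", "GCA", "CGC", "CTC")
  default_linkers <- c("GCGT", "ACGC", "TCGA", "ACCG", "CCGG", "ACGA")
  if (is.null(bulges))
    bulges <- rep_len(default_bulges, n_sites)
  if (is.null(linkers))
    linkers <- if (n_sites > 1L) rep_len(default_linkers, n_sites - 1L)
               else character(0)
  bulges <- toupper(bulges)
  linkers <- toupper(linkers)
  if (length(bulges) != n_sites)
    stop("need exactly n_sites bulge sequences")
  if (length(linkers) != max(n_sites - 1L, 0L))
    stop("need exactly n_sites - 1 linker sequences")
  if (any(nchar(bulges) != bulge_len))
    stop("every bulge must have length bulge_len")
  # bulge opposite small-RNA positions 9..(8 + bulge_len): warn if the bulge
  # base-pairs them perfectly, as that restores a cleavable duplex
  opp <- substr(chartr("U", "T", model$rna), 9L, 8L + bulge_len)
  cleavable <- as.character(reverseComplement(DNAString(opp)))
  if (any(bulges == cleavable))
    warning("bulge restores perfect complementarity to small-RNA ",
            "positions 9-", 8L + bulge_len, "; site may be cleaved")
  sites <- paste0(model$anchor5, bulges, model$anchor3)
  core <- sites[1L]
  if (n_sites > 1L)
    core <- paste0(core,
                   paste0(linkers, sites[-1L], collapse = ""))
  out <- toupper(paste0(flank5, core, flank3))
  attr(out, "model") <- model
  out
}
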