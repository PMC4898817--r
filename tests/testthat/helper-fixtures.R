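suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# synthetic stand-in for the studied ~20-nt small RNA: its first 8 nt and
# last 6 nt are fixed by the published sponge-site anchors, the middle is a
# placeholder
TEST_SMALL_RNA <- "CUGUACCAGAUAACGUCGGA"

extdata <- function(f) system.file("extdata", f, package = "morna")

# one fixture locus matching the documented worked example
make_locus <- function(strand = "+", id = "locA", chrom = "chr1",
                       pri = c(995L, 1090L),
                       m5 = c(1001L, 1022L), m3 = c(1061L, 1082L)) {
  pri_gr <- GRanges(chrom, IRanges(pri[1], pri[2]), strand)
  names(pri_gr) <- id
  mat <- GRanges(chrom, IRanges(c(m5[1], m3[1]), c(m5[2], m3[2])), strand,
                 locus_id = id, arm = c("5p", "3p"))
  mir_loci(pri_gr, mat)
}

# gap distance between 1-based closed intervals: bases strictly between
gap_dist <- function(s1, e1, s2, e2) {
  max(0L, s2 - e1 - 1L, s1 - e2 - 1L)
}

# independent re-derivation of the four windows from the counting rules,
# by plain arithmetic (1-based closed), used as the oracle for the package
naive_windows <- function(s, e, strand, arm, slack = 3L, ext = 35L) {
  mir <- c(s - slack, e + slack)
  if (arm == "5p") {
    first <- if (strand == "+") s else e
    mor <- if (strand == "+") c(first - ext, first + slack)
           else c(first - slack, first + ext)
  } else {
    last <- if (strand == "+") e else s
    mor <- if (strand == "+") c(last - slack, last + ext)
           else c(last - ext, last + slack)
  }
  list(mir = pmax(mir, 1L), mor = pmax(mor, 1L))
}

# naive O(reads x loci) reference quantifier over a mir_loci annotation;
# everything is recomputed with scalar arithmetic, no package calls
naive_quant <- function(reads, loci, locus_distance = 50L) {
  # flatten everything to plain vectors up front; all decisions below are
  # scalar arithmetic in an explicit reads x loci double loop
  r_chr <- as.character(seqnames(reads))
  r_str <- as.character(strand(reads))
  r_s <- start(reads); r_e <- end(reads)
  rid <- mcols(reads)$read_id
  pri <- loci$pri
  p_chr <- as.character(seqnames(pri))
  p_str <- as.character(strand(pri))
  p_s <- start(pri); p_e <- end(pri)
  p_id <- names(pri)
  mat <- loci$mature
  m_lid <- mcols(mat)$locus_id
  m_arm <- mcols(mat)$arm
  m_str <- as.character(strand(mat))
  m_s <- start(mat); m_e <- end(mat)

  n <- length(reads)
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- character(0)
    for (j in seq_along(p_id)) {
      if (r_chr[i] != p_chr[j] || r_str[i] != p_str[j]) next
      if (gap_dist(r_s[i], r_e[i], p_s[j], p_e[j]) <= locus_distance)
        hits <- c(hits, p_id[j])
    }
    cand[[i]] <- hits
  }
  per_read <- tapply(cand, rid, function(l) unique(unlist(l)),
                     simplify = FALSE)
  rows_read <- character(0); rows_loc <- character(0)
  rows_cat <- character(0)
  for (i in seq_len(n)) {
    for (lid in cand[[i]]) {
      k <- which(m_lid == lid)
      cat_i <- "UNASSIGNED"
      for (ci in c("MIR5P", "MIR3P", "MOR5P", "MOR3P")) {
        arm <- if (ci %in% c("MIR5P", "MOR5P")) "5p" else "3p"
        kk <- k[m_arm[k] == arm]
        if (length(kk) == 0L) next
        w <- naive_windows(m_s[kk], m_e[kk], m_str[kk], arm)
        win <- if (ci %in% c("MIR5P", "MIR3P")) w$mir else w$mor
        if (r_s[i] >= win[1] && r_e[i] <= win[2]) {
          cat_i <- ci
          break
        }
      }
      rows_read <- c(rows_read, rid[i])
      rows_loc <- c(rows_loc, lid)
      rows_cat <- c(rows_cat, cat_i)
    }
  }
  if (length(rows_read) == 0L)
    return(data.frame(locus = character(0), category = character(0),
                      count = numeric(0)))
  df <- unique(data.frame(read_id = rows_read, locus_id = rows_loc,
                          category = rows_cat))
  nloc <- lengths(per_read)
  df$weight <- 1 / nloc[df$read_id]
  df <- df[df$category != "UNASSIGNED", , drop = FALSE]
  agg <- aggregate(weight ~ locus_id + category, df, sum)
  out <- data.frame(locus = agg$locus_id, category = agg$category,
                    count = agg$weight)
  out[order(out$locus, out$category), ]
}
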