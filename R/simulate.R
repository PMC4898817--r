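#' Configuration for synthetic annotations and read libraries
#'
#' Defines the desk-scale study conditions for the read-classification
#' pipeline: a single synthetic chromosome carrying non-overlapping pri-miR
#' loci (each with 5p and 3p mature arms, random strand, >= 200 nt apart)
#' and a read library drawn from the four classification windows plus
#' intergenic background.
#'
#' When `multi_locus_fraction > 0`, part of the loci are laid out as close
#' same-strand pairs separated by a 100-nt gap — the arrangement of genomic
#' miR clusters — and that fraction of reads is placed centred in a pair's
#' gap, within 50 nt of both loci but inside no classification window, to
#' exercise the even-allotment rule.
#'
#' @param seed Integer seed; all outputs are pure functions of seed+config.
#' @param n_loci Number of pri-miR loci (default 20).
#' @param chrom_length Chromosome length in nt (default 1e5).
#' @param mature_len Range of mature-arm lengths (default 20-23 nt).
#' @param reads_per_library Number of reads (default 10000).
#' @param category_mix Named probabilities over `MIR5P`, `MIR3P`, `MOR5P`,
#'   `MOR3P`, `BACKGROUND` (must sum to 1).
#' @param read_len Range of read lengths (default 18-26 nt).
#' @param multi_locus_fraction Fraction of reads placed within 50 nt of two
#'   loci (default 0.05).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 20L, chrom_length = 100000L,
                       mature_len = c(20L, 23L),
                       reads_per_library = 10000L,
                       category_mix = c(MIR5P = 0.35, MIR3P = 0.25,
                                        MOR5P = 0.15, MOR3P = 0.10,
                                        BACKGROUND = 0.15),
                       read_len = c(18L, 26L),
                       multi_locus_fraction = 0.05) {
  stopifnot(length(category_mix) == 5L,
            all(names(category_mix) %in%
                  c(CATEGORIES[1:4], "BACKGROUND")),
            abs(sum(category_mix) - 1) < 1e-8,
            all(category_mix >= 0),
            mature_len[1] <= mature_len[2], read_len[1] <= read_len[2],
            multi_locus_fraction >= 0, multi_locus_fraction <= 1)
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 chrom_length = as.integer(chrom_length),
                 mature_len = as.integer(mature_len),
                 reads_per_library = as.integer(reads_per_library),
                 category_mix = category_mix,
                 read_len = as.integer(read_len),
                 multi_locus_fraction = multi_locus_fraction),
            class = "sim_config")
}

# sample one/many values uniformly from an integer range [a, b]
# (avoids base sample()'s scalar-x surprise when a == b)
.runif_int <- function(a, b, n = 1L) {
  a + sample.int(b - a + 1L, n, replace = TRUE) - 1L
}

# random DNA of total length n (internal helper)
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic pri-miR annotation
#'
#' Lays out `n_loci` pri-miR loci along one synthetic chromosome. Each locus
#' carries a 5p and a 3p mature arm (lengths from `mature_len`) separated by
#' a 12-18 nt loop, with 10 nt of pri-miR flank beyond each arm. Single loci
#' are separated by at least 200 nt; when `multi_locus_fraction > 0` about a
#' tenth of the loci form close pairs with a 100-nt gap (see [sim_config]).
#'
#' @param config A [sim_config].
#' @return A list: `genome` (a named [Biostrings::DNAStringSet]), `loci`
#'   (a [mir_loci]), and `truth` (data.frame of locus coordinates with the
#'   pair id of clustered loci, `NA` for singletons).
#' @export
gen_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_loci
    n_pairs <- if (config$multi_locus_fraction > 0 && n >= 2L)
      max(1L, n %/% 10L) else 0L
    unit_of <- integer(0)   # locus -> pair id (0 = singleton)
    units <- list()
    i <- 1L
    pid <- 0L
    while (i <= n) {
      if (pid < n_pairs && i + 1L <= n) {
        pid <- pid + 1L
        units[[length(units) + 1L]] <- c(i, i + 1L)
        unit_of[c(i, i + 1L)] <- pid
        i <- i + 2L
      } else {
        units[[length(units) + 1L]] <- i
        unit_of[i] <- 0L
        i <- i + 1L
      }
    }
    flank <- 10L
    m5 <- .runif_int(config$mature_len[1], config$mature_len[2], n)
    m3 <- .runif_int(config$mature_len[1], config$mature_len[2], n)
    loop <- .runif_int(12L, 18L, n)
    wid <- flank + m5 + loop + m3 + flank
    pri_s <- integer(n)
    pos <- .runif_int(200L, 400L)
    for (u in units) {
      pri_s[u[1L]] <- pos
      if (length(u) == 2L) {
        pri_s[u[2L]] <- pos + wid[u[1L]] + 100L
        pos <- pri_s[u[2L]] + wid[u[2L]]
      } else {
        pos <- pos + wid[u[1L]]
      }
      pos <- pos + .runif_int(200L, 500L)
    }
    if (pos > config$chrom_length)
      stop("infeasible packing: chrom_length too small for ", n,
           " loci with >= 200 nt spacing")
    strand_u <- sample(c("+", "-"), length(units), replace = TRUE)
    str <- character(n)
    for (j in seq_along(units)) str[units[[j]]] <- strand_u[j]

    ids <- sprintf("simmir-%03d", seq_len(n))
    pri <- GRanges("chrsim", IRanges(pri_s, width = wid), str)
    names(pri) <- ids
    # arm order along the genome follows the strand: 5p arm is 5'-most
    # in transcript orientation
    a1_s <- pri_s + flank
    a1_e <- a1_s + ifelse(str == "+", m5, m3) - 1L
    a2_s <- a1_e + loop + 1L
    a2_e <- a2_s + ifelse(str == "+", m3, m5) - 1L
    arm1 <- ifelse(str == "+", "5p", "3p")
    arm2 <- ifelse(str == "+", "3p", "5p")
    mature <- GRanges("chrsim",
                      IRanges(c(a1_s, a2_s), c(a1_e, a2_e)),
                      c(str, str),
                      locus_id = c(ids, ids),
                      arm = c(arm1, arm2),
                      name = paste0(c(ids, ids), "-", c(arm1, arm2)))
    genome <- DNAStringSet(.random_dna(config$chrom_length))
    names(genome) <- "chrsim"
    truth <- data.frame(locus_id = ids, start = pri_s,
                        end = pri_s + wid - 1L, strand = str,
                        pair = ifelse(unit_of > 0L, unit_of, NA_integer_))
    list(genome = genome, loci = mir_loci(pri, mature), truth = truth)
  })
}

#' Simulate an aligned small-RNA read library
#'
#' Draws reads from the category mix of the configuration: window-category
#' reads are placed uniformly among start positions that keep the read
#' entirely inside its category's window at its locus (lengths from
#' `read_len`, clipped to the window); `BACKGROUND` reads land at least
#' 100 nt from every locus; multi-locus reads (see [sim_config]) sit in the
#' gap of a clustered locus pair, within 50 nt of both and inside no window.
#' The RNG is seeded with `config$seed + 1` so the library is reproducible
#' independently of annotation generation.
#'
#' @param config A [sim_config].
#' @param ann A [gen_annotation()] result.
#' @return A list: `reads` (a [GenomicRanges::GRanges] with `read_id`) and
#'   `truth` (data.frame: `read_id`, true `category`, true `locus_id`;
#'   multi-locus reads have category `UNASSIGNED` and both loci, comma
#'   separated).
#' @export
simulate_reads <- function(config, ann) {
  stopifnot(inherits(config, "sim_config"))
  regions <- derive_regions(ann$loci, quant_params())
  pri <- ann$loci$pri
  pairs <- split(ann$truth$locus_id[!is.na(ann$truth$pair)],
                 ann$truth$pair[!is.na(ann$truth$pair)])
  # intergenic space: anything >= 100 nt from every pri-miR interval
  excl <- IRanges(pmax(start(pri) - 100L, 1L),
                  pmin(end(pri) + 100L, config$chrom_length))
  free <- IRanges::gaps(IRanges::reduce(excl), start = 1L,
                        end = config$chrom_length)
  # window lookup: (locus, category) -> region row
  rkey <- paste(mcols(regions)$locus_id, mcols(regions)$category)
  withr::with_seed(config$seed + 1L, {
    nr <- config$reads_per_library
    multi <- if (length(pairs)) runif(nr) < config$multi_locus_fraction
             else rep(FALSE, nr)
    cats <- sample(names(config$category_mix), nr, replace = TRUE,
                   prob = config$category_mix)
    st <- integer(nr); len <- integer(nr); strd <- character(nr)
    true_cat <- character(nr); true_loc <- character(nr)
    rid <- sprintf("read%06d", seq_len(nr))
    rlen <- config$read_len
    for (i in seq_len(nr)) {
      L <- .runif_int(rlen[1], rlen[2])
      if (multi[i]) {
        # centred in the 100-nt gap of a clustered pair: within 50 nt of
        # both loci, clear of both inward-extending moR windows
        pr <- pairs[[sample.int(length(pairs), 1L)]]
        e1 <- end(pri[pr[1L]])
        lo <- max(29L, 51L - L)
        hi <- min(51L, 73L - L)
        st[i] <- e1 + .runif_int(lo, hi)
        len[i] <- L
        strd[i] <- as.character(strand(pri[pr[1L]]))
        true_cat[i] <- "UNASSIGNED"
        true_loc[i] <- paste(pr, collapse = ",")
      } else if (cats[i] == "BACKGROUND") {
        ok <- width(free) >= L
        cand <- which(ok)
        j <- cand[sample.int(length(cand), 1L,
                             prob = width(free)[cand] - L + 1L)]
        st[i] <- start(free)[j] +
          sample.int(width(free)[j] - L + 1L, 1L) - 1L
        len[i] <- L
        strd[i] <- sample(c("+", "-"), 1L)
        true_cat[i] <- "BACKGROUND"
        true_loc[i] <- NA_character_
      } else {
        lid <- names(pri)[sample.int(length(pri), 1L)]
        w <- regions[match(paste(lid, cats[i]), rkey)]
        Lc <- min(L, width(w))
        st[i] <- start(w) + sample.int(width(w) - Lc + 1L, 1L) - 1L
        len[i] <- Lc
        strd[i] <- as.character(strand(w))
        true_cat[i] <- cats[i]
        true_loc[i] <- lid
      }
    }
    reads <- GRanges("chrsim", IRanges(st, width = len), strd, read_id = rid)
    truth <- data.frame(read_id = rid, category = true_cat,
                        locus_id = true_loc)
    list(reads = reads, truth = truth)
  })
}

#' Configuration for synthetic 3'UTR sets
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 2000).
#' @param utr_len Range of UTR lengths in nt (default 300-800).
#' @param planted_pattern DNA seed-match 7-mer planted into a fraction of
#'   the UTRs (default the seed-match of window 2 of the bundled synthetic
#'   small RNA, `TGGTACA`).
#' @param plant_rate Fraction of genes receiving one planted site
#'   (default 0.03).
#' @return An object of class `utr_sim_config`.
#' @export
utr_sim_config <- function(seed = 1L, n_genes = 2000L,
                           utr_len = c(300L, 800L),
                           planted_pattern = "TGGTACA",
                           plant_rate = 0.03) {
  stopifnot(n_genes >= 1L, utr_len[1] >= 7L, utr_len[1] <= utr_len[2],
            plant_rate >= 0, plant_rate <= 1,
            nchar(planted_pattern) == 7L)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 utr_len = as.integer(utr_len),
                 planted_pattern = toupper(planted_pattern),
                 plant_rate = plant_rate),
            class = "utr_sim_config")
}

#' Generate synthetic 3'UTR sequences with planted seed matches
#'
#' UTRs are i.i.d.-uniform random DNA; a `plant_rate` fraction of genes
#' receive one exact copy of the planted seed-match pattern at a uniform
#' position (substituted in place, preserving length). Background chance
#' occurrences of any 7-mer arise at the expected rate of roughly
#' `1 - (1 - 4^-7)^(L-6)` per gene of length L.
#'
#' @param config A [utr_sim_config].
#' @return A list: `utrs` (named [Biostrings::DNAStringSet]) and `truth`
#'   (data.frame: `gene`, `planted`, `plant_pos`).
#' @export
gen_utrs <- function(config = utr_sim_config()) {
  stopifnot(inherits(config, "utr_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    lens <- .runif_int(config$utr_len[1], config$utr_len[2], n)
    big <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
    stops <- cumsum(lens)
    seqs <- substring(paste(big, collapse = ""),
                      c(1L, head(stops, -1L) + 1L), stops)
    planted <- runif(n) < config$plant_rate
    pos <- rep(NA_integer_, n)
    for (i in which(planted)) {
      pos[i] <- sample.int(lens[i] - 6L, 1L)
      substr(seqs[i], pos[i], pos[i] + 6L) <- config$planted_pattern
    }
    ids <- sprintf("gene%05d", seq_len(n))
    utrs <- DNAStringSet(seqs)
    names(utrs) <- ids
    list(utrs = utrs,
         truth = data.frame(gene = ids, planted = planted, plant_pos = pos))
  })
}

#' Configuration for synthetic differential-expression tables
#'
#' Encodes the effect structure of a small-RNA over-expression array:
#' planted target genes are down-regulated with elevated probability
#' `p_down_target`, background genes with `p_down_background`; genes not
#' down-regulated are up-regulated with probability `p_up` regardless of
#' planting. Fold changes and adjusted p values are drawn so that the
#' thresholded class of every generated row equals the intended class
#' exactly (regulated rows strictly pass the default thresholds, unchanged
#' rows strictly fail both).
#'
#' @param seed Integer seed.
#' @param p_down_target P(down) for planted targets (default 0.5).
#' @param p_down_background P(down) for other genes (default 0.05).
#' @param p_up P(up) among genes not down (default 0.05).
#' @param fc_magnitude Fold-change magnitude range for regulated genes
#'   (default 1.4-4, strictly above the 1.3 cutoff).
#' @param fc_null Magnitude range for unchanged genes (default 1-1.25).
#' @param adjp_regulated Adjusted-p range for regulated genes (default
#'   1e-8 to 1.5e-3, strictly below the 0.002 cutoff).
#' @param adjp_null Adjusted-p range for unchanged genes (default 5e-3 to 1).
#' @param detected_rate Probability a gene is detected on the array
#'   (default 0.9).
#' @return An object of class `de_sim_config`.
#' @export
de_sim_config <- function(seed = 1L, p_down_target = 0.5,
                          p_down_background = 0.05, p_up = 0.05,
                          fc_magnitude = c(1.4, 4),
                          fc_null = c(1, 1.25),
                          adjp_regulated = c(1e-8, 1.5e-3),
                          adjp_null = c(5e-3, 1),
                          detected_rate = 0.9) {
  stopifnot(p_down_target >= 0, p_down_target <= 1,
            p_down_background >= 0, p_down_background <= 1,
            p_up >= 0, max(p_down_target, p_down_background) + p_up <= 1,
            fc_magnitude[1] > 1.3, fc_null[2] <= 1.3,
            adjp_regulated[2] < 0.002, adjp_null[1] >= 0.002,
            detected_rate >= 0, detected_rate <= 1)
  structure(list(seed = as.integer(seed), p_down_target = p_down_target,
                 p_down_background = p_down_background, p_up = p_up,
                 fc_magnitude = fc_magnitude, fc_null = fc_null,
                 adjp_regulated = adjp_regulated, adjp_null = adjp_null,
                 detected_rate = detected_rate),
            class = "de_sim_config")
}

#' Generate a synthetic differential-expression table
#'
#' @param config A [de_sim_config].
#' @param gene_truth Per-gene truth from [gen_utrs()] (needs columns `gene`
#'   and `planted`).
#' @return A list: `de` (data.frame: `gene`, `fold_change` signed magnitude,
#'   `adj_p`, `detected`) and `truth` (data.frame: `gene`, intended `class`
#'   among detected genes, `NOT_DETECTED` otherwise).
#' @export
gen_de_table <- function(config, gene_truth) {
  stopifnot(inherits(config, "de_sim_config"),
            all(c("gene", "planted") %in% names(gene_truth)))
  withr::with_seed(config$seed, {
    n <- nrow(gene_truth)
    pd <- ifelse(gene_truth$planted, config$p_down_target,
                 config$p_down_background)
    u <- runif(n)
    cls <- ifelse(u < pd, "DOWN",
           ifelse(u < pd + config$p_up, "UP", "UNCHANGED"))
    mag <- ifelse(cls == "UNCHANGED",
                  runif(n, config$fc_null[1], config$fc_null[2]),
                  runif(n, config$fc_magnitude[1], config$fc_magnitude[2]))
    sgn <- ifelse(cls == "DOWN", -1,
           ifelse(cls == "UP", 1, sample(c(-1, 1), n, replace = TRUE)))
    adj_p <- ifelse(cls == "UNCHANGED",
                    runif(n, config$adjp_null[1], config$adjp_null[2]),
                    runif(n, config$adjp_regulated[1],
                          config$adjp_regulated[2]))
    detected <- runif(n) < config$detected_rate
    de <- data.frame(gene = gene_truth$gene, fold_change = sgn * mag,
                     adj_p = adj_p, detected = detected)
    truth <- data.frame(gene = gene_truth$gene,
                        class = ifelse(detected, cls, "NOT_DETECTED"))
    list(de = de, truth = truth)
  })
}
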