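gff_lines <- function(...) paste(c("##gff-version 3", ...), collapse = "\n")

gff_rec <- function(chrom, type, s, e, strand, attr) {
  paste(chrom, "test", type, s, e, ".", strand, ".", attr, sep = "\t")
}

write_gff <- function(txt) {
  f <- tempfile(fileext = ".gff3")
  writeLines(txt, f)
  f
}

test_that("GFF3 parsing converts coordinates and resolves arms", {
  f <- write_gff(gff_lines(
    gff_rec("chr1", "miRNA_primary_transcript", 1001, 1100, "+",
            "ID=MI0001;Name=mmu-mir-1"),
    gff_rec("chr1", "miRNA", 1001, 1022, "+",
            "ID=MIMAT1;Name=mmu-miR-1-5p;Derives_from=MI0001"),
    gff_rec("chr1", "miRNA", 1061, 1082, "+",
            "ID=MIMAT2;Name=mmu-miR-1-3p;Derives_from=MI0001")))
  loci <- read_mirbase_gff(f)
  expect_s3_class(loci, "mir_loci")
  expect_length(loci, 1)
  expect_equal(start(loci$pri), 1001)
  expect_equal(end(loci$pri), 1100)
  m <- loci$mature
  expect_equal(start(m[mcols(m)$arm == "5p"]), 1001)
  expect_equal(end(m[mcols(m)$arm == "5p"]), 1022)
  expect_equal(start(m[mcols(m)$arm == "3p"]), 1061)
  expect_equal(end(m[mcols(m)$arm == "3p"]), 1082)
})

test_that("a locus may carry a single arm; windows follow the arms", {
  f <- write_gff(gff_lines(
    gff_rec("chr1", "miRNA_primary_transcript", 2001, 2090, "+",
            "ID=MI0002;Name=mmu-mir-2"),
    gff_rec("chr1", "miRNA", 2051, 2072, "+",
            "ID=MIMAT3;Name=mmu-miR-2-3p;Derives_from=MI0002")))
  loci <- read_mirbase_gff(f)
  expect_equal(mcols(loci$mature)$arm, "3p")
  r <- derive_regions(loci)
  expect_setequal(as.character(mcols(r)$category), c("MIR3P", "MOR3P"))
})

test_that("minus-strand arms come from name suffixes, not genomic order", {
  # on the minus strand the 5p arm is the genomically *rightmost* mature
  f <- write_gff(gff_lines(
    gff_rec("chr2", "miRNA_primary_transcript", 5001, 5100, "-",
            "ID=MI0003;Name=mmu-mir-3"),
    gff_rec("chr2", "miRNA", 5011, 5032, "-",
            "ID=MIMAT4;Name=mmu-miR-3-3p;Derives_from=MI0003"),
    gff_rec("chr2", "miRNA", 5071, 5092, "-",
            "ID=MIMAT5;Name=mmu-miR-3-5p;Derives_from=MI0003")))
  loci <- read_mirbase_gff(f)
  m <- loci$mature
  expect_equal(start(m[mcols(m)$arm == "5p"]), 5071)
  expect_equal(start(m[mcols(m)$arm == "3p"]), 5011)

  # without suffixes, transcript orientation decides: 5'-most mature = 5p
  f2 <- write_gff(gff_lines(
    gff_rec("chr2", "miRNA_primary_transcript", 5001, 5100, "-",
            "ID=MI0004;Name=mmu-mir-4"),
    gff_rec("chr2", "miRNA", 5011, 5032, "-",
            "ID=MIMAT6;Name=mmu-miR-4a;Derives_from=MI0004"),
    gff_rec("chr2", "miRNA", 5071, 5092, "-",
            "ID=MIMAT7;Name=mmu-miR-4b;Derives_from=MI0004")))
  m2 <- read_mirbase_gff(f2)$mature
  expect_equal(start(m2[mcols(m2)$arm == "5p"]), 5071)
})

test_that("malformed lines and orphan matures are reported", {
  f <- write_gff(gff_lines(
    gff_rec("chr1", "miRNA_primary_transcript", 1001, 1100, "+",
            "ID=MI0001"),
    "chr1\tbroken line without nine fields"))
  expect_error(read_mirbase_gff(f), "line 3")

  f2 <- write_gff(gff_lines(
    gff_rec("chr1", "miRNA_primary_transcript", 1001, 1100, "+",
            "ID=MI0001;Name=mmu-mir-1"),
    gff_rec("chr1", "miRNA", 1001, 1022, "+",
            "ID=MIMAT1;Name=x-5p;Derives_from=MI0001"),
    gff_rec("chr1", "miRNA", 3001, 3022, "+",
            "ID=MIMAT9;Name=y-5p;Derives_from=MI9999")))
  expect_warning(loci <- read_mirbase_gff(f2), "no resolvable")
  expect_length(loci$mature, 1)
})

test_that("derived windows match hand interval arithmetic", {
  r <- derive_regions(make_locus())
  df <- as.data.frame(r)
  get <- function(cat) unlist(df[df$category == cat, c("start", "end")],
                              use.names = FALSE)
  expect_equal(get("MIR5P"), c(998, 1025))
  expect_equal(get("MOR5P"), c(966, 1004))
  expect_equal(get("MIR3P"), c(1058, 1085))
  expect_equal(get("MOR3P"), c(1079, 1117))
})

test_that("window geometry: moR windows are 39 nt, miR windows arm + 6", {
  for (str in c("+", "-")) {
    r <- derive_regions(make_locus(strand = str))
    df <- as.data.frame(r)
    expect_equal(df$width[df$category %in% c("MOR5P", "MOR3P")], c(39, 39))
    expect_equal(df$width[df$category == "MIR5P"], 22 + 6)
    expect_equal(df$width[df$category == "MIR3P"], 22 + 6)
    # same-arm miR/moR windows overlap by exactly 7 nt
    for (arm in c("5P", "3P")) {
      mir <- r[mcols(r)$category == paste0("MIR", arm)]
      mor <- r[mcols(r)$category == paste0("MOR", arm)]
      ov <- width(pintersect(mir, mor))
      expect_equal(ov, 7)
    }
  }
})

test_that("no read-length interval fits in both a miR and a moR window", {
  # exhaustive enumeration of all contained sub-intervals of length 14-30
  for (str in c("+", "-")) {
    r <- derive_regions(make_locus(strand = str))
    for (arm in c("5P", "3P")) {
      mir <- r[mcols(r)$category == paste0("MIR", arm)]
      mor <- r[mcols(r)$category == paste0("MOR", arm)]
      for (L in 14:30) {
        for (s in start(mor):(end(mor) - L + 1L)) {
          in_mir <- s >= start(mir) && (s + L - 1L) <= end(mir)
          expect_false(in_mir)
        }
        if (end(mir) - start(mir) + 1L >= L) {
          for (s in start(mir):(end(mir) - L + 1L)) {
            in_mor <- s >= start(mor) && (s + L - 1L) <= end(mor)
            expect_false(in_mor)
          }
        }
      }
    }
  }
})

test_that("minus-strand windows mirror reflected plus-strand windows", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      m5s <- sample(500:600, 1)
      m5 <- c(m5s, m5s + sample(18:26, 1) - 1L)
      m3s <- m5[2] + sample(10:20, 1)
      m3 <- c(m3s, m3s + sample(18:26, 1) - 1L)
      pri <- c(m5[1] - 10L, m3[2] + 10L)
      plus <- make_locus("+", pri = pri, m5 = m5, m3 = m3)
      # reflect through position T: x -> T - x + 1 swaps strand geometry
      T <- 2000L
      refl <- function(iv) c(T - iv[2] + 1L, T - iv[1] + 1L)
      minus <- make_locus("-", pri = refl(pri), m5 = refl(m5), m3 = refl(m3))
      rp <- as.data.frame(derive_regions(plus))
      rm <- as.data.frame(derive_regions(minus))
      for (cat in c("MIR5P", "MIR3P", "MOR5P", "MOR3P")) {
        p <- rp[rp$category == cat, ]
        m <- rm[rm$category == cat, ]
        expect_equal(c(m$start, m$end), c(T - p$end + 1L, T - p$start + 1L))
      }
    }
  })
})

test_that("locus index answers distance queries like a brute-force scan", {
  # empty index
  empty <- build_locus_index(mir_loci(GRanges(), GRanges()))
  q <- GRanges("chr1", IRanges(100, 120), "+")
  expect_warning(res <- query_loci(empty, q), "not in index")
  expect_equal(res[[1]], character(0))

  loci <- make_locus()
  idx <- build_locus_index(loci)
  # overlapping query, D = 0
  expect_equal(query_loci(idx, GRanges("chr1", IRanges(1000, 1019), "+"),
                          0)[[1]], "locA")
  # 50 nt gap included, 51 excluded (pri starts at 995)
  expect_equal(query_loci(idx, GRanges("chr1", IRanges(920, 944), "+"),
                          50)[[1]], "locA")
  expect_equal(query_loci(idx, GRanges("chr1", IRanges(919, 943), "+"),
                          50)[[1]], character(0))

  # randomized agreement with the brute-force gap-distance oracle
  cf <- sim_config(seed = 5, n_loci = 15, multi_locus_fraction = 0)
  ann <- gen_annotation(cf)
  idx2 <- build_locus_index(ann$loci)
  withr::with_seed(7, {
    qs <- GRanges("chrsim",
                  IRanges(sample(1:90000, 200), width = sample(14:30, 200,
                                                               TRUE)),
                  sample(c("+", "-"), 200, TRUE))
  })
  got <- query_loci(idx2, qs)
  pri <- ann$loci$pri
  for (i in seq_along(qs)) {
    want <- names(pri)[vapply(seq_along(pri), function(j)
      as.character(strand(qs)[i]) == as.character(strand(pri)[j]) &&
        gap_dist(start(qs)[i], end(qs)[i],
                 start(pri)[j], end(pri)[j]) <= 50L, logical(1))]
    expect_setequal(got[[i]], want)
  }
})

test_that("duplicate locus ids are rejected", {
  pri <- GRanges("chr1", IRanges(c(100, 500), c(200, 600)), "+")
  names(pri) <- c("locA", "locA")
  mat <- GRanges("chr1", IRanges(c(110, 510), c(130, 530)), "+",
                 locus_id = "locA", arm = c("5p", "3p"))
  expect_error(mir_loci(pri, mat), "duplicate locus ids")
})

test_that("BED export round-trips window coordinates", {
  r <- derive_regions(make_locus())
  f <- tempfile(fileext = ".bed")
  write_regions_bed(r, f)
  back <- rtracklayer::import(f, format = "BED")
  expect_equal(start(back), start(r))
  expect_equal(end(back), end(r))
  expect_setequal(back$name, paste0("locA:", mcols(r)$category))
  # raw BED text is 0-based half-open
  raw <- read.delim(f, header = FALSE)
  expect_equal(sort(raw$V2), sort(start(r) - 1L))
})
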