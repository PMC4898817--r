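ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming removes full and truncated terminal matches", {
  ins <- "ACGTACGTGGCCAATT"
  expect_equal(trim_adapter(paste0(ins, ADAPTER), ADAPTER), ins)
  expect_equal(trim_adapter(ins, ADAPTER), ins)
  # truncated terminal adapter: only its first 8 bases present
  expect_equal(trim_adapter(paste0(ins, substr(ADAPTER, 1, 8)), ADAPTER), ins)
  # below min_overlap the terminal fragment is left alone
  short <- paste0(ins, substr(ADAPTER, 1, 5))
  expect_equal(trim_adapter(short, ADAPTER), short)
  # an interior false seed (adapter start followed by a mismatch and more
  # read) is not a match; the later real adapter is
  tricky <- paste0("AAAA", substr(ADAPTER, 1, 6), "CCCCAAAA", ADAPTER)
  expect_equal(trim_adapter(tricky, ADAPTER),
               paste0("AAAA", substr(ADAPTER, 1, 6), "CCCCAAAA"))
  expect_error(trim_adapter("", ADAPTER), "empty read")
  expect_error(trim_adapter("ACGT", "ACG", min_overlap = 6), "min_overlap")
})

test_that("insert filter keeps inserts longer than 13 bases", {
  expect_false(filter_insert(strrep("A", 13)))
  expect_true(filter_insert(strrep("A", 14)))
  expect_false(filter_insert(""))
  expect_equal(filter_insert(c("ACGTACGTACGTAC", "ACG")), c(TRUE, FALSE))
})

test_that("even allotment splits a read's unit weight over candidates", {
  expect_equal(allot_weights("r1", c("a", "b"))$weight, c(0.5, 0.5))
  expect_equal(allot_weights("r1", "a")$weight, 1.0)
  expect_equal(sum(allot_weights("r1", letters[1:4])$weight), 1.0)
  expect_equal(nrow(allot_weights("r1", character(0))), 0)
})

test_that("containment classification matches the window worked example", {
  loci <- make_locus()
  r <- derive_regions(loci)
  segs <- GRanges("chr1",
                  IRanges(c(999, 971, 1040, 999), c(1019, 990, 1055, 1019)),
                  c("+", "+", "+", "-"),
                  read_id = c("a", "b", "c", "d"))
  got <- classify_reads(segs, r, "locA")
  expect_equal(as.character(got),
               c("MIR5P", "MOR5P", "UNASSIGNED", "UNASSIGNED"))
  # boundary: a segment exactly filling the miR window is contained
  full <- GRanges("chr1", IRanges(998, 1025), "+", read_id = "e")
  expect_equal(as.character(classify_reads(full, r, "locA")), "MIR5P")
  over <- GRanges("chr1", IRanges(997, 1025), "+", read_id = "f")
  expect_equal(as.character(classify_reads(over, r, "locA")), "UNASSIGNED")
})

test_that("candidate search honours the 50-bp boundary", {
  loci <- make_locus()  # pri [995, 1090]
  idx <- build_locus_index(loci)
  p <- quant_params()
  at_gap <- function(g) GRanges("chr1", IRanges(995 - g - 20, 995 - g - 1),
                                "+", read_id = "r")
  expect_equal(find_candidate_loci(at_gap(50), idx, p)[[1]], "locA")
  expect_equal(find_candidate_loci(at_gap(51), idx, p)[[1]], character(0))
  expect_equal(find_candidate_loci(
    GRanges("chr1", IRanges(1000, 1020), "+", read_id = "r"),
    idx, p)[[1]], "locA")
})

test_that("tabulation sums weights and drops unassigned pairs", {
  empty <- tabulate_counts(data.frame(read_id = character(0),
                                      locus_id = character(0),
                                      weight = numeric(0),
                                      category = character(0)))
  expect_equal(nrow(empty), 0)
  one <- tabulate_counts(data.frame(read_id = "r1", locus_id = "locA",
                                    weight = 1, category = "MIR5P"))
  expect_equal(one$count, 1.0)
  split2 <- tabulate_counts(data.frame(
    read_id = "r1", locus_id = c("locA", "locB"),
    weight = 0.5, category = "MOR5P"))
  expect_equal(split2$count, c(0.5, 0.5))
  expect_equal(sum(split2$count), 1.0)
})

test_that("RPMR normalization scales to a million region reads", {
  ct <- structure(data.frame(library = "lib1",
                             locus = c("a", "b"),
                             category = "MIR5P",
                             count = c(176, 1e6 - 176)),
                  class = c("count_table", "data.frame"))
  r <- normalize_rpmr(ct)
  expect_equal(r$rpmr[1], 176)
  ct2 <- ct
  ct2$count <- ct2$count * 2  # doubled depth, same proportions
  expect_equal(normalize_rpmr(ct2)$rpmr[1], 176)
  expect_equal(sum(r$rpmr), 1e6)
  ct0 <- ct
  ct0$count <- 0
  expect_error(normalize_rpmr(ct0), "no region-mapped reads")
})

test_that("per-read weights sum to one across the pipeline", {
  cf <- sim_config(seed = 11, n_loci = 12, reads_per_library = 2000)
  ann <- gen_annotation(cf)
  sim <- simulate_reads(cf, ann)
  q <- quantify_smallrna(sim$reads, ann$loci)
  w <- tapply(q$assignments$weight, q$assignments$read_id, sum)
  expect_true(all(abs(w - 1) < 1e-12))
  expect_equal(sum(q$counts$rpmr), 1e6)
})

test_that("pipeline counts equal the naive reference exactly", {
  cf <- sim_config(seed = 3, n_loci = 8, reads_per_library = 1500,
                   chrom_length = 50000)
  ann <- gen_annotation(cf)
  sim <- simulate_reads(cf, ann)
  q <- quantify_smallrna(sim$reads, ann$loci)
  got <- data.frame(locus = q$counts$locus,
                    category = as.character(q$counts$category),
                    count = q$counts$count)
  want <- naive_quant(sim$reads, ann$loci)
  got <- got[order(got$locus, got$category), ]
  rownames(got) <- rownames(want) <- NULL
  want$category <- as.character(want$category)
  expect_equal(got, want)
})

test_that("classification recovers simulator truth on unambiguous reads", {
  cf <- sim_config(seed = 21, n_loci = 15, reads_per_library = 4000,
                   multi_locus_fraction = 0)
  ann <- gen_annotation(cf)
  sim <- simulate_reads(cf, ann)
  q <- quantify_smallrna(sim$reads, ann$loci)
  m <- merge(q$assignments, sim$truth, by = "read_id")
  expect_gt(nrow(m), 0)
  expect_true(all(as.character(m$category.x) == m$category.y))
  expect_true(all(m$locus_id.x == m$locus_id.y))
  # background reads acquire no assignment at all
  bg <- sim$truth$read_id[sim$truth$category == "BACKGROUND"]
  expect_false(any(bg %in% q$assignments$read_id))
})

test_that("multi-locus reads are split evenly and count nowhere", {
  cf <- sim_config(seed = 31, n_loci = 20, reads_per_library = 3000,
                   multi_locus_fraction = 0.1)
  ann <- gen_annotation(cf)
  sim <- simulate_reads(cf, ann)
  multi <- grepl(",", sim$truth$locus_id)
  expect_gt(sum(multi), 100)
  q <- quantify_smallrna(sim$reads, ann$loci)
  a <- q$assignments[q$assignments$read_id %in% sim$truth$read_id[multi], ]
  expect_true(all(a$weight == 0.5))
  expect_true(all(as.character(a$category) == "UNASSIGNED"))
  # and each sits within 50 nt of both named loci
  pri <- ann$loci$pri
  rd <- sim$reads[match(unique(a$read_id), mcols(sim$reads)$read_id)]
  tr <- sim$truth[match(unique(a$read_id), sim$truth$read_id), ]
  for (i in seq_len(min(50, length(rd)))) {
    for (lid in strsplit(tr$locus_id[i], ",")[[1]]) {
      expect_lte(gap_dist(start(rd)[i], end(rd)[i],
                          start(pri[lid]), end(pri[lid])), 50L)
    }
  }
})
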