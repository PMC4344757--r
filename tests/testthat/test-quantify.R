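test_that("RPKUM arithmetic matches the definition exactly", {
  # 100 reads over 1000 mappable bases in a 1e7-read library:
  # 100 * 1e9 / (1000 * 1e7) = 10
  expect_equal(compute_rpkum(100, 1000, 1e7), 10.0)
  expect_equal(compute_rpkum(0, 1000, 1e7), 0.0)
  # vectorized
  expect_equal(compute_rpkum(c(100, 50), c(1000, 500), 1e7), c(10, 10))
  # zero mappable bases: undefined, not zero and not infinite
  expect_true(is.na(compute_rpkum(7, 0, 1e7)))
  expect_error(compute_rpkum(1, 100, 0), "positive")
  expect_error(compute_rpkum(1, -5, 10), "nonnegative")
})

test_that("RPKUM equals RPKM for a fully mappable gene", {
  set.seed(51)
  genome <- rand_genome(2000)
  m <- exon1_model("G", "chr1", 200, 1200)   # 1000-base single-exon gene
  tr <- compute_mappability(genome, NULL, k = 50, epsilon = 2)
  mc <- count_mappable_bases(build_consensus_model(m), tr)
  expect_equal(mc$mappable_bases, 1000)      # fully mappable
  n_reads <- 300; total <- 2e6
  rpkum <- compute_rpkum(n_reads, mc$mappable_bases, total)
  rpkm <- n_reads / ((1000 / 1e3) * (total / 1e6))
  expect_equal(rpkum, rpkm)
})

test_that("alignment records round-trip through TSV", {
  rec <- data.frame(read_id = c("r1", "r2"), chrom = "chr1",
                    start = c(10L, 40L),
                    block_starts = c("10", "40,120"),
                    block_ends = c("60", "70,140"),
                    mismatches = c(0L, 1L), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_alignment_tsv(rec, path)
  back <- read_alignment_tsv(path)
  expect_equal(back, rec)
  # missing columns rejected
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(rec[, 1:3], bad, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_error(read_alignment_tsv(bad), "must have columns")
})

test_that("read filter keeps unique mappable reads and the ledger balances", {
  set.seed(53)
  genome <- rand_genome(2000)
  models <- list(G = exon1_model("G", "chr1", 100, 600))
  tr <- compute_mappability(genome, NULL, k = 50, epsilon = 2)
  rec <- data.frame(
    read_id = c("keep", "multi", "multi", "intergenic"),
    chrom = "chr1",
    start = c(150L, 200L, 900L, 1200L),
    block_starts = c("150", "200", "900", "1200"),
    block_ends = c("200", "250", "950", "1250"),
    mismatches = 0L, stringsAsFactors = FALSE)
  mrs <- filter_reads(rec, tr, models, sample_id = "sA")
  expect_equal(mrs$sample_id, "sA")
  expect_equal(unname(mrs$gene_counts["G"]), 1L)
  expect_equal(mrs$total_reads, 3L)   # 3 distinct reads
  expect_equal(unname(mrs$ledger["retained"]), 1L)
  expect_equal(unname(mrs$ledger["dropped_multi"]), 1L)
  expect_equal(unname(mrs$ledger["dropped_nongenic"]), 1L)
  expect_equal(sum(mrs$ledger), mrs$total_reads)
})

test_that("reads at unmappable starts are dropped as unmappable", {
  set.seed(59)
  base <- rand_dna(700)
  dup <- substr(base, 101, 180)   # 80-base exact repeat
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(base, dup, rand_dna(60))))
  models <- list(G = exon1_model("G", "chr1", 50, 400))
  tr <- compute_mappability(genome, NULL, k = 50, epsilon = 0)
  expect_false(tr$genome$chr1[101])   # inside the repeat
  rec <- data.frame(read_id = "r", chrom = "chr1", start = 100L,
                    block_starts = "100", block_ends = "150",
                    mismatches = 0L, stringsAsFactors = FALSE)
  mrs <- filter_reads(rec, tr, models)
  expect_equal(unname(mrs$ledger["dropped_unmappable"]), 1L)
  expect_equal(unname(mrs$gene_counts["G"]), 0L)
})

test_that("a read whose length disagrees with the track's k is a hard error", {
  set.seed(61)
  genome <- rand_genome(500)
  models <- list(G = exon1_model("G", "chr1", 0, 400))
  tr <- compute_mappability(genome, NULL, k = 50, epsilon = 2)
  rec <- data.frame(read_id = "r", chrom = "chr1", start = 10L,
                    block_starts = "10", block_ends = "40",   # 30-base read
                    mismatches = 0L, stringsAsFactors = FALSE)
  expect_error(filter_reads(rec, tr, models), "k = 50")
})

test_that("spliced reads are certified through unique junction k-mers", {
  set.seed(67)
  genome <- rand_genome(3000)
  k <- 50
  m <- exon2_model("G", "chr1", 100, 400, 600, 1000)
  regions <- build_synthetic_regions(list(G = m), genome, k)
  tr <- compute_mappability(genome, regions, k = k, epsilon = 2)
  expect_true(any(tr$regions[[regions$junction_id]]))
  # read crossing the junction: 20 bases of donor, 30 of acceptor
  rec <- data.frame(read_id = "sp", chrom = "chr1", start = 380L,
                    block_starts = "380,600", block_ends = "400,630",
                    mismatches = 0L, stringsAsFactors = FALSE)
  mrs <- filter_reads(rec, tr, list(G = m))
  expect_equal(unname(mrs$ledger["retained"]), 1L)
  expect_equal(unname(mrs$gene_counts["G"]), 1L)
  # a spliced read at a junction nobody annotated is unmappable
  rec2 <- rec
  rec2$block_starts <- "380,700"; rec2$block_ends <- "400,730"
  mrs2 <- filter_reads(rec2, tr, list(G = m))
  expect_equal(unname(mrs2$ledger["dropped_unmappable"]), 1L)
})

test_that("naive counting trusts unique alignments that the filter rejects", {
  fx <- fig1a_scenario(seed = 1)
  naive <- count_reads_naive(fx$records, fx$models)
  track <- compute_mappability(fx$genome, fx$regions, k = 50, epsilon = 2)
  filtered <- filter_reads(fx$records, track, fx$models)
  expect_gt(naive[["PSG1"]], 0)
  expect_equal(unname(naive[["PSG1"]]), length(fx$truth$misaligned_reads))
  expect_equal(unname(filtered$gene_counts[["PSG1"]]), 0L)
  expect_equal(sum(filtered$ledger), filtered$total_reads)
})

test_that("expression matrix assembly flags unquantifiable genes", {
  mk_count <- function(gid, mb) structure(
    list(gene_id = gid, mappable_bases = mb, total_consensus_bases = 1000L,
         fraction = mb / 1000), class = "MappableBaseCount")
  mk_sample <- function(sid, counts, total) structure(
    list(sample_id = sid, gene_counts = counts, total_reads = total,
         ledger = c(retained = sum(counts), dropped_multi = 0L,
                    dropped_unmappable = 0L,
                    dropped_nongenic = total - sum(counts))),
    class = "MappableReadSet")
  counts1 <- c(A = 100L, B = 10L, C = 5L)
  counts2 <- c(A = 200L, B = 0L, C = 50L)
  em <- build_expression_matrix(
    list(mk_sample("s1", counts1, 1e6), mk_sample("s2", counts2, 2e6)),
    list(mk_count("A", 1000L), mk_count("B", 30L), mk_count("C", 400L)),
    min_bases = 50)
  expect_equal(dim(em$rpkum), c(3, 2))
  expect_equal(em$rpkum["A", "s1"], 100 * 1e9 / (1000 * 1e6))
  expect_equal(em$rpkum["C", "s2"], 50 * 1e9 / (400 * 2e6))
  expect_equal(unname(em$unquantifiable), c(FALSE, TRUE, FALSE))
  # missing base count is an error
  expect_error(build_expression_matrix(
    list(mk_sample("s1", counts1, 1e6)),
    list(mk_count("A", 1000L), mk_count("B", 30L))), "missing mappable-base")
})

test_that("transcription calls apply all three thresholds and the recurrence floor", {
  mats <- function(counts, rpkum, mb) structure(
    list(rpkum = rpkum, counts = counts,
         mappable_bases = stats::setNames(mb, rownames(counts)),
         total_reads = stats::setNames(rep(1e6, ncol(counts)),
                                       colnames(counts)),
         unquantifiable = stats::setNames(mb < 50, rownames(counts))),
    class = "ExpressionMatrix")
  genes <- c("pass", "few_reads", "low_rpkum", "few_bases")
  samples <- paste0("s", 1:3)
  counts <- matrix(c(50, 50, 49,     # exactly at / below the 50-read line
                     49, 49, 49,
                     60, 60, 60,
                     80, 80, 80), 4, 3, byrow = TRUE,
                   dimnames = list(genes, samples))
  rpkum <- matrix(c(1.0, 1.0, 5.0,
                    2.0, 2.0, 2.0,
                    0.99, 0.99, 0.99,
                    9.0, 9.0, 9.0), 4, 3, byrow = TRUE,
                  dimnames = list(genes, samples))
  em <- mats(counts, rpkum, c(200L, 200L, 200L, 49L))
  calls <- call_transcribed(em, min_bases = 50, min_reads = 50,
                            min_rpkum = 1.0, recurrence_fraction = 0.10)
  expect_equal(calls$gene_id, genes)
  # "pass": samples 1 and 2 meet >=50 reads and >=1 RPKUM (boundary inclusive)
  expect_equal(calls$n_samples_transcribed, c(2L, 0L, 0L, 0L))
  expect_equal(calls$is_transcribed, c(TRUE, FALSE, FALSE, FALSE))
  # recurrence floor: floor(0.10 * 3) = 0 -> never below 1 sample
  expect_equal(calls$is_recurrent, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$unquantifiable, c(FALSE, FALSE, FALSE, TRUE))

  # with 80 samples the default 10% recurrence rule needs 8 samples
  big <- mats(matrix(50, 1, 80, dimnames = list("g", sprintf("s%02d", 1:80))),
              matrix(2, 1, 80, dimnames = list("g", sprintf("s%02d", 1:80))),
              200L)
  big$counts[1, 9:80] <- 0
  calls80 <- call_transcribed(big)
  expect_equal(calls80$n_samples_transcribed, 8L)
  expect_true(calls80$is_recurrent)
  big$counts[1, 8] <- 0
  expect_false(call_transcribed(big)$is_recurrent)
})

test_that("expression matrices round-trip through TSV", {
  m <- matrix(c(1.5, 0, 3.25, 10), 2, 2,
              dimnames = list(c("G1", "PSG1"), c("s1", "s2")))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  expect_equal(read_matrix_tsv(path), m)
})
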