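test_that("the Karlin-Altschul lambda solves its defining equation", {
  lam <- ka_lambda(2, -3)
  # sum_xy p_x p_y exp(lambda * s(x,y)) = 1 with match prob 1/4
  resid <- 0.25 * exp(2 * lam) + 0.75 * exp(-3 * lam) - 1
  expect_lt(abs(resid), 1e-9)
  expect_gt(lam, 0)
})

test_that("local alignment recovers planted subject intervals on both strands", {
  set.seed(71)
  query <- rand_dna(120)
  subject <- paste0(rand_dna(300), query, rand_dna(250))
  hits <- local_align(query, subject)
  best <- hits[which.min(hits$evalue), ]
  expect_equal(best$s_start, 300)
  expect_equal(best$s_end, 420)
  expect_equal(best$strand, "+")
  expect_lt(best$evalue, 1e-20)

  subject_rc <- paste0(rand_dna(100), revcomp_str(query), rand_dna(80))
  hits_rc <- local_align(query, subject_rc)
  best_rc <- hits_rc[which.min(hits_rc$evalue), ]
  expect_equal(best_rc$strand, "-")
  expect_equal(best_rc$s_start, 100)
  expect_equal(best_rc$s_end, 220)
})

test_that("pseudo-3' UTR is recovered exactly at zero divergence", {
  cfg <- simulation_config(seed = 404, n_parent_genes = 2,
                           pseudogene_plan = list(list(
                             class = "processed", divergence_rate = 0,
                             include_utr = TRUE)))
  sim <- simulate_genome(cfg)
  for (i in seq_len(nrow(sim$parent_map))) {
    pid <- sim$parent_map$pseudogene_id[i]
    gid <- sim$parent_map$parent_gene_id[i]
    ctx <- extract_context(sim$models[[pid]], sim$genome, flank = 10000)
    utr <- sim$truth$genes[[gid]]$utr
    p3 <- annotate_pseudo3utr(list(utr), ctx)
    ex <- sim$models[[pid]]$transcripts[[1]]
    expect_equal(unname(p3$interval["start"]), max(ex$end) - nchar(utr))
    expect_equal(unname(p3$interval["end"]), max(ex$end))
    expect_equal(p3$sequence, utr)
    expect_equal(p3$chrom, ex$chrom[1])
  }
})

test_that("pseudo-3' UTR recovery overlaps >=90% at 5% divergence", {
  cfg <- simulation_config(seed = 405, n_parent_genes = 2,
                           pseudogene_plan = list(list(
                             class = "processed", divergence_rate = 0.05,
                             include_utr = TRUE)))
  sim <- simulate_genome(cfg)
  for (i in seq_len(nrow(sim$parent_map))) {
    pid <- sim$parent_map$pseudogene_id[i]
    gid <- sim$parent_map$parent_gene_id[i]
    ctx <- extract_context(sim$models[[pid]], sim$genome, flank = 10000)
    utr <- sim$truth$genes[[gid]]$utr
    p3 <- annotate_pseudo3utr(list(utr), ctx)
    ex <- sim$models[[pid]]$transcripts[[1]]
    exp_start <- max(ex$end) - nchar(utr); exp_end <- max(ex$end)
    ov <- max(0, min(p3$interval["end"], exp_end) -
                 max(p3$interval["start"], exp_start))
    expect_gte(ov / nchar(utr), 0.9)
  }
})

test_that("no alignment above the E-value cutoff returns NULL", {
  set.seed(73)
  p3 <- annotate_pseudo3utr(list(rand_dna(200)),
                            list(seq = rand_dna(400), chrom = "chr1",
                                 start = 0L, end = 400L))
  expect_null(p3)
})

test_that("BLAST tabular output parses into the alignment record shape", {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(c("utr1", "ctx1", "98.5", "200", "3", "0",
                     "1", "200", "501", "700", "1e-100", "370"),
                   collapse = "\t"), path)
  hits <- parse_blast_tabular(path)
  expect_equal(hits$s_start, 500)   # to 0-based half-open
  expect_equal(hits$s_end, 700)
  expect_equal(hits$strand, "+")
  expect_equal(hits$evalue, 1e-100)
  # reversed subject coordinates mean a minus-strand hit
  writeLines(paste(c("utr1", "ctx1", "98.5", "200", "3", "0",
                     "1", "200", "700", "501", "1e-100", "370"),
                   collapse = "\t"), path)
  hits2 <- parse_blast_tabular(path)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$s_start, 500)
  expect_equal(hits2$s_end, 700)
})

test_that("miRNA FASTA loader normalizes RNA to DNA", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">mir-1 extra words", "UGAGGUAGUAGGUUGUAUAGUU",
               ">mir-2", "acgtacgtacgtacgtacgt"), path)
  m <- load_mirna_fasta(path)
  expect_equal(names(m), c("mir-1", "mir-2"))
  expect_equal(unname(m["mir-1"]), "TGAGGTAGTAGGTTGTATAGTT")
  expect_equal(unname(m["mir-2"]), "ACGTACGTACGTACGTACGT")
})

test_that("seed matching equals an independent brute-force oracle", {
  set.seed(79)
  for (rep in 1:5) {
    utr <- rand_dna(400)
    mirnas <- stats::setNames(vapply(1:8, function(i) rand_dna(22), ""),
                              sprintf("MIR%d", 1:8))
    got <- find_seed_matches(utr, mirnas)
    want <- oracle_seed_matches(utr, mirnas)
    cols <- c("mirna_id", "site_type", "start", "end")
    o <- function(d) d[do.call(order, d[cols]), cols, drop = FALSE]
    g <- o(got); w <- o(want)
    rownames(g) <- rownames(w) <- NULL
    expect_equal(g, w)
  }
})

test_that("site classes follow the canonical definitions", {
  # miRNA 5'->3': seed bases 2-7 = GAGGTA, base 8 = G
  mir <- c(let7 = "TGAGGTAGTAGGTTGTATAGTT")
  core <- revcomp_str("GAGGTA")          # TACCTC
  m8 <- "C"                              # complement of G (base 8)
  utr8 <- paste0("GGGG", m8, core, "A", "GGGG")      # 8mer
  utr7m8 <- paste0("GGGG", m8, core, "G", "GGGG")    # 7mer-m8, no A
  utr7a1 <- paste0("GGGG", "G", core, "A", "GGGG")   # 7mer-A1, no m8
  utr6 <- paste0("GGGG", "G", core, "G", "GGGG")     # bare 6mer
  for (u in list(c(utr8, "8mer"), c(utr7m8, "7mer-m8"),
                 c(utr7a1, "7mer-A1"), c(utr6, "6mer"))) {
    hit <- find_seed_matches(u[1], mir)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$site_type, u[2])
  }
  # 8mer site coordinates: starts at the m8 base (0-based 4), 8 bases long
  hit8 <- find_seed_matches(utr8, mir)
  expect_equal(hit8$start, 4L)
  expect_equal(hit8$end, 12L)
  expect_warning(find_seed_matches("ACGTACGT", c(short = "ACGTA")),
                 "shorter than 8")
})

test_that("shared miRNAs and top-expressed ranking behave as documented", {
  ps <- data.frame(mirna_id = c("m1", "m2", "m2"), stringsAsFactors = FALSE)
  gs <- data.frame(mirna_id = c("m2", "m3"), stringsAsFactors = FALSE)
  expect_equal(shared_mirnas(ps, gs), "m2")

  mat <- matrix(c(10, 10, 5, 1), 4, 1,
                dimnames = list(c("b", "a", "c", "d"), "s1"))
  # cutoff inside the tie on the mean -> both tied ids are kept
  expect_equal(top_expressed_mirnas(mat, n = 1), c("a", "b"))
  expect_equal(top_expressed_mirnas(mat, n = 3), c("a", "b", "c"))
  expect_error(top_expressed_mirnas(mat, n = 5))
})

test_that("pairwise correlation matches cor() on co-present samples", {
  set.seed(83)
  n <- 60
  x <- 2^rnorm(n, 4); y <- 2^(0.8 * log2(x) + rnorm(n, 0, 0.4))
  A <- matrix(x, 1, n, dimnames = list("P", sprintf("s%02d", 1:n)))
  B <- matrix(y, 1, n, dimnames = list("G", sprintf("s%02d", 1:n)))
  # knock some samples below presence in one side each
  A[1, 1:5] <- 0.5; B[1, 6:8] <- 0.2
  res <- pairwise_correlation(A, B, data.frame(id_a = "P", id_b = "G"),
                              min_present_samples = 20, presence_level = 1)
  co <- A[1, ] >= 1 & B[1, ] >= 1
  r_ref <- stats::cor(log2(A[1, co] + 1), log2(B[1, co] + 1))
  expect_equal(res$r, r_ref, tolerance = 1e-12)
  expect_equal(res$n_samples_used, sum(co))
  expect_false(res$excluded)
  # one-sided p for anti-correlation: lower tail of the t statistic
  t_ref <- r_ref * sqrt((sum(co) - 2) / (1 - r_ref^2))
  expect_equal(res$p_one_sided, stats::pt(t_ref, sum(co) - 2))
  # a strong positive correlation is NOT significant in this direction
  expect_gt(res$p_one_sided, 0.5)

  # too few co-present samples -> excluded, no p
  A2 <- A; A2[1, 1:45] <- 0
  res2 <- pairwise_correlation(A2, B, data.frame(id_a = "P", id_b = "G"))
  expect_true(res2$excluded)
  expect_true(is.na(res2$p_one_sided))
  # unknown ids are an error
  expect_error(pairwise_correlation(A, B, data.frame(id_a = "X", id_b = "G")),
               "unknown id_a")
})

test_that("anti-correlated pairs get small one-sided p-values", {
  set.seed(89)
  n <- 100
  z <- rnorm(n)
  A <- matrix(2^(4 - z), 1, n, dimnames = list("P", sprintf("s%03d", 1:n)))
  B <- matrix(2^(3 + z + rnorm(n, 0, 0.3)), 1, n,
              dimnames = list("M", sprintf("s%03d", 1:n)))
  res <- pairwise_correlation(A, B, data.frame(id_a = "P", id_b = "M"))
  expect_lt(res$r, -0.8)
  expect_lt(res$p_one_sided, 1e-10)
})

test_that("permutation null is reproducible and calibrated on planted structure", {
  sim <- simulate_cerna_expression(n_samples = 120, n_triples = 4,
                                   n_null_pairs = 12, seed = 97)
  pairs <- sim$pairs
  p1 <- permutation_null(sim$pseudogene_matrix, sim$gene_matrix, pairs,
                         n_permutations = 300, threshold = 0.3,
                         direction = "positive", seed = 5)
  p2 <- permutation_null(sim$pseudogene_matrix, sim$gene_matrix, pairs,
                         n_permutations = 300, threshold = 0.3,
                         direction = "positive", seed = 5)
  expect_identical(p1$null_counts, p2$null_counts)
  expect_identical(p1$empirical_p, p2$empirical_p)
  # 4 planted positive pairs out of 16: observed count is at least 4 and
  # beats the shuffled-pairing null
  expect_gte(p1$observed_count, 4)
  expect_lte(p1$empirical_p, 0.01)
  # negative direction finds the planted pseudogene-miRNA anti-correlations
  pm_pairs <- data.frame(id_a = sim$shared$pseudogene_id,
                         id_b = sim$shared$mirna_id, stringsAsFactors = FALSE)
  pn <- permutation_null(sim$pseudogene_matrix, sim$mirna_matrix, pm_pairs,
                         n_permutations = 300, threshold = 0.3,
                         direction = "negative", seed = 6)
  expect_gte(pn$observed_count, 4)
  expect_lte(pn$empirical_p, 0.01)
})

test_that("BH adjustment reproduces the hand-worked example", {
  # classic example: (0.01, 0.02, 0.03) all adjust to 0.03
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # order is preserved and NA passes through
  p <- c(0.04, NA, 0.001)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(p, "BH")[c(1, 3)])
  # monotone: q >= p, q <= 1
  set.seed(101)
  pr <- runif(50)
  qr <- bh_adjust(pr)
  expect_true(all(qr >= pr & qr <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("triple identification applies thresholds strictly and jointly", {
  cor_tbl <- function(a, b, r, p, excl = FALSE)
    data.frame(id_a = a, id_b = b, r = r, n_samples_used = 100L,
               p_one_sided = p, excluded = excl, stringsAsFactors = FALSE)
  shared <- data.frame(pseudogene_id = c("P1", "P2", "P3", "P4"),
                       parent_gene_id = c("G1", "G2", "G3", "G4"),
                       mirna_id = c("M1", "M2", "M3", "M4"),
                       stringsAsFactors = FALSE)
  cor_pg <- cor_tbl(paste0("P", 1:4), paste0("G", 1:4),
                    r = c(0.8, 0.30, 0.9, 0.7), p = 0.999)
  cor_pm <- cor_tbl(paste0("P", 1:4), paste0("M", 1:4),
                    r = c(-0.7, -0.8, -0.1, -0.75),
                    p = c(1e-8, 1e-8, 0.4, 1e-6))
  cor_gm <- cor_tbl(paste0("G", 1:4), paste0("M", 1:4),
                    r = c(-0.6, -0.7, -0.2, -0.65),
                    p = c(1e-5, 1e-5, 0.5, 1e-4))
  tri <- identify_cerna_triples(cor_pg, cor_pm, cor_gm, shared,
                                r_gene_threshold = 0.3, q_threshold = 0.05)
  # P2 fails: r == 0.30 is not strictly greater; P3 fails the q threshold
  expect_setequal(tri$pseudogene_id, c("P1", "P4"))
  expect_true(all(tri$r_pseudo_gene > 0.3))
  expect_true(all(tri$q_pseudo_mirna <= 0.05))
  # excluded pseudogene-gene correlation kills the triple
  cor_pg2 <- cor_pg; cor_pg2$excluded[1] <- TRUE
  tri2 <- identify_cerna_triples(cor_pg2, cor_pm, cor_gm, shared)
  expect_setequal(tri2$pseudogene_id, "P4")
})

test_that("planted ceRNA triples are recovered with no false positives", {
  sim <- simulate_cerna_expression(n_samples = 200, n_triples = 3,
                                   n_null_pairs = 10, seed = 31)
  tri <- call_triples_on_sim(sim)
  planted <- sim$truth$pseudogene_id[sim$truth$planted]
  expect_setequal(tri$pseudogene_id, planted)
  expect_true(all(tri$r_pseudo_gene > 0.3))
  expect_true(all(tri$r_pseudo_mirna < 0))
})
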