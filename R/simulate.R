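BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute each base independently with probability `rate`, always to a
# different base
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1)
  paste(v, collapse = "")
}

# place `n` substitutions at given or random positions (1-based)
apply_snps <- function(seq, n, positions = NULL) {
  v <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sort(sample.int(length(v), n))
  for (i in positions) v[i] <- sample(setdiff(BASES, v[i]), 1)
  list(seq = paste(v, collapse = ""), positions = positions)
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates exon sequences in transcript order (reverse-complementing for
#' minus-strand genes).
#'
#' @param genome A `DNAStringSet`.
#' @param exons Exon data frame in transcript order (`chrom`, `start`, `end`,
#'   `strand`, 0-based half-open).
#' @return Transcript sequence, 5' to 3'.
#' @export
transcript_seq <- function(genome, exons) {
  chrom <- as.character(genome[[exons$chrom[1]]])
  pieces <- substring(chrom, exons$start + 1L, exons$end)
  if (exons$strand[1] == "-") {
    paste(vapply(pieces, revcomp_str, ""), collapse = "")
  } else {
    paste(pieces, collapse = "")
  }
}

#' Simulation configuration
#'
#' Collects the parameters of the synthetic-genome and read generators with
#' the package defaults: 50-base reads, a per-base sequencing error rate of
#' 0.1 percent, pseudogene-parent divergence of 2 percent, and a 200-base 3'
#' UTR on each parent transcript.
#'
#' @param seed Mandatory RNG seed, recorded in all outputs.
#' @param n_parent_genes Number of multi-exon parent genes.
#' @param pseudogene_plan List (recycled over parents) of plans:
#'   `list(class = "processed"|"duplicated", divergence_rate, include_utr)`.
#' @param n_unitary Standalone pseudogenes with no parent.
#' @param k Read length.
#' @param error_rate Per-base read error rate.
#' @param subject_snps_per_gene SNPs applied to each expressed transcript
#'   copy before reads are drawn.
#' @param library_size Total aligned reads the per-gene Poisson read counts
#'   are scaled to.
#' @param true_rpkm Named per-gene expression, or `NULL` to draw uniformly
#'   from `rpkm_range` for each expressed gene.
#' @param rpkm_range Range for drawn expression levels.
#' @param exon_length_range,intron_length_range,n_exons_range,spacer_length,utr_length
#'   Gene architecture parameters (bases).
#' @param max_mismatches Mismatch allowance of the idealized aligner.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed,
                              n_parent_genes = 2,
                              pseudogene_plan = list(list(class = "processed",
                                                          divergence_rate = 0.02,
                                                          include_utr = TRUE)),
                              n_unitary = 0,
                              k = 50,
                              error_rate = 0.001,
                              subject_snps_per_gene = 0,
                              library_size = 1e6,
                              true_rpkm = NULL,
                              rpkm_range = c(1, 200),
                              exon_length_range = c(120, 250),
                              intron_length_range = c(80, 160),
                              n_exons_range = c(2, 5),
                              spacer_length = 300,
                              utr_length = 200,
                              max_mismatches = 2) {
  cfg <- as.list(environment())
  stopifnot(is.numeric(seed), length(seed) == 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a genome with parent genes and pseudogenes
#'
#' Builds a random background genome carrying multi-exon parent genes
#' (plus-strand, one transcript each, last `utr_length` transcript bases
#' acting as the 3' UTR) and pseudogenes per plan: processed pseudogenes are
#' the parent's spliced transcript sequence (junction-spanning, intron-less)
#' inserted elsewhere with point mutations at the plan's divergence rate;
#' duplicated pseudogenes copy the full genomic span including introns;
#' unitary pseudogenes are standalone gene-like loci with no parent.
#'
#' @param config A `SimulationConfig` from [simulation_config()].
#' @return List with `genome` (`DNAStringSet`), `models` (named list of gene
#'   models), `parent_map` (data frame), and `truth` (per-gene provenance:
#'   source sequences, UTR coordinates, seed).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  # parent genes live on chr1; pseudogene copies insert on chr2, emulating
  # retrotransposition / duplication away from the parent locus
  segs <- list(chr1 = character(0), chr2 = character(0))
  cursor <- c(chr1 = 0L, chr2 = 0L)
  models <- list()
  truth <- list(seed = config$seed, genes = list())
  pmap_rows <- list()
  push <- function(seq, chrom) {
    segs[[chrom]][[length(segs[[chrom]]) + 1L]] <<- seq
    s <- cursor[[chrom]]
    cursor[[chrom]] <<- cursor[[chrom]] + nchar(seq)
    s
  }
  spacer <- function(chrom) push(random_dna(config$spacer_length), chrom)

  make_gene_body <- function() {
    n_ex <- sample(seq(config$n_exons_range[1], config$n_exons_range[2]), 1)
    ex_len <- sample(seq(config$exon_length_range[1],
                         config$exon_length_range[2]), n_ex, replace = TRUE)
    ex_len[n_ex] <- ex_len[n_ex] + config$utr_length  # 3' UTR on last exon
    in_len <- if (n_ex > 1)
      sample(seq(config$intron_length_range[1],
                 config$intron_length_range[2]), n_ex - 1, replace = TRUE)
      else integer(0)
    list(n_ex = n_ex, ex_len = ex_len, in_len = in_len,
         total = sum(ex_len) + sum(in_len))
  }
  place_gene <- function(gid, body, seq, biotype, chrom) {
    start <- push(seq, chrom)
    offs <- cumsum(c(0L, as.vector(rbind(body$ex_len,
                                         c(body$in_len, 0L)))[seq_len(2 * body$n_ex - 1)]))
    ex_starts <- start + offs[seq(1, length(offs), by = 2)]
    ex <- data.frame(chrom = chrom, start = ex_starts,
                     end = ex_starts + body$ex_len, strand = "+",
                     stringsAsFactors = FALSE)
    m <- list(gene_id = gid, biotype = biotype, pseudo_class = "none",
              parent_gene_id = NA_character_,
              transcripts = stats::setNames(list(ex), paste0(gid, ".t1")))
    class(m) <- "GeneModel"
    models[[gid]] <<- m
    m
  }

  for (g in seq_len(config$n_parent_genes)) {
    spacer("chr1")
    gid <- sprintf("GENE%d", g)
    body <- make_gene_body()
    seq <- random_dna(body$total)
    m <- place_gene(gid, body, seq, "coding", "chr1")
    tx <- transcript_seq(NULL_genome_stub(segs), m$transcripts[[1]])
    truth$genes[[gid]] <- list(transcript = tx,
                               utr = substr(tx, nchar(tx) - config$utr_length + 1L,
                                            nchar(tx)))
    plans <- config$pseudogene_plan
    plan <- plans[[(g - 1L) %% length(plans) + 1L]]
    if (!is.null(plan$class)) {
      spacer("chr2")
      pid <- sprintf("PSG%d", g)
      if (plan$class == "processed") {
        src <- if (isTRUE(plan$include_utr)) tx
               else substr(tx, 1, nchar(tx) - config$utr_length)
        pseq <- mutate_seq(src, plan$divergence_rate)
        pstart <- push(pseq, "chr2")
        ex <- data.frame(chrom = "chr2", start = pstart,
                         end = pstart + nchar(pseq), strand = "+",
                         stringsAsFactors = FALSE)
        pm <- list(gene_id = pid, biotype = "pseudogene",
                   pseudo_class = "processed", parent_gene_id = gid,
                   transcripts = stats::setNames(list(ex), paste0(pid, ".t1")))
        class(pm) <- "GeneModel"
        models[[pid]] <- pm
        truth$genes[[pid]] <- list(source = src, inserted = pseq)
      } else if (plan$class == "duplicated") {
        gseq <- mutate_seq(seq, plan$divergence_rate)
        pm <- place_gene(pid, body, gseq, "pseudogene", "chr2")
        pm$pseudo_class <- "duplicated"; pm$parent_gene_id <- gid
        models[[pid]] <- pm
        truth$genes[[pid]] <- list(source = seq, inserted = gseq)
      } else stop("unknown pseudogene class: ", plan$class)
      pmap_rows[[length(pmap_rows) + 1L]] <- data.frame(
        pseudogene_id = pid, parent_gene_id = gid,
        pseudo_class = plan$class, stringsAsFactors = FALSE)
    }
  }
  for (u in seq_len(config$n_unitary)) {
    spacer("chr1")
    uid <- sprintf("UPSG%d", u)
    body <- make_gene_body()
    m <- place_gene(uid, body, random_dna(body$total), "pseudogene", "chr1")
    m$pseudo_class <- "unitary"
    models[[uid]] <- m
    pmap_rows[[length(pmap_rows) + 1L]] <- data.frame(
      pseudogene_id = uid, parent_gene_id = "", pseudo_class = "unitary",
      stringsAsFactors = FALSE)
  }
  spacer("chr1")
  if (length(segs$chr2)) spacer("chr2")
  genome <- NULL_genome_stub(segs)
  parent_map <- if (length(pmap_rows)) do.call(rbind, pmap_rows)
    else data.frame(pseudogene_id = character(),
                    parent_gene_id = character(),
                    pseudo_class = character(), stringsAsFactors = FALSE)
  list(genome = genome, models = models, parent_map = parent_map,
       truth = truth)
}

# lets transcript_seq run against a genome still under construction
NULL_genome_stub <- function(segs) {
  chrs <- vapply(segs, paste, "", collapse = "")
  Biostrings::DNAStringSet(chrs[nchar(chrs) > 0])
}

#' Simulate RNA-seq reads with subject SNPs, errors, and all alignments
#'
#' Draws reads uniformly along each expressed transcript at the gene's true
#' RPKM (Poisson read counts against `library_size`), after applying
#' `subject_snps_per_gene` substitutions to the expressed copy. Per-base
#' sequencing errors are then applied. Alignments are produced by an
#' idealized exhaustive aligner: every direct genomic placement within
#' `max_mismatches` on either strand, plus every spliced placement across an
#' annotated junction (matched through the junction's synthetic region).
#'
#' @param genome,models,truth Output of [simulate_genome()].
#' @param config A `SimulationConfig`; `true_rpkm` may name a subset of genes
#'   to express (default: all coding genes at levels drawn from
#'   `rpkm_range`).
#' @return List with `reads` (data frame: `read_id`, `gene_id`, `tx_pos`,
#'   `seq`), `records` (alignment records as in [read_alignment_tsv()]),
#'   and `truth` (per-gene read counts, SNP positions, true RPKM).
#' @export
simulate_reads <- function(genome, models, truth, config) {
  set.seed(config$seed + 1L)
  k <- config$k
  expressed <- config$true_rpkm
  if (is.null(expressed)) {
    coding <- names(models)[vapply(models, function(m) m$biotype == "coding",
                                   TRUE)]
    expressed <- stats::setNames(
      stats::runif(length(coding), config$rpkm_range[1], config$rpkm_range[2]),
      coding)
  }
  reads <- list(); read_truth <- list()
  for (gid in names(expressed)) {
    ex <- models[[gid]]$transcripts[[1]]
    tx <- transcript_seq(genome, ex)
    L <- nchar(tx)
    if (L < k) stop("transcript of '", gid, "' shorter than read length")
    snps <- NULL
    subj <- tx
    if (config$subject_snps_per_gene > 0) {
      s <- apply_snps(tx, config$subject_snps_per_gene)
      subj <- s$seq; snps <- s$positions
    }
    n_reads <- stats::rpois(1, expressed[[gid]] * (L / 1000) *
                               (config$library_size / 1e6))
    if (n_reads == 0) { read_truth[[gid]] <- list(n_reads = 0, snps = snps); next }
    starts <- sample.int(L - k + 1L, n_reads, replace = TRUE)
    seqs <- substring(subj, starts, starts + k - 1L)
    if (config$error_rate > 0)
      seqs <- vapply(seqs, mutate_seq, "", rate = config$error_rate,
                     USE.NAMES = FALSE)
    reads[[gid]] <- data.frame(
      read_id = sprintf("%s_r%d", gid, seq_len(n_reads)), gene_id = gid,
      tx_pos = starts - 1L, seq = seqs, stringsAsFactors = FALSE)
    read_truth[[gid]] <- list(n_reads = n_reads, snps = snps,
                              true_rpkm = expressed[[gid]])
  }
  reads <- if (length(reads)) do.call(rbind, reads)
    else data.frame(read_id = character(), gene_id = character(),
                    tx_pos = integer(), seq = character(),
                    stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  records <- align_reads_exhaustive(genome, models, reads, k,
                                    config$max_mismatches)
  list(reads = reads, records = records,
       truth = list(seed = config$seed, genes = read_truth,
                    true_rpkm = expressed))
}

# idealized aligner over small genomes: all direct hits plus spliced hits at
# annotated junctions, each within max_mm mismatches
align_reads_exhaustive <- function(genome, models, reads, k, max_mm) {
  empty <- data.frame(read_id = character(), chrom = character(),
                      start = integer(), block_starts = character(),
                      block_ends = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) return(empty)
  chrom_seq <- stats::setNames(as.character(genome), names(genome))
  direct <- cpp_scan_hits(unname(chrom_seq), reads$seq, max_mm)
  rows <- list()
  if (nrow(direct) > 0) {
    rows[[1]] <- data.frame(
      read_id = reads$read_id[direct$read],
      chrom = names(chrom_seq)[direct$subject],
      start = direct$pos,
      block_starts = as.character(direct$pos),
      block_ends = as.character(direct$pos + k),
      mismatches = direct$mismatches, stringsAsFactors = FALSE)
  }
  regions <- build_synthetic_regions(models, genome, k)
  if (nrow(regions) > 0) {
    sphits <- cpp_scan_hits(regions$seq, reads$seq, max_mm)
    if (nrow(sphits) > 0) {
      for (i in seq_len(nrow(sphits))) {
        reg <- regions[sphits$subject[i], ]
        gpos <- region_genomic_positions(reg)
        covered <- sort(gpos[(sphits$pos[i] + 1L):(sphits$pos[i] + k)])
        gap <- which(diff(covered) > 1L)
        if (length(gap) != 1L) next   # k-mer does not cross the junction
        b1 <- c(covered[1], covered[gap] + 1L)
        b2 <- c(covered[gap + 1L], covered[k] + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = reads$read_id[sphits$read[i]], chrom = reg$chrom,
          start = b1[1],
          block_starts = paste(b1[1], b2[1], sep = ","),
          block_ends = paste(b1[2], b2[2], sep = ","),
          mismatches = sphits$mismatches[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  rec <- do.call(rbind, rows)
  # the same placement reported twice (e.g. on both strands of a palindromic
  # window, or via two transcripts sharing a junction) counts once
  key <- paste(rec$read_id, rec$chrom, rec$block_starts, rec$block_ends)
  rec <- rec[order(key, rec$mismatches), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$read_id, rec$chrom, rec$block_starts,
                               rec$block_ends)), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' The gene/pseudogene misalignment scenario
#'
#' Constructs the textbook failure mode of naive unique-read counting: a
#' single-exon gene and a pseudogene copy differing at exactly one
#' nucleotide, with the subject genome's gene carrying three clustered SNPs,
#' one of which coincides with the pseudogene's divergent base. Reads tiled
#' across the subject gene that cover all three SNPs are then within two
#' mismatches of the pseudogene only, so an aligner allowing two mismatches
#' places them uniquely — and wrongly — on the pseudogene. Because gene and
#' pseudogene are everywhere within Hamming distance 1, the whole pseudogene
#' is unmappable at a safety margin of 2 and the mappability filter discards
#' every misaligned read.
#'
#' @param seed RNG seed.
#' @param k Read length (default 50).
#' @param gene_length Length of the gene (default 300).
#' @return List with `genome`, `models`, `parent_map`, `reads`, `records`
#'   (alignment records of all tiled reads), and `truth` (ids of the
#'   misaligned reads and the SNP positions).
#' @export
fig1a_scenario <- function(seed = 1, k = 50, gene_length = 300) {
  set.seed(seed)
  bg_n <- 3000L
  chrom <- strsplit(random_dna(bg_n), "")[[1]]
  gene_start <- 500L; psg_start <- 1500L
  G <- paste(chrom[(gene_start + 1):(gene_start + gene_length)], collapse = "")
  diff_off <- as.integer(gene_length / 2)        # 1-based offset within gene
  P <- apply_snps(G, 1, positions = diff_off)$seq
  chrom[(psg_start + 1):(psg_start + gene_length)] <- strsplit(P, "")[[1]]
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(chrom, collapse = "")))

  mk <- function(gid, start, biotype, pclass, parent) {
    ex <- data.frame(chrom = "chr1", start = start,
                     end = start + gene_length, strand = "+",
                     stringsAsFactors = FALSE)
    m <- list(gene_id = gid, biotype = biotype, pseudo_class = pclass,
              parent_gene_id = parent,
              transcripts = stats::setNames(list(ex), paste0(gid, ".t1")))
    class(m) <- "GeneModel"
    m
  }
  models <- list(GENE1 = mk("GENE1", gene_start, "coding", "none",
                            NA_character_),
                 PSG1 = mk("PSG1", psg_start, "pseudogene", "processed",
                           "GENE1"))
  # subject gene: 3 clustered SNPs; the middle one matches the pseudogene
  snp_off <- c(diff_off - 2L, diff_off, diff_off + 2L)
  S <- strsplit(G, "")[[1]]
  S[diff_off] <- substr(P, diff_off, diff_off)
  for (i in snp_off[c(1, 3)])
    S[i] <- sample(setdiff(BASES, c(S[i], substr(P, i, i))), 1)
  S <- paste(S, collapse = "")

  starts <- seq_len(gene_length - k + 1L)
  reads <- data.frame(read_id = sprintf("read%03d", starts),
                      gene_id = "GENE1", tx_pos = starts - 1L,
                      seq = substring(S, starts, starts + k - 1L),
                      stringsAsFactors = FALSE)
  records <- align_reads_exhaustive(genome, models, reads, k, max_mm = 2)
  n_aln <- table(records$read_id)
  uniq <- names(n_aln)[n_aln == 1]
  urec <- records[records$read_id %in% uniq, ]
  mis <- urec$read_id[urec$start >= psg_start &
                      urec$start < psg_start + gene_length]
  list(genome = genome, models = models,
       parent_map = data.frame(pseudogene_id = "PSG1",
                               parent_gene_id = "GENE1",
                               pseudo_class = "processed",
                               stringsAsFactors = FALSE),
       reads = reads, records = records,
       truth = list(seed = seed, misaligned_reads = mis,
                    snp_offsets = snp_off, divergent_offset = diff_off))
}

#' Robustness of RPKUM to the number of mappable bases
#'
#' For each simulated gene, draws a true expression level, generates
#' uniform-coverage read start positions at that level, samples `m` transcript
#' positions as the gene's only mappable bases, counts the reads starting at
#' those positions, and computes RPKUM. Reports the Spearman rank correlation
#' between RPKUM and the true RPKM for each `m`.
#'
#' @param n_genes Number of simulated genes (at least 50).
#' @param rpkm_range True expression range (default 1-200 RPKM).
#' @param mappable_bases_options Values of `m` to test (default 50, 100,
#'   500).
#' @param gene_length Transcript length in bases (default 1000).
#' @param library_size Total aligned reads (default 5e6).
#' @param log_uniform Draw RPKM log-uniformly instead of uniformly.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `m` and `spearman_rho`.
#' @export
rpkum_robustness_simulation <- function(n_genes = 1000,
                                        rpkm_range = c(1, 200),
                                        mappable_bases_options = c(50, 100, 500),
                                        gene_length = 1000,
                                        library_size = 5e6,
                                        log_uniform = FALSE,
                                        seed = NULL) {
  stopifnot(n_genes >= 50, all(mappable_bases_options <= gene_length))
  if (!is.null(seed)) set.seed(seed)
  rpkm <- if (log_uniform)
    exp(stats::runif(n_genes, log(rpkm_range[1]), log(rpkm_range[2])))
  else stats::runif(n_genes, rpkm_range[1], rpkm_range[2])
  counts <- matrix(0L, nrow = n_genes, ncol = length(mappable_bases_options))
  for (g in seq_len(n_genes)) {
    n_reads <- stats::rpois(1, rpkm[g] * (gene_length / 1000) *
                               (library_size / 1e6))
    tab <- tabulate(sample.int(gene_length, n_reads, replace = TRUE),
                    nbins = gene_length)
    for (j in seq_along(mappable_bases_options)) {
      pos <- sample.int(gene_length, mappable_bases_options[j])
      counts[g, j] <- sum(tab[pos])
    }
  }
  rho <- vapply(seq_along(mappable_bases_options), function(j) {
    rpkum <- compute_rpkum(counts[, j], mappable_bases_options[j],
                           library_size)
    stats::cor(rpkum, rpkm, method = "spearman")
  }, 0)
  data.frame(m = mappable_bases_options, spearman_rho = rho)
}

#' Simulate expression matrices with planted ceRNA structure
#'
#' Each planted triple shares a positive latent factor between pseudogene and
#' parent gene and is depressed by a per-sample miRNA level, yielding
#' positive pseudogene-gene correlation and negative correlations of both
#' with the miRNA. Null pairs (and their assigned miRNAs) are independent.
#' Latent levels are exponentiated to an RPKUM-like scale (`2^(base + z)`).
#'
#' @param n_samples Number of samples (at least 20; default 200).
#' @param n_triples Planted ceRNA triples.
#' @param n_null_pairs Independent pseudogene-gene pairs.
#' @param effect List: `shared` (latent factor loading), `mirna` (miRNA
#'   suppression loading), `noise_sd` (independent noise).
#' @param base_log2 Log2 baseline expression (default 3, i.e. around 8
#'   RPKUM).
#' @param seed Optional RNG seed.
#' @return List with `pseudogene_matrix`, `gene_matrix`, `mirna_matrix`,
#'   `pairs` (all pseudogene-gene pairs), `shared` (pair-to-miRNA map), and
#'   `truth` (which pairs are planted).
#' @export
simulate_cerna_expression <- function(n_samples = 200, n_triples = 5,
                                      n_null_pairs = 15,
                                      effect = list(shared = 1, mirna = 0.8,
                                                    noise_sd = 0.5),
                                      base_log2 = 3, seed = NULL) {
  stopifnot(n_samples >= 20)
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- n_triples + n_null_pairs
  P <- G <- matrix(0, n_pairs, n_samples)
  M <- matrix(0, n_pairs, n_samples)
  planted <- rep(c(TRUE, FALSE), c(n_triples, n_null_pairs))
  for (i in seq_len(n_pairs)) {
    if (planted[i]) {
      mz <- stats::rnorm(n_samples)
      f <- stats::rnorm(n_samples)
      P[i, ] <- effect$shared * f - effect$mirna * mz +
        effect$noise_sd * stats::rnorm(n_samples)
      G[i, ] <- effect$shared * f - effect$mirna * mz +
        effect$noise_sd * stats::rnorm(n_samples)
      M[i, ] <- mz + 0.2 * stats::rnorm(n_samples)
    } else {
      P[i, ] <- stats::rnorm(n_samples)
      G[i, ] <- stats::rnorm(n_samples)
      M[i, ] <- stats::rnorm(n_samples)
    }
  }
  expn <- function(Z) 2^(base_log2 + Z)
  pg_ids <- sprintf("PSG%d", seq_len(n_pairs))
  g_ids <- sprintf("GENE%d", seq_len(n_pairs))
  m_ids <- sprintf("MIR%d", seq_len(n_pairs))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  dn <- function(m, ids) matrix(m, nrow = n_pairs,
                                dimnames = list(ids, sample_ids))
  list(pseudogene_matrix = dn(expn(P), pg_ids),
       gene_matrix = dn(expn(G), g_ids),
       mirna_matrix = dn(expn(M), m_ids),
       pairs = data.frame(id_a = pg_ids, id_b = g_ids,
                          stringsAsFactors = FALSE),
       shared = data.frame(pseudogene_id = pg_ids, parent_gene_id = g_ids,
                           mirna_id = m_ids, stringsAsFactors = FALSE),
       truth = data.frame(pseudogene_id = pg_ids, parent_gene_id = g_ids,
                          mirna_id = m_ids, planted = planted,
                          stringsAsFactors = FALSE))
}

#' Write simulated reads to FASTQ
#'
#' Constant maximum base quality; the simulator models errors directly.
#'
#' @param reads Read table from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads$seq), function(n)
    paste(rep("I", n), collapse = ""), "")
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
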