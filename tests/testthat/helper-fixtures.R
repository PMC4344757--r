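# Shared fixture builders for the test suite. Everything is generated from
# seeds at test time; no binary fixtures are stored.

DNA4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

rand_genome <- function(lens) {
  Biostrings::DNAStringSet(
    stats::setNames(vapply(lens, rand_dna, ""),
                    paste0("chr", seq_along(lens))))
}

# single-exon gene model on given 0-based half-open interval
exon1_model <- function(gid, chrom, start, end, strand = "+",
                        biotype = "coding") {
  ex <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  m <- list(gene_id = gid, biotype = biotype, pseudo_class = "none",
            parent_gene_id = NA_character_,
            transcripts = stats::setNames(list(ex), paste0(gid, ".t1")))
  class(m) <- "GeneModel"
  m
}

# two-exon gene model; exons given genomically left-to-right, reordered to
# transcript order for minus-strand genes
exon2_model <- function(gid, chrom, s1, e1, s2, e2, strand = "+",
                        biotype = "coding") {
  ex <- data.frame(chrom = chrom, start = c(s1, s2), end = c(e1, e2),
                   strand = strand, stringsAsFactors = FALSE)
  if (strand == "-") ex <- ex[2:1, ]
  rownames(ex) <- NULL
  m <- list(gene_id = gid, biotype = biotype, pseudo_class = "none",
            parent_gene_id = NA_character_,
            transcripts = stats::setNames(list(ex), paste0(gid, ".t1")))
  class(m) <- "GeneModel"
  m
}

# independent R reimplementation of canonical seed-site scanning, used as an
# oracle against find_seed_matches()
oracle_seed_matches <- function(utr, mirnas) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  utr <- toupper(chartr("Uu", "Tt", utr))
  rows <- list()
  for (id in names(mirnas)) {
    m <- toupper(chartr("Uu", "Tt", mirnas[[id]]))
    if (nchar(m) < 8) next
    core <- rc(substr(m, 2, 7))
    m8 <- comp[[substr(m, 8, 8)]]
    for (p in seq_len(nchar(utr) - 5L)) {          # 1-based core start
      if (substr(utr, p, p + 5) != core) next
      has_m8 <- p > 1 && substr(utr, p - 1, p - 1) == m8
      has_a1 <- p + 6 <= nchar(utr) && substr(utr, p + 6, p + 6) == "A"
      type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
              else if (has_a1) "7mer-A1" else "6mer"
      s0 <- if (has_m8) p - 2L else p - 1L
      e0 <- if (has_a1) p + 6L else p + 5L
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = id, site_type = type, start = s0, end = e0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(), site_type = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# run the full ceRNA calling chain on one simulate_cerna_expression() output
call_triples_on_sim <- function(sim, min_present_samples = 20) {
  pg_pairs <- data.frame(id_a = sim$shared$pseudogene_id,
                         id_b = sim$shared$parent_gene_id,
                         stringsAsFactors = FALSE)
  pm_pairs <- data.frame(id_a = sim$shared$pseudogene_id,
                         id_b = sim$shared$mirna_id, stringsAsFactors = FALSE)
  gm_pairs <- data.frame(id_a = sim$shared$parent_gene_id,
                         id_b = sim$shared$mirna_id, stringsAsFactors = FALSE)
  cor_pg <- pairwise_correlation(sim$pseudogene_matrix, sim$gene_matrix,
                                 pg_pairs,
                                 min_present_samples = min_present_samples)
  cor_pm <- pairwise_correlation(sim$pseudogene_matrix, sim$mirna_matrix,
                                 pm_pairs,
                                 min_present_samples = min_present_samples)
  cor_gm <- pairwise_correlation(sim$gene_matrix, sim$mirna_matrix,
                                 gm_pairs,
                                 min_present_samples = min_present_samples)
  identify_cerna_triples(cor_pg, cor_pm, cor_gm, sim$shared)
}
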