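#' Extract a pseudogene locus with genomic context
#'
#' Returns the pseudogene locus sequence plus up to `flank` bases on either
#' side (default 10 kb), clipped at chromosome edges, together with offset
#' metadata for mapping context coordinates back to the genome.
#'
#' @param pseudogene A gene model.
#' @param genome A `DNAStringSet` genome.
#' @param flank Context to take on each side, in bases.
#' @return List with `seq`, `chrom`, `start` (0-based genomic position of the
#'   first context base), `locus_start`, `locus_end`, and `clipped_left` /
#'   `clipped_right` flags.
#' @export
extract_context <- function(pseudogene, genome, flank = 10000) {
  ex <- do.call(rbind, pseudogene$transcripts)
  chrom <- ex$chrom[1]
  L <- Biostrings::width(genome)[match(chrom, names(genome))]
  locus_start <- min(ex$start); locus_end <- max(ex$end)
  start <- max(0L, locus_start - flank)
  end <- min(L, locus_end + flank)
  seq <- substr(as.character(genome[[chrom]]), start + 1L, end)
  list(seq = seq, chrom = chrom, start = start,
       locus_start = locus_start, locus_end = locus_end,
       clipped_left = locus_start - flank < 0L,
       clipped_right = locus_end + flank > L)
}

ka_lambda <- function(match, mismatch) {
  stats::uniroot(function(l) 0.25 * exp(match * l) + 0.75 * exp(mismatch * l) - 1,
                 c(1e-8, 10), tol = 1e-10)$root
}

#' Local alignment with approximate Karlin-Altschul significance
#'
#' Smith-Waterman local alignment of `query` against `subject` on both
#' strands, scored with the given match/mismatch/affine-gap parameters.
#' Significance is an E-value-like score `E = K * m * n * exp(-lambda * S)`
#' with `lambda` solved from the ungapped score distribution under uniform
#' base composition and a fixed `K = 0.1`; this is an approximation adequate
#' for thresholding homologous from random local hits. The best alignment per
#' strand is reported. Coordinates are 0-based half-open.
#'
#' @param query,subject DNA sequences (character).
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (penalties positive; defaults 2 / -3 / 5 / 2).
#' @param K Karlin-Altschul prefactor.
#' @return Data frame (one row per strand with a positive-score alignment):
#'   `score`, `q_start`, `q_end`, `s_start`, `s_end`, `length` (subject
#'   span), `strand`, `evalue`, sorted by E-value then decreasing length.
#' @export
local_align <- function(query, subject,
                        scoring = list(match = 2, mismatch = -3,
                                       gap_open = 5, gap_extend = 2),
                        K = 0.1) {
  stopifnot(nzchar(query), nzchar(subject))
  lambda <- ka_lambda(scoring$match, scoring$mismatch)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  m <- nchar(query); n <- nchar(subject)
  one <- function(q, strand) {
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(q),
      subject = Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    s <- Biostrings::score(al)
    if (s <= 0) return(NULL)
    ss <- Biostrings::start(Biostrings::subject(al))
    se <- Biostrings::end(Biostrings::subject(al))
    qs <- Biostrings::start(Biostrings::pattern(al))
    qe <- Biostrings::end(Biostrings::pattern(al))
    if (strand == "-") { tmp <- qs; qs <- m - qe + 1L; qe <- m - tmp + 1L }
    data.frame(score = s, q_start = qs - 1L, q_end = qe,
               s_start = ss - 1L, s_end = se, length = se - ss + 1L,
               strand = strand, evalue = K * m * n * exp(-lambda * s),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(query, "+"), one(revcomp_str(query), "-"))
  if (is.null(out))
    return(data.frame(score = numeric(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), length = integer(),
                      strand = character(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  out[order(out$evalue, -out$length), , drop = FALSE]
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Drop-in alternative to [local_align()] results, so an external BLAST run
#' can supply the alignments for pseudo-3' UTR annotation. Coordinates are
#' converted to 0-based half-open; subject coordinates with start > end are
#' reported as minus-strand hits.
#'
#' @param path Path to a 12-column BLAST `-outfmt 6` file.
#' @return Data frame with the same columns as [local_align()] plus
#'   `query_id`, `subject_id`.
#' @export
parse_blast_tabular <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 outfmt-6 columns in ", path)
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "alnlen", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  minus <- df$send < df$sstart
  s_lo <- pmin(df$sstart, df$send); s_hi <- pmax(df$sstart, df$send)
  data.frame(query_id = df$qseqid, subject_id = df$sseqid,
             score = df$bitscore,
             q_start = df$qstart - 1L, q_end = df$qend,
             s_start = s_lo - 1L, s_end = s_hi,
             length = s_hi - s_lo + 1L,
             strand = ifelse(minus, "-", "+"),
             evalue = df$evalue, stringsAsFactors = FALSE)
}

#' Annotate the pseudo-3' UTR of a pseudogene
#'
#' Aligns every annotated 3' UTR of the parent gene against the pseudogene
#' locus plus genomic context; among alignments passing the significance
#' cutoff, the longest (by subject span) is taken as the pseudo-3' UTR.
#' Ties break by better significance, then leftmost subject start.
#'
#' @param parent_utrs Character vector of parent 3' UTR sequences (one per
#'   annotated transcript).
#' @param context Context list from [extract_context()].
#' @param scoring,K Passed to [local_align()].
#' @param evalue_cutoff Significance cutoff (default 1e-6).
#' @return A `Pseudo3UTR` list with `interval` (0-based half-open genomic),
#'   `context_interval`, `sequence` (transcript orientation: reverse
#'   complement of the genomic slice for minus-strand hits),
#'   `alignment_length`, `evalue`, `strand`; or `NULL` if no alignment
#'   passes.
#' @export
annotate_pseudo3utr <- function(parent_utrs, context,
                                scoring = list(match = 2, mismatch = -3,
                                               gap_open = 5, gap_extend = 2),
                                K = 0.1, evalue_cutoff = 1e-6) {
  stopifnot(length(parent_utrs) >= 1)
  hits <- do.call(rbind, lapply(parent_utrs, function(u)
    local_align(u, context$seq, scoring = scoring, K = K)))
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  hits <- hits[order(-hits$length, hits$evalue, hits$s_start), , drop = FALSE]
  best <- hits[1, ]
  seq <- substr(context$seq, best$s_start + 1L, best$s_end)
  if (best$strand == "-") seq <- revcomp_str(seq)
  structure(list(
    interval = c(start = context$start + best$s_start,
                 end = context$start + best$s_end),
    context_interval = c(start = best$s_start, end = best$s_end),
    chrom = context$chrom, sequence = seq,
    alignment_length = best$length, evalue = best$evalue,
    strand = best$strand), class = "Pseudo3UTR")
}

#' Load mature miRNA sequences from FASTA
#'
#' Accepts RNA or DNA alphabet; sequences are normalized to uppercase DNA
#' (U -> T). Distinct headers (including isomiR variants of one locus) are
#' kept as distinct miRNAs.
#'
#' @param path FASTA path.
#' @return Named character vector of mature sequences, 5' to 3'.
#' @export
load_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("Uu", "Tt", as.character(ss)))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Find canonical miRNA seed-match sites in a UTR
#'
#' Scans for the four canonical site classes defined by complementarity to
#' the miRNA seed (miRNA bases 2-7/2-8, 5' to 3'): `8mer` (match to bases 2-8
#' plus an A opposite base 1), `7mer-m8` (match to bases 2-8), `7mer-A1`
#' (match to bases 2-7 plus the A), and `6mer` (match to bases 2-7 only,
#' reported only where not part of a longer site). Overlapping occurrences
#' are all reported. Sequences are normalized to DNA (U -> T) before
#' matching.
#'
#' @param utr UTR sequence, 5' to 3' (character).
#' @param mirnas Named character vector of mature miRNA sequences, 5' to 3'.
#'   Entries shorter than 8 bases are skipped with a warning.
#' @param on_pseudogene Logical tag copied into the output (which transcript
#'   the UTR belongs to).
#' @return Data frame: `mirna_id`, `site_type`, `start`, `end` (0-based
#'   half-open on the UTR), `on_pseudogene`.
#' @export
find_seed_matches <- function(utr, mirnas, on_pseudogene = NA) {
  utr <- toupper(chartr("Uu", "Tt", utr))
  rows <- list()
  for (id in names(mirnas)) {
    m <- toupper(chartr("Uu", "Tt", mirnas[[id]]))
    if (nchar(m) < 8) {
      warning("miRNA '", id, "' shorter than 8 bases; skipped")
      next
    }
    core6 <- revcomp_str(substr(m, 2, 7))
    m8c <- COMP[[substr(m, 8, 8)]]
    # overlapping occurrences of the 6-base core
    occ <- gregexpr(paste0("(?=", core6, ")"), utr, perl = TRUE)[[1]]
    if (occ[1] == -1) next
    for (p in as.integer(occ)) {             # 1-based core start
      has_m8 <- p > 1 && substr(utr, p - 1, p - 1) == m8c
      has_a1 <- p + 6 <= nchar(utr) && substr(utr, p + 6, p + 6) == "A"
      if (has_m8 && has_a1) { type <- "8mer";    s <- p - 1L; e <- p + 6L }
      else if (has_m8)      { type <- "7mer-m8"; s <- p - 1L; e <- p + 5L }
      else if (has_a1)      { type <- "7mer-A1"; s <- p;      e <- p + 6L }
      else                  { type <- "6mer";    s <- p;      e <- p + 5L }
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = id, site_type = type, start = s - 1L, end = e,
        on_pseudogene = on_pseudogene, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(), site_type = character(),
                      start = integer(), end = integer(),
                      on_pseudogene = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' miRNAs with predicted sites on both pseudogene and parent
#'
#' @param pseudo_sites,parent_sites Site tables from [find_seed_matches()]
#'   computed with the same miRNA panel.
#' @return Character vector of shared miRNA ids.
#' @export
shared_mirnas <- function(pseudo_sites, parent_sites) {
  sort(intersect(unique(pseudo_sites$mirna_id),
                 unique(parent_sites$mirna_id)))
}

#' Top expressed miRNAs by mean expression
#'
#' Ranks miRNAs by mean expression across samples, descending, breaking ties
#' by id; isomiRs enter as distinct rows. If the cutoff falls inside a tie on
#' the mean, all tied miRNAs are included (so more than `n` ids may return).
#'
#' @param mirna_matrix Numeric miRNAs-by-samples matrix.
#' @param n Number of top miRNAs (default 100).
#' @return Character vector of miRNA ids, ranked.
#' @export
top_expressed_mirnas <- function(mirna_matrix, n = 100) {
  stopifnot(n <= nrow(mirna_matrix))
  means <- rowMeans(mirna_matrix)
  ord <- order(-means, rownames(mirna_matrix))
  ranked <- rownames(mirna_matrix)[ord]
  cutoff <- means[ranked[n]]
  ranked[means[ranked] >= cutoff]
}

# Row-wise Pearson correlation of paired matrices on co-present samples,
# log2(x+1)-transformed. Returns r (NA where n < min_n or degenerate) and n.
masked_pair_cor <- function(A, B, presence_level, min_n) {
  M <- (A >= presence_level) & (B >= presence_level)
  n <- rowSums(M)
  LA <- log2(A + 1) * M
  LB <- log2(B + 1) * M
  sx <- rowSums(LA); sy <- rowSums(LB)
  sxx <- rowSums(LA^2); syy <- rowSums(LB^2); sxy <- rowSums(LA * LB)
  cov <- sxy - sx * sy / n
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  r <- cov / sqrt(vx * vy)
  r[!is.finite(r)] <- NA_real_
  r[n < min_n] <- NA_real_
  list(r = r, n = n)
}

#' Pairwise expression correlation with presence filtering
#'
#' For each (id_a, id_b) pair, restricts to samples where both members are
#' present at `presence_level` or greater; pairs with fewer than
#' `min_present_samples` co-present samples are marked excluded. Otherwise
#' Pearson correlation is computed on log2(x+1)-transformed values over the
#' co-present samples, with a one-sided p-value from the t-statistic
#' `t = r * sqrt((n-2)/(1-r^2))` for the null hypothesis that the correlation
#' is no smaller than zero (small p = significant anti-correlation).
#'
#' @param mat_a,mat_b Numeric matrices sharing the sample (column) axis.
#' @param pairs Data frame with columns `id_a`, `id_b` (row names of
#'   `mat_a` / `mat_b`).
#' @param min_present_samples Minimum co-present samples (default 20).
#' @param presence_level Presence threshold on the expression scale
#'   (default 1, i.e. 1 RPKUM).
#' @return Data frame: `id_a`, `id_b`, `r`, `n_samples_used`, `p_one_sided`,
#'   `excluded`.
#' @export
pairwise_correlation <- function(mat_a, mat_b, pairs,
                                 min_present_samples = 20,
                                 presence_level = 1.0) {
  if (!all(pairs$id_a %in% rownames(mat_a)))
    stop("unknown id_a: ",
         paste(utils::head(setdiff(pairs$id_a, rownames(mat_a))), collapse = ", "))
  if (!all(pairs$id_b %in% rownames(mat_b)))
    stop("unknown id_b: ",
         paste(utils::head(setdiff(pairs$id_b, rownames(mat_b))), collapse = ", "))
  A <- mat_a[pairs$id_a, , drop = FALSE]
  B <- mat_b[pairs$id_b, , drop = FALSE]
  mc <- masked_pair_cor(A, B, presence_level, min_present_samples)
  r <- mc$r; n <- mc$n
  tstat <- r * sqrt(pmax(n - 2, 0) / (1 - r^2))
  p <- stats::pt(tstat, df = n - 2)
  excluded <- n < min_present_samples
  p[excluded | is.na(r)] <- NA_real_
  data.frame(id_a = pairs$id_a, id_b = pairs$id_b, r = r,
             n_samples_used = as.integer(n), p_one_sided = p,
             excluded = excluded, stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation null for the number of correlated pairs
#'
#' Randomly re-pairs the two sides of a pair set `n_permutations` times
#' (uniform shuffle of the side-b labels); for each permuted set, applies the
#' same presence filter and log-scale Pearson correlation as
#' [pairwise_correlation()] and counts pairs beyond `threshold` in the stated
#' direction. The empirical p-value is the fraction of permutations with a
#' count at least as large as the observed one.
#'
#' @inheritParams pairwise_correlation
#' @param true_pairs The observed pair set (`id_a`, `id_b`).
#' @param n_permutations Number of random pairings (default 5000).
#' @param threshold Correlation magnitude threshold (default 0.3).
#' @param direction `"positive"` counts r > threshold; `"negative"` counts
#'   r < -threshold.
#' @param seed Optional RNG seed for reproducibility.
#' @return A `PermutationResult`: list with `observed_count`, `null_counts`,
#'   `threshold`, `direction`, `empirical_p`, `n_permutations`, `seed`.
#' @export
permutation_null <- function(mat_a, mat_b, true_pairs, n_permutations = 5000,
                             threshold = 0.3,
                             direction = c("positive", "negative"),
                             seed = NULL, min_present_samples = 20,
                             presence_level = 1.0) {
  direction <- match.arg(direction)
  stopifnot(length(unique(true_pairs$id_a)) >= 2,
            length(unique(true_pairs$id_b)) >= 2)
  if (!is.null(seed)) set.seed(seed)
  A <- mat_a[true_pairs$id_a, , drop = FALSE]
  B <- mat_b[true_pairs$id_b, , drop = FALSE]
  count_fn <- function(r) {
    if (direction == "positive") sum(r > threshold, na.rm = TRUE)
    else sum(r < -threshold, na.rm = TRUE)
  }
  observed <- count_fn(masked_pair_cor(A, B, presence_level,
                                       min_present_samples)$r)
  null_counts <- integer(n_permutations)
  np <- nrow(B)
  for (i in seq_len(n_permutations)) {
    Bp <- B[sample.int(np), , drop = FALSE]
    null_counts[i] <- count_fn(masked_pair_cor(A, Bp, presence_level,
                                               min_present_samples)$r)
  }
  structure(list(observed_count = observed, null_counts = null_counts,
                 threshold = threshold, direction = direction,
                 empirical_p = mean(null_counts >= observed),
                 n_permutations = n_permutations, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: observed %d pair(s) with %s correlation beyond %.2f; empirical p = %.4g over %d permutations\n",
              x$observed_count, x$direction, x$threshold, x$empirical_p,
              x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up BH adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Identify pseudogene / parent-gene / miRNA triples with ceRNA potential
#'
#' A triple is reported iff the miRNA is a shared predicted targeter of both
#' transcripts, the pseudogene-gene correlation exceeds `r_gene_threshold`
#' (strictly), and the pseudogene-miRNA anti-correlation is significant after
#' BH adjustment at `q_threshold` (q-values computed across all non-excluded
#' pseudogene-miRNA records supplied).
#'
#' @param cor_pg Correlation records for (pseudogene, parent gene) pairs from
#'   [pairwise_correlation()].
#' @param cor_pm,cor_gm Correlation records for (pseudogene, miRNA) and
#'   (gene, miRNA) pairs.
#' @param shared Data frame of shared-targeting combinations:
#'   `pseudogene_id`, `parent_gene_id`, `mirna_id`.
#' @param r_gene_threshold Pseudogene-gene correlation threshold (default
#'   0.3).
#' @param q_threshold BH q-value threshold on the pseudogene-miRNA
#'   anti-correlation (default 0.05).
#' @return Data frame of `CeRNATriple` rows: ids, the three pairwise
#'   correlations, and the BH q-values of the two miRNA correlations.
#' @export
identify_cerna_triples <- function(cor_pg, cor_pm, cor_gm, shared,
                                   r_gene_threshold = 0.3,
                                   q_threshold = 0.05) {
  cor_pm$q_bh <- bh_adjust(cor_pm$p_one_sided)
  cor_gm$q_bh <- bh_adjust(cor_gm$p_one_sided)
  key <- function(df) paste(df$id_a, df$id_b, sep = "\r")
  out <- list()
  for (i in seq_len(nrow(shared))) {
    pg <- cor_pg[key(cor_pg) == paste(shared$pseudogene_id[i],
                                      shared$parent_gene_id[i], sep = "\r"), ]
    pm <- cor_pm[key(cor_pm) == paste(shared$pseudogene_id[i],
                                      shared$mirna_id[i], sep = "\r"), ]
    gm <- cor_gm[key(cor_gm) == paste(shared$parent_gene_id[i],
                                      shared$mirna_id[i], sep = "\r"), ]
    if (nrow(pg) == 0 || nrow(pm) == 0) next
    if (pg$excluded[1] || is.na(pg$r[1]) || pg$r[1] <= r_gene_threshold) next
    if (pm$excluded[1] || is.na(pm$q_bh[1]) || pm$q_bh[1] > q_threshold) next
    out[[length(out) + 1L]] <- data.frame(
      pseudogene_id = shared$pseudogene_id[i],
      parent_gene_id = shared$parent_gene_id[i],
      mirna_id = shared$mirna_id[i],
      r_pseudo_gene = pg$r[1], r_pseudo_mirna = pm$r[1],
      r_gene_mirna = if (nrow(gm)) gm$r[1] else NA_real_,
      q_pseudo_mirna = pm$q_bh[1],
      q_gene_mirna = if (nrow(gm)) gm$q_bh[1] else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(pseudogene_id = character(),
                      parent_gene_id = character(), mirna_id = character(),
                      r_pseudo_gene = numeric(), r_pseudo_mirna = numeric(),
                      r_gene_mirna = numeric(), q_pseudo_mirna = numeric(),
                      q_gene_mirna = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
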