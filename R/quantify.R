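#' Read alignment records from TSV
#'
#' Alignment records carry every candidate alignment the aligner reported for
#' each read, one row per alignment: `read_id`, `chrom`, `start` (0-based),
#' `block_starts` / `block_ends` (comma-joined 0-based half-open splice
#' blocks; a single block for direct alignments), `mismatches`.
#'
#' @param path Path to the alignment TSV (written by [write_alignment_tsv()]
#'   or the simulator).
#' @return Data frame of alignment records.
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "start", "block_starts", "block_ends",
            "mismatches")
  if (!all(need %in% names(df)))
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  # single-block records parse as integers; blocks are always strings
  df$block_starts <- as.character(df$block_starts)
  df$block_ends <- as.character(df$block_ends)
  df
}

#' @rdname read_alignment_tsv
#' @param records Data frame of alignment records.
#' @export
write_alignment_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

parse_blocks <- function(starts, ends) {
  cbind(start = as.integer(strsplit(starts, ",")[[1]]),
        end = as.integer(strsplit(ends, ",")[[1]]))
}

# gene lookup table: one row per consensus interval
consensus_table <- function(models) {
  rows <- lapply(models, function(m) {
    cm <- build_consensus_model(m)
    data.frame(gene_id = cm$gene_id, chrom = cm$chrom,
               start = cm$intervals$start, end = cm$intervals$end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

genes_at_position <- function(ctab, chrom, pos) {
  hit <- ctab$chrom == chrom & ctab$start <= pos & pos < ctab$end
  unique(ctab$gene_id[hit])
}

# Offset of a spliced read's k-mer within a synthetic region, or NA if the
# read does not correspond to a contiguous k-mer of that region.
region_offset_for_read <- function(region, k, left_end_pos, right_start_pos,
                                   d) {
  gpos <- region_genomic_positions(region)
  covered <- c(seq.int(left_end_pos - d, left_end_pos - 1L),
               seq.int(right_start_pos, right_start_pos + (k - d) - 1L))
  idx <- match(covered, gpos)
  if (anyNA(idx)) return(NA_integer_)
  idx <- sort(idx)
  if (length(idx) != k || idx[k] - idx[1] != k - 1L) return(NA_integer_)
  idx[1]   # 1-based k-mer start within the region sequence
}

#' Filter aligned reads to the uniquely mappable set
#'
#' A read is retained iff it is uniquely aligned (exactly one reported
#' alignment) and either (1) its direct alignment starts at a mappable genomic
#' position, or (2) it has a spliced alignment whose junction k-mer occurs
#' exactly once in genome plus transcriptome (the matching synthetic-region
#' k-mer is flagged unique). Retained reads are assigned to genes whose
#' consensus model contains the alignment start (direct) or that own the
#' junction (spliced); a read falling in two overlapping genes is counted for
#' both. Spliced reads crossing more than one junction cannot be certified by
#' a single synthetic region and are classified unmappable.
#'
#' @param records Alignment records (see [read_alignment_tsv()]); must carry
#'   all reported alignments per read.
#' @param track `MappabilityTrack` computed at the read length (`k`).
#' @param models Named list of gene models used for read-to-gene assignment.
#' @param sample_id Sample label stored in the result.
#' @return A `MappableReadSet`: list with `sample_id`, `gene_counts` (named
#'   integer over all genes), `total_reads` (all aligned input reads,
#'   pre-filter), and `ledger`, the per-read disposition counts
#'   (`retained`, `dropped_multi`, `dropped_unmappable`, `dropped_nongenic`),
#'   which sum to `total_reads`.
#' @export
filter_reads <- function(records, track, models, sample_id = "sample1") {
  k <- track$k
  ctab <- consensus_table(models)
  meta <- track$region_meta
  gene_counts <- stats::setNames(integer(length(models)), names(models))
  ledger <- c(retained = 0L, dropped_multi = 0L, dropped_unmappable = 0L,
              dropped_nongenic = 0L)
  by_read <- split(seq_len(nrow(records)), records$read_id)
  for (idx in by_read) {
    if (length(idx) > 1) { ledger["dropped_multi"] <- ledger["dropped_multi"] + 1L; next }
    rec <- records[idx, ]
    blocks <- parse_blocks(rec$block_starts, rec$block_ends)
    rlen <- sum(blocks[, "end"] - blocks[, "start"])
    if (rlen != k)
      stop("read '", rec$read_id, "' has length ", rlen,
           " but mappability track was computed at k = ", k)
    genes <- character(0); mappable <- FALSE
    if (nrow(blocks) == 1) {
      flags <- track$genome[[rec$chrom]]
      if (is.null(flags)) stop("chromosome '", rec$chrom, "' not in track")
      pos <- blocks[1, "start"]
      mappable <- pos + 1L <= length(flags) && isTRUE(flags[pos + 1L])
      if (mappable) genes <- genes_at_position(ctab, rec$chrom, pos)
    } else if (nrow(blocks) == 2) {
      le <- blocks[1, "end"]; rs <- blocks[2, "start"]
      d <- blocks[1, "end"] - blocks[1, "start"]
      cand <- which(meta$chrom == rec$chrom & meta$left_end == le &
                    meta$right_start == rs)
      for (ri in cand) {
        off <- region_offset_for_read(meta[ri, ], k, le, rs, d)
        if (is.na(off)) next
        flags <- track$regions[[meta$junction_id[ri]]]
        if (off <= length(flags) && isTRUE(flags[off])) {
          mappable <- TRUE
          genes <- union(genes, strsplit(meta$gene_ids[ri], ",")[[1]])
        }
      }
    }
    if (!mappable) {
      ledger["dropped_unmappable"] <- ledger["dropped_unmappable"] + 1L
    } else if (length(genes) == 0) {
      ledger["dropped_nongenic"] <- ledger["dropped_nongenic"] + 1L
    } else {
      ledger["retained"] <- ledger["retained"] + 1L
      gene_counts[genes] <- gene_counts[genes] + 1L
    }
  }
  structure(list(sample_id = sample_id, gene_counts = gene_counts,
                 total_reads = length(by_read), ledger = ledger),
            class = "MappableReadSet")
}

#' Naive unique-read counting (no mappability filter)
#'
#' Counts uniquely aligned reads per gene by alignment start position,
#' trusting every unique alignment. This is the baseline the mappability
#' filter improves on: in the presence of subject SNPs and read errors, naive
#' counting attributes uniquely *mis*aligned reads to pseudogenes.
#'
#' @inheritParams filter_reads
#' @return Named integer vector of per-gene unique-read counts.
#' @export
count_reads_naive <- function(records, models) {
  ctab <- consensus_table(models)
  gene_counts <- stats::setNames(integer(length(models)), names(models))
  by_read <- split(seq_len(nrow(records)), records$read_id)
  for (idx in by_read) {
    if (length(idx) > 1) next
    rec <- records[idx, ]
    blocks <- parse_blocks(rec$block_starts, rec$block_ends)
    genes <- genes_at_position(ctab, rec$chrom, blocks[1, "start"])
    gene_counts[genes] <- gene_counts[genes] + 1L
  }
  gene_counts
}

#' RPKUM: reads per kilobase of uniquely mappable transcript per million reads
#'
#' `RPKUM = retained_reads * 1e9 / (mappable_bases * total_reads)`. Replacing
#' the transcript length of classical RPKM with the count of mappable bases
#' avoids underestimating expression when reads over unmappable regions are
#' discarded; the two coincide for fully mappable genes. Vectorized over its
#' arguments.
#'
#' @param retained_reads Mappability-filtered read count(s).
#' @param mappable_bases Mappable bases of the gene(s); where 0, the value is
#'   undefined and `NA` is returned (not 0, not infinity).
#' @param total_reads Library size: all aligned reads in the sample,
#'   pre-filter. Must be positive.
#' @return Numeric RPKUM value(s).
#' @export
compute_rpkum <- function(retained_reads, mappable_bases, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(mappable_bases < 0)) stop("mappable_bases must be nonnegative")
  out <- retained_reads * 1e9 / (mappable_bases * total_reads)
  out[mappable_bases == 0] <- NA_real_
  out
}

#' Assemble an RPKUM expression matrix across samples
#'
#' @param samples List of `MappableReadSet` objects (one per sample, from
#'   [filter_reads()]).
#' @param base_counts List of `MappableBaseCount` objects covering every gene.
#' @param min_bases Genes with fewer mappable bases are flagged
#'   unquantifiable (default 50) and excluded from transcription calls.
#' @return An `ExpressionMatrix`: list with `rpkum` and `counts`
#'   (genes x samples matrices), `mappable_bases`, `total_reads`, and
#'   `unquantifiable` (named logical).
#' @export
build_expression_matrix <- function(samples, base_counts, min_bases = 50) {
  mb <- stats::setNames(vapply(base_counts, function(b) b$mappable_bases, 0L),
                        vapply(base_counts, function(b) b$gene_id, ""))
  sample_ids <- vapply(samples, function(s) s$sample_id, "")
  genes <- names(samples[[1]]$gene_counts)
  if (!all(genes %in% names(mb)))
    stop("missing mappable-base counts for: ",
         paste(setdiff(genes, names(mb)), collapse = ", "))
  counts <- sapply(samples, function(s) s$gene_counts[genes])
  counts <- matrix(counts, nrow = length(genes),
                   dimnames = list(genes, sample_ids))
  totals <- vapply(samples, function(s) as.numeric(s$total_reads), 0)
  if (any(totals == 0))
    stop("sample(s) with zero total reads: ",
         paste(sample_ids[totals == 0], collapse = ", "))
  names(totals) <- sample_ids
  rpkum <- counts
  for (j in seq_along(totals))
    rpkum[, j] <- compute_rpkum(counts[, j], mb[genes], totals[j])
  structure(list(rpkum = rpkum, counts = counts,
                 mappable_bases = mb[genes], total_reads = totals,
                 unquantifiable = stats::setNames(mb[genes] < min_bases,
                                                  genes)),
            class = "ExpressionMatrix")
}

#' Call transcribed and recurrently transcribed genes
#'
#' A gene is called transcribed if it has at least `min_bases` mappable bases
#' and, in at least one sample, at least `min_reads` mappability-filtered
#' reads and `min_rpkum` RPKUM. It is recurrent if the number of samples
#' meeting the read and RPKUM thresholds reaches
#' `floor(recurrence_fraction * n_samples)` (never less than 1).
#'
#' @param em An `ExpressionMatrix` from [build_expression_matrix()].
#' @param min_bases,min_reads,min_rpkum,recurrence_fraction Thresholds;
#'   defaults 50 mappable bases, 50 reads, 1 RPKUM, and recurrence in 10
#'   percent of samples.
#' @return Data frame with one row per gene: `gene_id`,
#'   `n_samples_transcribed`, `is_transcribed`, `is_recurrent`,
#'   `unquantifiable`.
#' @export
call_transcribed <- function(em, min_bases = 50, min_reads = 50,
                             min_rpkum = 1.0, recurrence_fraction = 0.10) {
  n_samples <- ncol(em$rpkum)
  need <- max(1L, as.integer(floor(recurrence_fraction * n_samples)))
  pass <- em$counts >= min_reads & !is.na(em$rpkum) & em$rpkum >= min_rpkum
  n_tr <- rowSums(pass)
  unq <- em$unquantifiable | em$mappable_bases < min_bases
  n_tr[unq] <- 0L
  data.frame(gene_id = rownames(em$rpkum),
             n_samples_transcribed = as.integer(n_tr),
             is_transcribed = n_tr >= 1L & !unq,
             is_recurrent = n_tr >= need & !unq,
             unquantifiable = unname(unq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a genes-by-samples numeric matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path File path.
#' @return `path` invisibly, or the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d gene(s) x %d sample(s); %d unquantifiable\n",
              nrow(x$rpkum), ncol(x$rpkum), sum(x$unquantifiable)))
  invisible(x)
}

#' @export
print.MappableReadSet <- function(x, ...) {
  cat(sprintf("MappableReadSet '%s': %d reads; retained %d, multi %d, unmappable %d, non-genic %d\n",
              x$sample_id, x$total_reads, x$ledger["retained"],
              x$ledger["dropped_multi"], x$ledger["dropped_unmappable"],
              x$ledger["dropped_nongenic"]))
  invisible(x)
}
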