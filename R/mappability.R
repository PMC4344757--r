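#' Build synthetic regions around splice junctions
#'
#' A synthetic region concatenates the `k - 1` bases of donor exon immediately
#' upstream of a splice junction with the `k - 1` bases of acceptor exon
#' immediately downstream, in transcript orientation (reverse-complemented for
#' minus-strand junctions). It therefore contains every k-mer a read of length
#' `k` can produce while crossing that junction, and nothing else: all
#' `k - 1` k-mer starts of a full-length region span the junction.
#'
#' Exons shorter than `k - 1` contribute only their available bases and the
#' region is flagged `truncated`; sequences are never padded.
#'
#' @param models Named list of gene models (see [load_annotations()]).
#' @param genome A `DNAStringSet` genome.
#' @param k Read length in bases (`k >= 2`).
#' @return A data frame with one row per distinct junction: `junction_id`,
#'   `chrom`, `strand`, `gene_ids`, `seq`, genomic extents of the two pieces
#'   (`left_start`, `left_end`, `right_start`, `right_end`; "left"/"right" are
#'   genomic, not transcript, sides), and `truncated`.
#' @export
build_synthetic_regions <- function(models, genome, k) {
  stopifnot(k >= 2)
  chrom_seq <- stats::setNames(as.character(genome), names(genome))
  best <- list()   # junction key -> row; keep longest pieces, merge gene ids
  for (m in models) {
    for (ex in m$transcripts) {
      if (nrow(ex) < 2) next
      exg <- ex[order(ex$start), , drop = FALSE]
      for (i in seq_len(nrow(exg) - 1L)) {
        chrom <- exg$chrom[i]; strand <- exg$strand[i]
        ls <- exg$start[i];     le <- exg$end[i]
        rs <- exg$start[i + 1]; re <- exg$end[i + 1]
        key <- paste(chrom, le, rs, strand, sep = ":")
        left_start <- max(ls, le - (k - 1L)); right_end <- min(re, rs + (k - 1L))
        prev <- best[[key]]
        if (!is.null(prev)) {
          gids <- union(prev$gene_ids, m$gene_id)
          left_start <- min(left_start, prev$left_start)
          right_end <- max(right_end, prev$right_end)
        } else gids <- m$gene_id
        best[[key]] <- list(junction_id = key, chrom = chrom, strand = strand,
                            gene_ids = gids,
                            left_start = left_start, left_end = le,
                            right_start = rs, right_end = right_end,
                            truncated = (le - left_start < k - 1L) ||
                                        (right_end - rs < k - 1L))
      }
    }
  }
  if (length(best) == 0)
    return(data.frame(junction_id = character(), chrom = character(),
                      strand = character(), gene_ids = character(),
                      seq = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), truncated = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(best, function(b) {
    fwd <- paste0(substr(chrom_seq[[b$chrom]], b$left_start + 1L, b$left_end),
                  substr(chrom_seq[[b$chrom]], b$right_start + 1L, b$right_end))
    seq <- if (b$strand == "-") revcomp_str(fwd) else fwd
    data.frame(junction_id = b$junction_id, chrom = b$chrom, strand = b$strand,
               gene_ids = paste(sort(b$gene_ids), collapse = ","), seq = seq,
               left_start = b$left_start, left_end = b$left_end,
               right_start = b$right_start, right_end = b$right_end,
               truncated = b$truncated, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Genomic position of every base of a synthetic region
#'
#' Maps region coordinates (0-based, transcript orientation) back to genomic
#' positions on the region's chromosome.
#'
#' @param region One row of the data frame from [build_synthetic_regions()].
#' @return Integer vector, one 0-based genomic position per region base.
#' @export
region_genomic_positions <- function(region) {
  pos <- c(seq.int(region$left_start, region$left_end - 1L),
           seq.int(region$right_start, region$right_end - 1L))
  if (region$strand == "-") rev(pos) else pos
}

new_mappability_track <- function(k, epsilon, genome_flags, region_flags,
                                  region_meta) {
  structure(list(k = k, epsilon = epsilon, genome = genome_flags,
                 regions = region_flags, region_meta = region_meta),
            class = "MappabilityTrack")
}

mappability_core <- function(genome, regions, k, epsilon, brute) {
  stopifnot(k >= 2, epsilon >= 0)
  chrom_seq <- stats::setNames(as.character(genome), names(genome))
  if (any(nchar(chrom_seq) < k))
    warning("chromosome(s) shorter than k = ", k, " are entirely unmappable")
  region_seq <- if (is.null(regions) || nrow(regions) == 0) character(0)
                else regions$seq
  res <- cpp_mappability(unname(chrom_seq), unname(region_seq),
                         as.integer(k), as.integer(epsilon), brute)
  genome_flags <- stats::setNames(res$genome, names(chrom_seq))
  region_flags <- stats::setNames(res$regions,
                                  if (length(region_seq)) regions$junction_id
                                  else character(0))
  meta <- if (is.null(regions))
    data.frame(junction_id = character(), stringsAsFactors = FALSE) else regions
  new_mappability_track(k, epsilon, genome_flags, region_flags, meta)
}

#' Compute the epsilon-tolerant mappability track
#'
#' A position `i` of the genome is mappable at read length `k` and safety
#' margin `epsilon` iff no other k-mer occurrence — at any other genomic start,
#' on either strand, or within any synthetic region — lies within Hamming
#' distance `epsilon` of the k-mer starting at `i`. The safety margin
#' guarantees that a read carrying up to `epsilon` base-call errors or SNPs
#' cannot be uniquely misaligned to a mappable position. k-mers containing `N`
#' are unmappable and are excluded from being anyone's neighbor. The same rule
#' is applied to every synthetic-region k-mer, yielding the per-region
#' uniqueness flags used for spliced reads.
#'
#' @param genome A `DNAStringSet` genome.
#' @param regions Synthetic regions from [build_synthetic_regions()], or
#'   `NULL` for genome-only mappability.
#' @param k Read length (default 50, the typical short-read length).
#' @param epsilon Mismatch safety margin (default 2, matching aligners that
#'   allow two mismatches).
#' @return A `MappabilityTrack`: list with `k`, `epsilon`, `genome` (per-chrom
#'   logical vector over k-mer start positions, length `L - k + 1`), `regions`
#'   (per-junction logical vector over the region's k-mer starts), and
#'   `region_meta`.
#' @seealso [brute_force_mappability()] for the exhaustive reference
#'   implementation used as a test oracle.
#' @export
compute_mappability <- function(genome, regions = NULL, k = 50, epsilon = 2) {
  mappability_core(genome, regions, k, epsilon, brute = FALSE)
}

#' Mappability by exhaustive all-pairs Hamming comparison
#'
#' Same contract as [compute_mappability()], implemented by comparing every
#' k-mer occurrence against every other occurrence directly. Quadratic in
#' genome size and guarded to 50 kb of total sequence; serves as the
#' independent oracle for the accelerated pigeonhole search.
#'
#' @inheritParams compute_mappability
#' @export
brute_force_mappability <- function(genome, regions = NULL, k = 50,
                                    epsilon = 2) {
  total <- sum(Biostrings::width(genome)) +
    if (is.null(regions)) 0L else sum(nchar(regions$seq))
  if (total > 50000)
    stop("brute_force_mappability refuses inputs over 50 kb (got ",
         total, " bases)")
  mappability_core(genome, regions, k, epsilon, brute = TRUE)
}

#' Genomic bases covered by mappable k-mers
#'
#' Converts start-position mappability to per-base coverage: a base is
#' genome-mappable if at least one mappable k-mer window covers it.
#'
#' @param track A `MappabilityTrack`.
#' @param chrom Chromosome name.
#' @return An `IRanges` of 1-based covered positions.
#' @keywords internal
mappable_base_ranges <- function(track, chrom) {
  flags <- track$genome[[chrom]]
  if (is.null(flags)) stop("chromosome '", chrom, "' not in mappability track")
  starts <- which(flags)   # 1-based k-mer start positions
  if (length(starts) == 0) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts, width = track$k))
}

#' Count mappable bases of a consensus gene model
#'
#' A consensus position counts as mappable if either (1) it is covered by a
#' mappable k-mer of the genome track, or (2) it falls within the genomic
#' provenance of a synthetic-region k-mer flagged unique — the positions a
#' uniquely-placeable spliced read can cover.
#'
#' @param consensus A `ConsensusGeneModel` from [build_consensus_model()].
#' @param track A `MappabilityTrack` computed with the synthetic regions.
#' @return A `MappableBaseCount`: list with `gene_id`, `mappable_bases`,
#'   `total_consensus_bases`, `fraction`.
#' @export
count_mappable_bases <- function(consensus, track) {
  chrom <- consensus$chrom
  if (!chrom %in% names(track$genome))
    stop("chromosome '", chrom, "' absent from mappability track")
  cov <- mappable_base_ranges(track, chrom)
  # clause (2): provenance of unique junction k-mers
  extra <- integer(0)
  meta <- track$region_meta
  if (!is.null(meta) && nrow(meta) > 0) {
    for (i in seq_len(nrow(meta))) {
      if (meta$chrom[i] != chrom) next
      flags <- track$regions[[meta$junction_id[i]]]
      if (is.null(flags) || !any(flags)) next
      gpos <- region_genomic_positions(meta[i, ])   # 0-based, per region base
      k <- track$k
      for (j in which(flags)) {                     # k-mer start j (1-based)
        extra <- c(extra, gpos[j:(j + k - 1L)])
      }
    }
  }
  if (length(extra) > 0) {
    cov <- IRanges::reduce(c(cov, IRanges::IRanges(start = unique(extra) + 1L,
                                                   width = 1L)))
  }
  cons <- IRanges::IRanges(start = consensus$intervals$start + 1L,
                           end = consensus$intervals$end)
  total <- sum(IRanges::width(cons))
  mappable <- sum(IRanges::width(IRanges::intersect(cov, cons)))
  structure(list(gene_id = consensus$gene_id,
                 mappable_bases = mappable,
                 total_consensus_bases = total,
                 fraction = if (total > 0) mappable / total else NA_real_),
            class = "MappableBaseCount")
}

#' Per-gene mappable-base report
#'
#' @param models Named list of gene models.
#' @param track A `MappabilityTrack`.
#' @return Data frame with columns `gene_id`, `mappable_bases`,
#'   `consensus_bases`, `fraction`.
#' @export
mappable_base_report <- function(models, track) {
  rows <- lapply(models, function(m) {
    mc <- count_mappable_bases(build_consensus_model(m), track)
    data.frame(gene_id = mc$gene_id, mappable_bases = mc$mappable_bases,
               consensus_bases = mc$total_consensus_bases,
               fraction = mc$fraction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a mappability track to BED
#'
#' Emits maximal runs of mappable k-mer start positions as BED intervals
#' (0-based half-open over start coordinates). Header comment lines record
#' `k`, `epsilon` and per-chromosome vector lengths so the genome track
#' round-trips losslessly; synthetic-region flags are not serialized (they are
#' regenerated from the annotation).
#'
#' @param track A `MappabilityTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mappability_bed <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mappability k=%d epsilon=%d", track$k, track$epsilon),
             con)
  for (chrom in names(track$genome)) {
    flags <- track$genome[[chrom]]
    writeLines(sprintf("#chrom %s %d", chrom, length(flags)), con)
    if (length(flags) == 0 || !any(flags)) next
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths      # 0-based
    keep <- r$values
    writeLines(sprintf("%s\t%d\t%d", chrom, starts[keep], ends[keep]), con)
  }
  invisible(path)
}

#' Load a mappability track written by [write_mappability_bed()]
#'
#' @param path Path to the BED file.
#' @return A `MappabilityTrack` (with empty synthetic-region flags).
#' @export
load_mappability_bed <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#mappability ", lines, value = TRUE)
  if (length(hdr) != 1)
    stop("missing '#mappability k=.. epsilon=..' header in ", path)
  k <- as.integer(sub(".*k=(\\d+).*", "\\1", hdr))
  eps <- as.integer(sub(".*epsilon=(\\d+).*", "\\1", hdr))
  if (is.na(k) || is.na(eps)) stop("unparseable mappability header: ", hdr)
  chrom_lines <- grep("^#chrom ", lines, value = TRUE)
  if (length(chrom_lines) == 0) stop("missing '#chrom' length records in ", path)
  parts <- strsplit(sub("^#chrom ", "", chrom_lines), " ")
  flags <- stats::setNames(
    lapply(parts, function(p) logical(as.integer(p[2]))),
    vapply(parts, `[`, "", 1))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) > 0) {
    f <- strsplit(body, "\t")
    for (row in f) {
      chrom <- row[1]; s <- as.integer(row[2]); e <- as.integer(row[3])
      flags[[chrom]][(s + 1L):e] <- TRUE
    }
  }
  new_mappability_track(k, eps, flags, list(),
                        data.frame(junction_id = character(),
                                   stringsAsFactors = FALSE))
}

#' @export
print.MappabilityTrack <- function(x, ...) {
  n_pos <- sum(vapply(x$genome, length, 0L))
  n_map <- sum(vapply(x$genome, sum, 0L))
  cat(sprintf("MappabilityTrack k=%d epsilon=%d: %d chrom(s), %d/%d start positions mappable, %d synthetic region(s)\n",
              x$k, x$epsilon, length(x$genome), n_map, n_pos,
              length(x$regions)))
  invisible(x)
}
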