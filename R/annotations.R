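#' @useDynLib rpkum, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into a named `DNAStringSet`, normalizing all
#' bases to uppercase. Chromosome order follows the file; duplicate headers
#' are an error.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet-class], one entry per chromosome.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # keep only the first word of each header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0)) stop("empty sequence record in FASTA")
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Load gene models from GTF with optional parent-gene map
#'
#' Parses `exon` features from a GTF file into gene models. GTF 1-based closed
#' coordinates are converted to the package's internal 0-based half-open
#' convention. Pseudogene-to-parent links, which GTF cannot carry, come from a
#' separate tab-delimited map with columns `pseudogene_id`, `parent_gene_id`,
#' `pseudo_class` (one of `processed`, `duplicated`, `unitary`).
#'
#' @param gtf_path Path to a GTF file with `exon` features carrying `gene_id`,
#'   `transcript_id` and (optionally) `gene_biotype` attributes.
#' @param parent_map_path Optional path to the parent map TSV.
#' @param genome Optional genome (`DNAStringSet`); when supplied, exons falling
#'   outside chromosome bounds raise an error.
#' @return A named list of gene models. Each model is a list with elements
#'   `gene_id`, `biotype` (`"coding"` or `"pseudogene"`), `pseudo_class`,
#'   `parent_gene_id` (or `NA`), and `transcripts`: a named list of exon
#'   data frames (`chrom`, `start`, `end`, `strand`; 0-based half-open) in
#'   transcript order.
#' @export
load_annotations <- function(gtf_path, parent_map_path = NULL, genome = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", gtf_path)
  df <- data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    biotype = if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype)
              else NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    bad <- is.na(lens[df$chrom]) | df$start < 0 | df$end > lens[df$chrom]
    if (any(bad))
      stop("exon outside chromosome bounds: ",
           paste(utils::head(df$transcript_id[bad], 3), collapse = ", "))
  }
  pmap <- NULL
  if (!is.null(parent_map_path)) pmap <- read_parent_map(parent_map_path)

  models <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    txs <- list()
    for (tid in unique(gdf$transcript_id)) {
      ex <- gdf[gdf$transcript_id == tid, c("chrom", "start", "end", "strand")]
      # transcript order: 5' to 3' along the strand
      ex <- ex[order(ex$start, decreasing = ex$strand[1] == "-"), , drop = FALSE]
      rownames(ex) <- NULL
      txs[[tid]] <- ex
    }
    biotype <- gdf$biotype[1]
    is_pseudo <- !is.na(biotype) && grepl("pseudogene", biotype)
    m <- list(gene_id = gid,
              biotype = if (is_pseudo) "pseudogene" else "coding",
              pseudo_class = "none",
              parent_gene_id = NA_character_,
              transcripts = txs)
    if (!is.null(pmap) && gid %in% pmap$pseudogene_id) {
      row <- pmap[match(gid, pmap$pseudogene_id), ]
      m$biotype <- "pseudogene"
      m$pseudo_class <- row$pseudo_class
      if (!is.na(row$parent_gene_id) && nzchar(row$parent_gene_id)) {
        if (!row$parent_gene_id %in% df$gene_id) {
          warning("parent gene '", row$parent_gene_id, "' of '", gid,
                  "' not in annotation; parent unset")
        } else {
          m$parent_gene_id <- row$parent_gene_id
        }
      }
    }
    class(m) <- "GeneModel"
    models[[gid]] <- m
  }
  models
}

read_parent_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pseudogene_id", "parent_gene_id", "pseudo_class")
  if (!all(need %in% names(pm)))
    stop("parent map must have columns: ", paste(need, collapse = ", "))
  pm
}

#' Write gene models to GTF
#'
#' Inverse of [load_annotations()]: emits one `exon` feature per exon,
#' converting back to GTF 1-based closed coordinates.
#'
#' @param models Named list of gene models.
#' @param gtf_path Output path.
#' @return `gtf_path`, invisibly.
#' @export
write_annotations <- function(models, gtf_path) {
  rows <- list()
  for (m in models) {
    for (tid in names(m$transcripts)) {
      ex <- m$transcripts[[tid]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ex$chrom, start = ex$start, end = ex$end, strand = ex$strand,
        gene_id = m$gene_id, transcript_id = tid,
        biotype = if (m$biotype == "pseudogene") "pseudogene" else "protein_coding",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  gr$type <- "exon"
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  gr$gene_biotype <- df$biotype
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(gtf_path)
}

#' Write a parent-gene map TSV
#'
#' @param parent_map Data frame with columns `pseudogene_id`, `parent_gene_id`,
#'   `pseudo_class`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parent_map <- function(parent_map, path) {
  utils::write.table(parent_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Merge all annotated exons of a gene into a consensus model
#'
#' The consensus model is the nonredundant union of every exonic position of
#' every transcript of the gene, so no position is counted twice when tallying
#' mappable bases or assigning reads.
#'
#' @param gene A gene model (see [load_annotations()]).
#' @return A `ConsensusGeneModel`: list with `gene_id`, `chrom`, and
#'   `intervals`, a data frame of sorted disjoint 0-based half-open intervals.
#' @export
build_consensus_model <- function(gene) {
  stopifnot(length(gene$transcripts) >= 1)
  ex <- do.call(rbind, gene$transcripts)
  if (length(unique(ex$chrom)) != 1)
    stop("gene '", gene$gene_id, "' spans multiple chromosomes")
  ir <- IRanges::reduce(IRanges::IRanges(start = ex$start + 1L, end = ex$end))
  out <- list(gene_id = gene$gene_id,
              chrom = ex$chrom[1],
              intervals = data.frame(start = IRanges::start(ir) - 1L,
                                     end = IRanges::end(ir)))
  class(out) <- "ConsensusGeneModel"
  out
}

#' @export
print.ConsensusGeneModel <- function(x, ...) {
  cat("ConsensusGeneModel", x$gene_id, "on", x$chrom, "-",
      nrow(x$intervals), "interval(s),",
      sum(x$intervals$end - x$intervals$start), "bases\n")
  invisible(x)
}

#' Enumerate distinct splice junctions of a set of gene models
#'
#' One junction per adjacent exon pair per transcript, deduplicated across
#' transcripts and genes. Junctions are stored in genomic orientation —
#' `donor_end` is the (exclusive) end of the genomically left exon and
#' `acceptor_start` the start of the genomically right exon — with the strand
#' flag carrying transcript orientation.
#'
#' @param models Named list of gene models.
#' @return Data frame with columns `junction_id`, `chrom`, `donor_end`,
#'   `acceptor_start`, `strand`, and `gene_ids` (comma-joined ids of genes
#'   carrying the junction).
#' @export
enumerate_junctions <- function(models) {
  rows <- list()
  for (m in models) {
    for (ex in m$transcripts) {
      if (nrow(ex) < 2) next
      # genomic order regardless of transcript order
      exg <- ex[order(ex$start), , drop = FALSE]
      for (i in seq_len(nrow(exg) - 1L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = exg$chrom[i], donor_end = exg$end[i],
          acceptor_start = exg$start[i + 1L], strand = exg$strand[i],
          gene_id = m$gene_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(junction_id = character(), chrom = character(),
                      donor_end = integer(), acceptor_start = integer(),
                      strand = character(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  key <- paste(df$chrom, df$donor_end, df$acceptor_start, df$strand, sep = ":")
  gene_ids <- vapply(split(df$gene_id, key),
                     function(g) paste(sort(unique(g)), collapse = ","), "")
  df <- df[!duplicated(key), , drop = FALSE]
  df$gene_ids <- gene_ids[paste(df$chrom, df$donor_end, df$acceptor_start,
                                df$strand, sep = ":")]
  df$junction_id <- paste(df$chrom, df$donor_end, df$acceptor_start,
                          df$strand, sep = ":")
  rownames(df) <- NULL
  df[, c("junction_id", "chrom", "donor_end", "acceptor_start", "strand",
         "gene_ids")]
}
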