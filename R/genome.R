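#' Read a genome from a FASTA file
#'
#' Record names are truncated at the first whitespace and sequences are
#' uppercased. Only `A`, `C`, `G`, `T` and `N` are accepted downstream.
#'
#' @param path Path to a (multi-record, possibly line-wrapped) FASTA file.
#' @return A named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  as_genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  g <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path, width = width)
  invisible(path)
}

# coerce to a validated named character genome
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome)) {
    g <- genome
  } else {
    stop("genome must be a named character vector or a DNAStringSet")
  }
  if (length(g) == 0L) stop("genome is empty")
  if (is.null(names(g)) || anyNA(names(g)) || any(names(g) == "")) {
    stop("every chromosome needs a name")
  }
  if (anyDuplicated(names(g))) stop("duplicated chromosome names")
  g <- toupper(g)
  for (ch in names(g)) {
    bad <- regexpr("[^ACGTN]", g[[ch]])
    if (bad != -1L) {
      stop(sprintf(
        "chromosome '%s': non-nucleotide character '%s' at position %d",
        ch, substr(g[[ch]], bad, bad), as.integer(bad)))
    }
  }
  g
}

#' Find GATC motif start positions in a sequence
#'
#' Positions are 0-based. The motif cannot overlap itself, so returned
#' positions are always at least 4 bp apart.
#'
#' @param seq A single uppercase nucleotide string (`N` allowed).
#' @return Integer vector of 0-based motif start positions, ascending.
#' @examples
#' find_gatc_sites("AAGATCTTGATCAA")  # 2, 8
#' @export
find_gatc_sites <- function(seq) {
  seq <- as.character(seq)
  if (length(seq) != 1L) stop("seq must be a single string")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L) {
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 substr(seq, bad, bad), as.integer(bad)))
  }
  m <- gregexpr("GATC", seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Build the GATC fragment map of a genome
#'
#' Chromosomes are partitioned into fragments delimited by GATC motif
#' start positions: with motif starts `p1 < ... < pk` on a chromosome of
#' length `L`, the fragments are `[0,p1), [p1,p2), ..., [pk,L)` (each
#' motif's 4 bp belong to the downstream fragment). A chromosome without
#' the motif yields a single fragment. Coordinates are 0-based half-open;
#' fragment ids are genome-wide unique and ascending in chromosome then
#' coordinate order.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @return A `fragment_map`: a data frame with columns `chrom`, `start`,
#'   `end`, `id` and a `chrom_lengths` attribute.
#' @export
build_fragment_map <- function(genome) {
  g <- as_genome(genome)
  lens <- vapply(g, nchar, integer(1))
  parts <- lapply(names(g), function(ch) {
    L <- nchar(g[[ch]])
    p <- find_gatc_sites(g[[ch]])
    starts <- c(0L, p)
    ends <- c(p, L)
    keep <- starts < ends  # a motif at position 0 leaves no upstream fragment
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, parts)
  map$id <- seq_len(nrow(map))
  fragment_map(map, chrom_lengths = lens)
}

#' Construct / validate a fragment map
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `id`.
#' @param chrom_lengths Named integer vector of chromosome lengths; if
#'   missing, taken as the last fragment end per chromosome.
#' @return A validated `fragment_map`.
#' @export
fragment_map <- function(df, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  chroms <- unique(df$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(df$end[df$chrom == ch]),
                            integer(1))
  }
  chrom_lengths <- chrom_lengths[chroms]
  ord <- order(match(df$chrom, chroms), df$start)
  df <- df[ord, , drop = FALSE]
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  df$id <- as.integer(df$id)
  rownames(df) <- NULL
  for (ch in chroms) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (sub$start[1L] != 0L) stop("first fragment must start at 0 on ", ch)
    if (sub$end[nrow(sub)] != chrom_lengths[[ch]]) {
      stop("last fragment must end at the chromosome length on ", ch)
    }
    if (nrow(sub) > 1L && any(sub$end[-nrow(sub)] != sub$start[-1L])) {
      stop("fragments must tile the chromosome contiguously on ", ch)
    }
    if (any(sub$start >= sub$end)) stop("empty fragment on ", ch)
  }
  if (any(df$id != seq_len(nrow(df)))) {
    stop("fragment ids must be 1..n in chromosome/coordinate order")
  }
  structure(df, chrom_lengths = chrom_lengths,
            class = c("fragment_map", "data.frame"))
}

#' Fragment lengths in bp
#' @param map A `fragment_map`.
#' @return Integer vector of fragment lengths.
#' @export
fragment_lengths <- function(map) map$end - map$start

#' Median GATC fragment length
#'
#' The median spacing between consecutive GATC sites, i.e. the median
#' fragment length over all fragments of the map.
#'
#' @param map A `fragment_map`.
#' @return Median fragment length in bp.
#' @export
median_fragment_spacing <- function(map) {
  if (nrow(map) == 0L) stop("empty fragment map")
  stats::median(fragment_lengths(map))
}

#' @export
print.fragment_map <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat(sprintf("GATC fragment map: %d fragments on %d chromosome(s), median length %g bp\n",
              nrow(x), length(cl), stats::median(x$end - x$start)))
  NextMethod()
}

# lightweight signature used to detect mismatched maps between objects
map_signature <- function(map) {
  list(n = nrow(map), chrom_lengths = attr(map, "chrom_lengths"))
}

#' Write a fragment map to BED4 or GFF3
#'
#' BED is 0-based half-open; GFF3 is 1-based closed.
#'
#' @param map A `fragment_map`.
#' @param path Output file.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(map, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.frame(map$chrom, map$start, map$end,
                      paste0("fragment_", map$id))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      map$chrom, IRanges::IRanges(map$start + 1L, map$end))
    S4Vectors::mcols(gr)$type <- "GATC_fragment"
    S4Vectors::mcols(gr)$ID <- paste0("fragment_", map$id)
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Read a fragment map written by [write_fragment_map()]
#'
#' @param path BED4 or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A `fragment_map`.
#' @export
read_fragment_map <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    map <- data.frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]])
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    d <- as.data.frame(gr)
    map <- data.frame(chrom = as.character(d$seqnames),
                      start = d$start - 1L, end = d$end)
  }
  fragment_map(map)
}

#' Construct a gene annotation
#'
#' @param genes Data frame with `gene_id`, `name`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`).
#' @param tss Data frame with `gene_id`, `chrom`, `pos` (0-based bp),
#'   `strand`; defaults to the 5' end of each gene.
#' @param cds Data frame with `chrom`, `start`, `end`, `gene_id`
#'   (0-based half-open) or `NULL` when coding intervals are unknown.
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(genes, tss = NULL, cds = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (is.null(genes$name)) genes$name <- genes$gene_id
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(tss)) {
    tss <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                      pos = ifelse(genes$strand == "+", genes$start,
                                   genes$end - 1L),
                      strand = genes$strand, stringsAsFactors = FALSE)
  }
  tss$pos <- as.integer(tss$pos)
  hit <- match(tss$gene_id, genes$gene_id)
  if (anyNA(hit)) stop("TSS refers to unknown gene_id")
  if (any(tss$pos < genes$start[hit] | tss$pos >= genes$end[hit])) {
    stop("every TSS must lie within its gene body")
  }
  if (!is.null(cds)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(cds)))
    cds$start <- as.integer(cds$start)
    cds$end <- as.integer(cds$end)
    if (nrow(cds) > 0 && any(cds$start >= cds$end)) {
      stop("CDS start must be < end")
    }
  }
  structure(list(genes = genes, tss = tss, cds = cds),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene annotation: %d genes, %d TSS, %s CDS intervals\n",
              nrow(x$genes), nrow(x$tss),
              if (is.null(x$cds)) "no" else nrow(x$cds)))
  invisible(x)
}

#' Read gene annotation from GFF3 or simplified TSV
#'
#' GFF3 files should carry `gene` features (with `ID`, optionally
#' `Name`), and may carry `mRNA` features (TSS are taken from their 5'
#' ends; otherwise from gene 5' ends) and `CDS` features (linked to
#' genes through `Parent`). The TSV format has six columns
#' `gene_id name chrom start end strand` with 0-based half-open
#' coordinates and carries no CDS information.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A `gene_annotation`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            header = FALSE)
    names(df)[1:6] <- c("gene_id", "name", "chrom", "start", "end", "strand")
    return(gene_annotation(df))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  d$seqnames <- as.character(d$seqnames)
  first_chr <- function(x) vapply(x, function(v) as.character(v)[1L],
                                  character(1))
  gene_rows <- d[d$type == "gene", , drop = FALSE]
  if (nrow(gene_rows) == 0L) stop("no gene features in ", path)
  genes <- data.frame(
    gene_id = as.character(gene_rows$ID),
    name = if (!is.null(gene_rows$Name)) {
      ifelse(is.na(gene_rows$Name), as.character(gene_rows$ID),
             as.character(gene_rows$Name))
    } else as.character(gene_rows$ID),
    chrom = gene_rows$seqnames,
    start = gene_rows$start - 1L,
    end = gene_rows$end,
    strand = as.character(gene_rows$strand),
    stringsAsFactors = FALSE)

  mrna <- d[d$type == "mRNA", , drop = FALSE]
  tss <- NULL
  mrna_gene <- character(0)
  if (nrow(mrna) > 0L) {
    mrna_gene <- first_chr(mrna$Parent)
    tss <- data.frame(
      gene_id = mrna_gene,
      chrom = mrna$seqnames,
      pos = ifelse(as.character(mrna$strand) == "+", mrna$start - 1L,
                   mrna$end - 1L),
      strand = as.character(mrna$strand),
      stringsAsFactors = FALSE)
    tss <- tss[tss$gene_id %in% genes$gene_id, , drop = FALSE]
    if (nrow(tss) == 0L) tss <- NULL
  }

  cds_rows <- d[d$type == "CDS", , drop = FALSE]
  cds <- NULL
  if (nrow(cds_rows) > 0L) {
    parent <- first_chr(cds_rows$Parent)
    # Parent may be an mRNA id; chase one level up to the gene
    if (nrow(mrna) > 0L) {
      up <- match(parent, as.character(mrna$ID))
      parent <- ifelse(is.na(up), parent, mrna_gene[up])
    }
    cds <- data.frame(chrom = cds_rows$seqnames,
                      start = cds_rows$start - 1L,
                      end = cds_rows$end,
                      gene_id = parent,
                      stringsAsFactors = FALSE)
  }
  gene_annotation(genes, tss = tss, cds = cds)
}

#' Write gene annotation as GFF3
#'
#' Emits `gene`, `mRNA` (one per TSS) and `CDS` features with
#' `ID`/`Parent` links, 1-based closed coordinates.
#'
#' @param ann A `gene_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  g <- ann$genes
  rows <- list()
  rows$gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Name = g$name, Parent = NA_character_,
    phase = NA_integer_)
  t <- ann$tss
  tg <- g[match(t$gene_id, g$gene_id), , drop = FALSE]
  mrna_id <- paste0(t$gene_id, ".t", stats::ave(seq_len(nrow(t)), t$gene_id,
                                                FUN = seq_along))
  rows$mrna <- GenomicRanges::GRanges(
    tg$chrom, IRanges::IRanges(tg$start + 1L, tg$end), strand = tg$strand,
    type = "mRNA", ID = mrna_id, Name = mrna_id, Parent = t$gene_id,
    phase = NA_integer_)
  if (!is.null(ann$cds) && nrow(ann$cds) > 0L) {
    cc <- ann$cds
    parent_mrna <- mrna_id[match(cc$gene_id, t$gene_id)]
    rows$cds <- GenomicRanges::GRanges(
      cc$chrom, IRanges::IRanges(cc$start + 1L, cc$end),
      strand = g$strand[match(cc$gene_id, g$gene_id)],
      type = "CDS", ID = paste0(cc$gene_id, ".cds", seq_len(nrow(cc))),
      Name = NA_character_, Parent = parent_mrna, phase = 0L)
  }
  gr <- do.call(c, unname(rows))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
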