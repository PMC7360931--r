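# Genome annotation I/O: GFF3 + genomic FASTA (via rtracklayer/Biostrings
# when available) and a minimal GenBank flat-file dialect with simple CDS
# locations (the format the synthetic generator emits).

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a genome annotation from GFF3 + genomic FASTA
#'
#' Extracts CDS features of one contig (the first seqid unless `contig` is
#' given), in genomic order, with strand-aware coding sequences. Requires the
#' `rtracklayer` and `Biostrings` packages.
#'
#' @param gff_file Path to a GFF3 file with CDS features.
#' @param fasta_file Path to the genomic FASTA.
#' @param contig Optional contig/seqid to read.
#' @return A [genome_annotation()] with gene coordinates.
#' @export
read_genome_gff3 <- function(gff_file, fasta_file, contig = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("Biostrings", quietly = TRUE))
    stop("read_genome_gff3 requires the rtracklayer and Biostrings packages")
  gr <- rtracklayer::import(gff_file)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", gff_file)
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(contig)) contig <- as.character(GenomicRanges::seqnames(gr))[1]
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  gr <- gr[order(GenomicRanges::start(gr))]
  if (!contig %in% names(seqs)) stop("contig ", contig, " not in FASTA")
  contig_seq <- as.character(seqs[[contig]])
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else sprintf("cds%04d", seq_along(gr))
  nt <- substring(contig_seq, starts, ends)
  rev <- strands == "-"
  nt[rev] <- revcomp(nt[rev])
  ann <- genome_annotation(contig_id = contig, gene_id = ids, nt_seq = nt,
                           strand = ifelse(rev, "-", "+"), source_format = "gff3")
  ann$genes$start <- starts
  ann$genes$end <- ends
  attr(ann, "contig_seq") <- contig_seq
  ann
}

#' Write a genome annotation to GFF3 + FASTA
#'
#' @param annotation A [genome_annotation()] carrying gene coordinates
#'   (`start`/`end` columns) and a `contig_seq` attribute, as produced by
#'   [generate_genome()] or the readers.
#' @param prefix Output path prefix; writes `<prefix>.gff3` and
#'   `<prefix>.fna`.
#' @param region Optional [gene_region()]: member genes get a
#'   `region_label` attribute.
#' @return The two file paths, invisibly.
#' @export
write_genome_gff3 <- function(annotation, prefix, region = NULL) {
  g <- annotation$genes
  if (is.null(g$start) || is.null(attr(annotation, "contig_seq")))
    stop("annotation lacks coordinates/contig sequence; cannot serialize")
  labels <- rep(NA_character_, nrow(g))
  if (!is.null(region)) labels[region$member_indices] <- region$gene_labels
  attrs <- paste0("ID=", g$gene_id,
                  ifelse(is.na(labels), "", paste0(";region_label=", labels)))
  lines <- c("##gff-version 3",
             sprintf("%s\tgtacarbon\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     annotation$contig_id, g$start, g$end, g$strand, attrs))
  gff <- paste0(prefix, ".gff3")
  fna <- paste0(prefix, ".fna")
  writeLines(lines, gff)
  write_fasta(stats::setNames(attr(annotation, "contig_seq"),
                              annotation$contig_id), fna)
  invisible(c(gff, fna))
}

#' Read a genome annotation from a GenBank flat file
#'
#' A minimal reader for single-record GenBank files with simple CDS locations
#' (`start..end` or `complement(start..end)`; `join(...)` features are
#' skipped with a warning). Gene ids come from `/locus_tag` (or `/gene`)
#' qualifiers.
#'
#' @param file Path to the GenBank file.
#' @return A [genome_annotation()] with gene coordinates.
#' @export
read_genome_genbank <- function(file) {
  lines <- readLines(file)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  contig <- if (is.na(locus)) "unknown" else strsplit(trimws(locus), "\\s+")[[1]][2]
  ori <- grep("^ORIGIN", lines)[1]
  if (is.na(ori)) stop("no ORIGIN section in ", file)
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  contig_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat <- grep("^\\s{5}CDS\\s", lines)
  if (length(feat) == 0L) stop("no CDS features in ", file)
  starts <- integer(0); ends <- integer(0); strands <- character(0); ids <- character(0)
  for (i in feat) {
    loc <- trimws(sub("^\\s{5}CDS\\s+", "", lines[i]))
    if (grepl("join", loc)) {
      warning("skipping joined CDS location: ", loc)
      next
    }
    comp <- grepl("^complement", loc)
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) != 2L) {
      warning("skipping unparsable CDS location: ", loc)
      next
    }
    # qualifiers on the following indented lines
    j <- i + 1L
    id <- NA_character_
    while (j <= length(lines) && grepl("^\\s{6,}", lines[j]) &&
           !grepl("^\\s{5}\\S", lines[j])) {
      q <- trimws(lines[j])
      if (grepl("^/locus_tag=", q)) id <- gsub('^/locus_tag="?|"?$', "", q)
      if (is.na(id) && grepl("^/gene=", q)) id <- gsub('^/gene="?|"?$', "", q)
      j <- j + 1L
    }
    starts <- c(starts, nums[1]); ends <- c(ends, nums[2])
    strands <- c(strands, if (comp) "-" else "+")
    ids <- c(ids, id)
  }
  if (length(starts) == 0L) stop("no usable CDS features in ", file)
  ids[is.na(ids)] <- sprintf("cds%04d", which(is.na(ids)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; strands <- strands[o]; ids <- ids[o]
  nt <- substring(contig_seq, starts, ends)
  nt[strands == "-"] <- revcomp(nt[strands == "-"])
  ann <- genome_annotation(contig_id = contig, gene_id = ids, nt_seq = nt,
                           strand = strands, source_format = "genbank")
  ann$genes$start <- starts
  ann$genes$end <- ends
  attr(ann, "contig_seq") <- contig_seq
  ann
}

#' Write a genome annotation as a minimal GenBank flat file
#'
#' @inheritParams write_genome_gff3
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_genome_genbank <- function(annotation, file) {
  g <- annotation$genes
  contig_seq <- attr(annotation, "contig_seq")
  if (is.null(g$start) || is.null(contig_seq))
    stop("annotation lacks coordinates/contig sequence; cannot serialize")
  out <- c(sprintf("LOCUS       %s %d bp DNA linear BCT",
                   annotation$contig_id, nchar(contig_seq)),
           "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(g))) {
    loc <- if (g$strand[i] == "-")
      sprintf("complement(%d..%d)", g$start[i], g$end[i])
    else sprintf("%d..%d", g$start[i], g$end[i])
    out <- c(out, sprintf("     CDS             %s", loc),
             sprintf('                     /locus_tag="%s"', g$gene_id[i]))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, nchar(contig_seq), 60L)
  chunk <- substring(contig_seq, pos, pmin(pos + 59L, nchar(contig_seq)))
  blocks <- vapply(chunk, function(x) {
    p <- seq(1L, nchar(x), 10L)
    paste(substring(x, p, pmin(p + 9L, nchar(x))), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  out <- c(out, sprintf("%9d %s", pos, tolower(blocks)), "//")
  writeLines(out, file)
  invisible(file)
}
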