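# Codon-position GC decomposition and amino-acid composition analytics for
# gene sets, regions and their genomic neighborhoods.

#' Construct a genome annotation
#'
#' An ordered set of CDS records on one replicon/contig. Gene order must
#' reflect genomic coordinates; each nucleotide sequence must be a
#' coding-strand CDS whose length is divisible by 3 (a trailing stop codon is
#' allowed and trimmed during GC computation).
#'
#' @param contig_id Contig/replicon identifier.
#' @param gene_id Character vector of CDS identifiers (unique).
#' @param nt_seq Character vector of coding-strand nucleotide sequences.
#' @param aa_seq Optional character vector of translations (computed from
#'   `nt_seq` with the standard code if omitted).
#' @param strand Optional vector of "+"/"-" (annotation metadata only;
#'   sequences are always coding-strand).
#' @param source_format One of "genbank", "gff3", "synthetic", "other".
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(contig_id, gene_id, nt_seq, aa_seq = NULL,
                              strand = NULL,
                              source_format = c("other", "genbank", "gff3", "synthetic")) {
  source_format <- match.arg(source_format)
  n <- length(gene_id)
  stopifnot(n >= 1L, length(nt_seq) == n, !anyDuplicated(gene_id))
  nt_seq <- toupper(nt_seq)
  bad <- which(nchar(nt_seq) %% 3L != 0L | nchar(nt_seq) == 0L)
  if (length(bad))
    stop("CDS length not a positive multiple of 3 for gene(s): ",
         paste(gene_id[bad], collapse = ", "))
  if (is.null(aa_seq)) aa_seq <- vapply(nt_seq, translate_cds, character(1), USE.NAMES = FALSE)
  if (is.null(strand)) strand <- rep("+", n)
  structure(list(contig_id = contig_id,
                 genes = data.frame(gene_id = gene_id, nt_seq = nt_seq,
                                    aa_seq = aa_seq, strand = strand,
                                    stringsAsFactors = FALSE),
                 source_format = source_format),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d CDS (%s)\n",
              x$contig_id, nrow(x$genes), x$source_format))
  invisible(x)
}

#' Construct a gene region
#'
#' A labeled, contiguous (or near-contiguous) block of CDS indices within a
#' [genome_annotation()] -- here, homologs of the 17-gene GTA head-tail
#' cluster, labeled g1..g17.
#'
#' @param region_id Region identifier.
#' @param member_indices Integer positions into the annotation's gene table
#'   (1-based).
#' @param gene_labels Character vector of labels (e.g. "g1".."g17"), one per
#'   member; must be unique.
#' @return Object of class `gene_region`.
#' @export
gene_region <- function(region_id, member_indices, gene_labels) {
  member_indices <- as.integer(member_indices)
  stopifnot(length(member_indices) >= 1L, length(member_indices) <= 17L,
            length(gene_labels) == length(member_indices),
            !anyDuplicated(gene_labels), !anyDuplicated(member_indices))
  o <- order(member_indices)
  structure(list(region_id = region_id,
                 member_indices = member_indices[o],
                 gene_labels = gene_labels[o]),
            class = "gene_region")
}

# standard-code translation used when no translation is supplied; trailing
# stop rendered as "" (dropped), internal stops as "*"
translate_cds <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- GENETIC_CODE_1L[codons]
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

GENETIC_CODE_1L <- local({
  c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G", GGG = "G")
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' GC content by codon position
#'
#' Pools codons over a set of coding sequences and returns the fraction of G
#' or C at each of the three codon positions. A trailing stop codon on any
#' sequence is trimmed first so that GC3 is not deflated by the AT-rich stop
#' codons; positions holding ambiguity codes (anything other than A, C, G, T)
#' are excluded from both numerator and denominator of that position.
#'
#' @param genes Character vector of coding-strand nucleotide sequences, or a
#'   [genome_annotation()] (all genes), each of length divisible by 3.
#' @return Object of class `gc_profile`: list with `gc1`, `gc2`, `gc3`
#'   (fractions in \[0, 1\]) and `n_codons`.
#' @export
#' @examples
#' gc_by_codon_position("ATGGCC")  # gc1 0.5, gc2 0.5, gc3 1
gc_by_codon_position <- function(genes) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes$nt_seq
  if (length(genes) == 0L) stop("empty gene set: GC profile undefined")
  genes <- toupper(genes)
  bad <- which(nchar(genes) %% 3L != 0L)
  if (length(bad))
    stop("sequence length not divisible by 3 at position(s): ",
         paste(bad, collapse = ", "))
  counts <- matrix(0, nrow = 3, ncol = 2,
                   dimnames = list(NULL, c("gc", "total")))
  n_codons <- 0L
  for (s in genes) {
    nc <- nchar(s)
    if (nc >= 3L && substr(s, nc - 2L, nc) %in% STOP_CODONS) {
      s <- substr(s, 1L, nc - 3L)
      nc <- nc - 3L
    }
    if (nc == 0L) next
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- rep_len(1:3, nc)
    ok <- chars %in% c("A", "C", "G", "T")
    gc <- chars %in% c("G", "C")
    for (k in 1:3) {
      sel <- pos == k & ok
      counts[k, "gc"] <- counts[k, "gc"] + sum(gc[sel])
      counts[k, "total"] <- counts[k, "total"] + sum(sel)
    }
    n_codons <- n_codons + nc %/% 3L
  }
  if (n_codons == 0L) stop("no codons left after stop trimming; GC profile undefined")
  if (any(counts[, "total"] == 0))
    stop("no unambiguous bases at some codon position")
  structure(list(gc1 = unname(counts[1, "gc"] / counts[1, "total"]),
                 gc2 = unname(counts[2, "gc"] / counts[2, "total"]),
                 gc3 = unname(counts[3, "gc"] / counts[3, "total"]),
                 n_codons = n_codons,
                 counts = counts),
            class = "gc_profile")
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("<gc_profile> GC1 %.4f  GC2 %.4f  GC3 %.4f  (%d codons)\n",
              x$gc1, x$gc2, x$gc3, x$n_codons))
  invisible(x)
}

#' Partition a genome into a region, six flanking windows and the genome set
#'
#' Splits the 51 genes upstream and 51 genes downstream of a gene region into
#' three nonoverlapping 17-gene windows on each side, ordered by distance
#' from the region, and adds the region itself and the whole-genome gene set
#' -- eight labeled groups in total. Windows that run off the contig edge are
#' truncated and flagged rather than dropped.
#'
#' @param annotation A [genome_annotation()].
#' @param region A [gene_region()] within it.
#' @param window_size Genes per window (default 17).
#' @param n_windows Windows per side (default 3).
#' @return List of class `neighborhood_partition`: `groups` (named list of
#'   integer gene-index vectors: `up3`, `up2`, `up1`, `region`, `down1`,
#'   `down2`, `down3`, `genome`; `up1`/`down1` are nearest the region) and
#'   `truncated` (named logical).
#' @export
partition_neighborhood <- function(annotation, region, window_size = 17L,
                                   n_windows = 3L) {
  stopifnot(inherits(annotation, "genome_annotation"), inherits(region, "gene_region"))
  n <- nrow(annotation$genes)
  mem <- region$member_indices
  if (any(mem < 1L | mem > n)) stop("region indices outside annotation")
  lo <- min(mem); hi <- max(mem)
  groups <- list()
  truncated <- logical(0)
  for (w in seq_len(n_windows)) {
    # upstream window w: the w-th block of `window_size` genes moving away
    # from the region start
    u_hi <- lo - 1L - (w - 1L) * window_size
    u_lo <- u_hi - window_size + 1L
    idx <- seq2(max(1L, u_lo), u_hi)
    lab <- paste0("up", w)
    groups[[lab]] <- idx
    truncated[lab] <- length(idx) < window_size
    d_lo <- hi + 1L + (w - 1L) * window_size
    d_hi <- d_lo + window_size - 1L
    idx <- seq2(d_lo, min(n, d_hi))
    lab <- paste0("down", w)
    groups[[lab]] <- idx
    truncated[lab] <- length(idx) < window_size
  }
  # genes inside [lo, hi] not labeled as region members go to the nearest
  # neighborhood window (the innermost one)
  interlopers <- setdiff(seq2(lo, hi), mem)
  if (length(interlopers)) groups[["up1"]] <- sort(c(groups[["up1"]], interlopers))
  groups <- c(groups[paste0("up", rev(seq_len(n_windows)))],
              list(region = mem),
              groups[paste0("down", seq_len(n_windows))],
              list(genome = seq_len(n)))
  truncated <- truncated[names(groups)[names(groups) %in% names(truncated)]]
  if (any(truncated))
    warning("truncated window(s): ",
            paste(sprintf("%s (%d genes)", names(truncated)[truncated],
                          lengths(groups[names(truncated)[truncated]])),
                  collapse = ", "))
  structure(list(groups = groups, truncated = truncated,
                 contig_id = annotation$contig_id, region_id = region$region_id),
            class = "neighborhood_partition")
}

# integer sequence that is empty when from > to (seq() would count down)
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' GC profiles for every group of a neighborhood partition
#'
#' @param annotation A [genome_annotation()].
#' @param partition Result of [partition_neighborhood()].
#' @return data.frame with columns `group_label`, `gc1`, `gc2`, `gc3`,
#'   `n_codons` (empty groups omitted).
#' @export
neighborhood_gc_table <- function(annotation, partition) {
  rows <- lapply(names(partition$groups), function(lab) {
    idx <- partition$groups[[lab]]
    if (length(idx) == 0L) return(NULL)
    p <- gc_by_codon_position(annotation$genes$nt_seq[idx])
    data.frame(group_label = lab, gc1 = p$gc1, gc2 = p$gc2, gc3 = p$gc3,
               n_codons = p$n_codons, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Amino-acid frequencies of a pooled protein set
#'
#' @param proteins Character vector of protein sequences (pooled).
#' @return Named numeric vector over the 20 canonical residues, summing to 1.
#'   Ambiguity codes (X, B, Z, J, U, O) and gaps are excluded from numerator
#'   and denominator.
#' @export
aa_frequencies <- function(proteins) {
  res <- split_residues(proteins)
  res <- res[res %in% AA_ALPHABET]
  if (length(res) == 0L) stop("no canonical residues in protein pool")
  tab <- table(factor(res, levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab) / length(res), AA_ALPHABET)
}

# amino acids encoded by codons with G or C at the first and second
# positions: Ala (GCN), Arg (CGN), Gly (GGN), Pro (CCN); the set is fixed to
# these four even though two Arg codons (AGA/AGG) lack G/C at position 1
GCRICH_AA <- c("A", "R", "G", "P")

#' Pooled abundance of amino acids encoded by GC-rich codons
#'
#' Sum of the frequencies of alanine, arginine, glycine and proline -- the
#' amino acids encoded by codons with G or C in the first and second
#' positions.
#'
#' @inheritParams aa_frequencies
#' @return A fraction in \[0, 1\].
#' @export
gcrich_aa_abundance <- function(proteins) {
  sum(aa_frequencies(proteins)[GCRICH_AA])
}

#' Write a neighborhood GC table to TSV
#' @param tab data.frame from [neighborhood_gc_table()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gc_table <- function(tab, file) {
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
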