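# Energetic scoring of proteins: side-chain carbon content and biosynthetic
# cost (high-energy phosphate bonds per amino acid molecule).

# canonical one-letter codes, alphabetical; this order is also the residue
# tie-break order used throughout the ancestral-sequence machinery
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Load the per-amino-acid cost table
#'
#' Reads the packaged table of side-chain carbon atom counts and aerobic
#' biosynthetic costs (high-energy phosphate bonds per molecule, Akashi &
#' Gojobori's Escherichia coli values) and returns it as a `cost_table`
#' object. Carbon counts follow the side-chain structural formulas (glycine,
#' whose side chain is a lone hydrogen, has 0; tryptophan's methylene plus
#' indole ring has 9).
#'
#' @param file Path to a TSV with columns `amino_acid`, `side_chain_carbons`,
#'   `phosphate_cost`. Defaults to the table shipped with the package.
#' @return An object of class `cost_table`: a list with named numeric vectors
#'   `carbons` and `phosphate_cost` (names = one-letter residue codes) and a
#'   `source` attribute.
#' @export
#' @examples
#' tab <- build_cost_table()
#' tab$carbons[c("G", "A", "F", "W")]
build_cost_table <- function(file = system.file("extdata", "amino_acid_costs.tsv",
                                                package = "gtacarbon")) {
  stopifnot(nzchar(file), file.exists(file))
  d <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("amino_acid", "side_chain_carbons", "phosphate_cost")
  if (!all(need %in% names(d)))
    stop("cost table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(d$amino_acid, AA_ALPHABET))
    stop("cost table must contain exactly the 20 canonical amino acids")
  carbons <- stats::setNames(as.numeric(d$side_chain_carbons), d$amino_acid)[AA_ALPHABET]
  pcost <- stats::setNames(as.numeric(d$phosphate_cost), d$amino_acid)[AA_ALPHABET]
  if (any(pcost <= 0)) stop("phosphate costs must be strictly positive")
  if (carbons[["G"]] != 0 || carbons[["W"]] != 9 || any(carbons < 0 | carbons > 9))
    stop("carbon counts out of range (side chains span Gly = 0 to Trp = 9)")
  structure(list(carbons = carbons, phosphate_cost = pcost, source = file),
            class = "cost_table")
}

#' Score a protein's carbon content and biosynthetic cost
#'
#' Counts side-chain carbon atoms and high-energy phosphate bonds over a
#' protein sequence and normalizes by the number of scored residues.
#' Ambiguity codes and nonstandard residues (X, B, Z, J, U, O, gaps, stops)
#' are excluded from both numerator and denominator.
#'
#' @param seq A protein sequence (single string, or a character vector of
#'   single residues).
#' @param table A `cost_table` from [build_cost_table()].
#' @param protein_id Optional identifier carried into the result.
#' @return An object of class `cost_score`: list with `protein_id`,
#'   `carbons_per_site`, `cost_per_site`, and `length` (number of residues
#'   actually scored).
#' @export
#' @examples
#' tab <- build_cost_table()
#' score_protein("AW", tab)$carbons_per_site  # (1 + 9) / 2 = 5
score_protein <- function(seq, table, protein_id = NA_character_) {
  res <- split_residues(seq)
  keep <- res %in% AA_ALPHABET
  n <- sum(keep)
  if (n == 0L) stop("sequence has no scorable residues")
  res <- res[keep]
  structure(list(protein_id = protein_id,
                 carbons_per_site = sum(table$carbons[res]) / n,
                 cost_per_site = sum(table$phosphate_cost[res]) / n,
                 length = n),
            class = "cost_score")
}

#' @export
print.cost_score <- function(x, ...) {
  cat(sprintf("<cost_score> %s: %.4f carbons/site, %.4f ~P/site over %d residues\n",
              ifelse(is.na(x$protein_id), "(unnamed)", x$protein_id),
              x$carbons_per_site, x$cost_per_site, x$length))
  invisible(x)
}

# uppercase and split sequences into single residues; accepts either one
# string or a vector of strings (pooled)
split_residues <- function(seq) {
  if (length(seq) == 0L) stop("empty sequence set")
  unlist(strsplit(toupper(paste(seq, collapse = "")), "", fixed = TRUE),
         use.names = FALSE)
}

#' Relative carbon utilization of a gene set
#'
#' The ratio of the mean number of side-chain carbon atoms per residue in a
#' focal gene set (e.g. a GTA region's proteins) to that of a housekeeping
#' reference set (e.g. 26 single-copy genes) from the same genome. Dividing
#' by the housekeeping baseline corrects for genome-wide GC-content effects
#' on amino-acid composition, making values comparable across taxa.
#'
#' @param focal,housekeeping Lists of `cost_score` objects (see
#'   [score_protein()]).
#' @param taxon_id Optional genome identifier.
#' @param weighted If `TRUE` (default) residues are pooled across proteins
#'   (length-weighted mean); if `FALSE`, the unweighted mean of per-protein
#'   values is used.
#' @return List of class `relative_utilization` with `taxon_id`, `value`, and
#'   the two per-set means.
#' @export
relative_carbon_utilization <- function(focal, housekeeping,
                                        taxon_id = NA_character_,
                                        weighted = TRUE) {
  if (length(focal) == 0L) stop("empty focal set")
  if (length(housekeeping) == 0L) stop("empty housekeeping set")
  pool <- function(scores) {
    cps <- vapply(scores, function(s) s$carbons_per_site, numeric(1))
    len <- vapply(scores, function(s) s$length, numeric(1))
    if (weighted) sum(cps * len) / sum(len) else mean(cps)
  }
  f <- pool(focal); h <- pool(housekeeping)
  if (h == 0) stop("housekeeping set has zero carbon content; ratio undefined")
  structure(list(taxon_id = taxon_id, value = f / h,
                 focal_mean = f, housekeeping_mean = h, weighted = weighted),
            class = "relative_utilization")
}

#' Summarize cost scores by group
#'
#' Median and quartiles of per-protein carbons/site and cost/site within
#' groups (e.g. "GTA", "viral", "housekeeping") -- the numbers behind
#' box-plot style comparisons.
#'
#' @param scores List of `cost_score` objects.
#' @param grouping Character vector (or factor) of group labels, one per
#'   score, or a named vector mapping `protein_id` to group.
#' @return A data.frame with one row per group: n, medians and quartiles of
#'   both statistics. Empty groups are dropped with a warning.
#' @export
group_cost_summary <- function(scores, grouping) {
  if (length(scores) == 0L) stop("no scores")
  ids <- vapply(scores, function(s) as.character(s$protein_id), character(1))
  if (!is.null(names(grouping))) {
    grouping <- grouping[ids]
    if (anyNA(grouping)) stop("grouping does not cover all protein_ids")
  }
  if (length(grouping) != length(scores))
    stop("grouping must map every score to a group")
  grouping <- as.character(grouping)
  cps <- vapply(scores, function(s) s$carbons_per_site, numeric(1))
  pps <- vapply(scores, function(s) s$cost_per_site, numeric(1))
  groups <- sort(unique(grouping))
  rows <- lapply(groups, function(g) {
    i <- grouping == g
    if (!any(i)) return(NULL)
    q1 <- stats::quantile(cps[i], c(.25, .5, .75), names = FALSE)
    q2 <- stats::quantile(pps[i], c(.25, .5, .75), names = FALSE)
    data.frame(group = g, n = sum(i),
               carbons_q1 = q1[1], carbons_median = q1[2], carbons_q3 = q1[3],
               cost_q1 = q2[1], cost_median = q2[2], cost_q3 = q2[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
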