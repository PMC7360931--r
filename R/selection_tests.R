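# Bootstrap test for net carbon-content change between a viral homolog and
# its ancestral sequence, the conservative cumulative multi-gene variant,
# positively-selected-site carbon accounting, and group-comparison wrappers.

# columns where both aligned sequences carry a residue; returns the pair of
# residue vectors and the original column indices
shared_columns <- function(viral_seq, ancestral_seq) {
  v <- strsplit(toupper(viral_seq), "", fixed = TRUE)[[1]]
  a <- strsplit(toupper(ancestral_seq), "", fixed = TRUE)[[1]]
  if (length(v) != length(a)) stop("aligned sequences must have equal length")
  keep <- v %in% AA_ALPHABET & a %in% AA_ALPHABET
  if (!any(keep)) stop("no shared non-gap columns")
  list(viral = v[keep], ancestral = a[keep], columns = which(keep))
}

#' Net change in side-chain carbons per amino acid
#'
#' Mean side-chain carbon count of the viral sequence minus that of the
#' ancestral sequence, computed over the alignment columns where both carry a
#' residue. Positive values mean the viral homolog gained carbon relative to
#' its ancestor.
#'
#' @param viral_seq,ancestral_seq Aligned protein sequences (equal length,
#'   gaps as `-`).
#' @param table A [build_cost_table()] table.
#' @return A single number (carbons per residue).
#' @export
net_carbon_change <- function(viral_seq, ancestral_seq, table) {
  sh <- shared_columns(viral_seq, ancestral_seq)
  mean(table$carbons[sh$viral] - table$carbons[sh$ancestral])
}

#' Column-resampling bootstrap for net carbon change
#'
#' Resamples the shared non-gap alignment columns with replacement (same
#' number of columns) `n` times, recomputing the net carbon change for each
#' replicate. The one-sided p-value is the proportion of replicates with a
#' zero or negative net change, i.e. the support for "no increase in carbon
#' content in the viral homolog".
#'
#' @inheritParams net_carbon_change
#' @param n Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the replicate stream is deterministic given it.
#' @param gene_id,virus_id Identifiers carried into the result.
#' @return Object of class `bootstrap_result`: `gene_id`, `virus_id`,
#'   `delta_carbons_per_site` (observed), `p_value`, `n_replicates`, `seed`,
#'   `alignment_length_nt` (3 x shared amino-acid columns, the nucleotide
#'   convention used in reports), and `replicates` (the bootstrap deltas).
#' @export
bootstrap_net_change <- function(viral_seq, ancestral_seq, table, n = 1000L,
                                 seed = 1L, gene_id = NA_character_,
                                 virus_id = NA_character_) {
  stopifnot(n >= 1L)
  sh <- shared_columns(viral_seq, ancestral_seq)
  deltas <- unname(table$carbons[sh$viral] - table$carbons[sh$ancestral])
  L <- length(deltas)
  set.seed(seed)
  idx <- matrix(sample.int(L, L * n, replace = TRUE), nrow = L, ncol = n)
  reps <- colMeans(matrix(deltas[idx], nrow = L))
  structure(list(gene_id = gene_id, virus_id = virus_id,
                 delta_carbons_per_site = mean(deltas),
                 p_value = mean(reps <= 0),
                 n_replicates = as.integer(n), seed = as.integer(seed),
                 alignment_length_nt = 3L * L,
                 replicates = reps),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s vs %s: delta %+0.4f carbons/site, p = %.4g (%d replicates, %d nt)\n",
              ifelse(is.na(x$gene_id), "gene", x$gene_id),
              ifelse(is.na(x$virus_id), "ancestor", x$virus_id),
              x$delta_carbons_per_site, x$p_value, x$n_replicates,
              x$alignment_length_nt))
  invisible(x)
}

#' Conservative cumulative net carbon change across genes
#'
#' For each gene, picks the viral homolog with the smallest net carbon change
#' (the conservative choice), then combines genes into a single per-amino-acid
#' estimate: the total carbon difference over all shared columns divided by
#' the total number of shared columns (a length-weighted combination). The
#' bootstrap resamples columns within each gene independently and recombines,
#' and the p-value is the proportion of replicates with a zero or negative
#' cumulative change.
#'
#' @param pairs Named list (one element per gene); each element is a list of
#'   viral/ancestral pairs, themselves lists with elements `viral`,
#'   `ancestral` (aligned sequences) and optionally `virus_id`.
#' @param table A [build_cost_table()] table.
#' @param n Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A `bootstrap_result` whose `gene_id` is `"cumulative"`, plus
#'   `selected` (data.frame: the homolog chosen per gene and its delta).
#' @export
cumulative_net_change <- function(pairs, table, n = 1000L, seed = 1L) {
  stopifnot(length(pairs) >= 1L)
  genes <- names(pairs)
  if (is.null(genes)) genes <- paste0("gene", seq_along(pairs))
  chosen <- lapply(seq_along(pairs), function(i) {
    cand <- pairs[[i]]
    deltas <- vapply(cand, function(p) net_carbon_change(p$viral, p$ancestral, table),
                     numeric(1))
    j <- which.min(deltas)
    p <- cand[[j]]
    sh <- shared_columns(p$viral, p$ancestral)
    list(gene_id = genes[i],
         virus_id = if (!is.null(p$virus_id)) p$virus_id else NA_character_,
         deltas = unname(table$carbons[sh$viral] - table$carbons[sh$ancestral]))
  })
  col_deltas <- lapply(chosen, `[[`, "deltas")
  lens <- lengths(col_deltas)
  total_cols <- sum(lens)
  observed <- sum(vapply(col_deltas, sum, numeric(1))) / total_cols
  set.seed(seed)
  tot <- numeric(n)
  for (d in col_deltas) {
    L <- length(d)
    idx <- matrix(sample.int(L, L * n, replace = TRUE), nrow = L, ncol = n)
    tot <- tot + colSums(matrix(d[idx], nrow = L))
  }
  reps <- tot / total_cols
  structure(list(gene_id = "cumulative", virus_id = NA_character_,
                 delta_carbons_per_site = observed,
                 p_value = mean(reps <= 0),
                 n_replicates = as.integer(n), seed = as.integer(seed),
                 alignment_length_nt = 3L * total_cols,
                 replicates = reps,
                 selected = data.frame(
                   gene_id = vapply(chosen, `[[`, character(1), "gene_id"),
                   virus_id = vapply(chosen, `[[`, character(1), "virus_id"),
                   delta = vapply(col_deltas, mean, numeric(1)),
                   n_columns = lens, stringsAsFactors = FALSE)),
            class = "bootstrap_result")
}

#' Filter positively selected sites
#'
#' Applies the three-part retention rule to a table of Bayes empirical Bayes
#' (BEB) site posteriors: a site is kept iff its posterior probability of
#' positive selection is at least `beb_min` and it is present (non-gap) in at
#' least `presence_min` of the sequences of each of the two partitions (the
#' focal clade and the rest).
#'
#' @param beb_table data.frame with columns `site` (1-based alignment column)
#'   and `probability`; a `column_map` from [filter_columns()] may be given
#'   to translate site numbers from a filtered to the original alignment.
#' @param alignment Named character vector of aligned sequences or matrix.
#' @param focal_taxa Character vector of sequence names forming the focal
#'   partition.
#' @param beb_min Minimum BEB posterior (default 0.95, inclusive).
#' @param presence_min Minimum presence fraction per partition (default 0.5,
#'   inclusive).
#' @param column_map Optional integer vector mapping the BEB site numbering
#'   to original alignment columns.
#' @return data.frame of class `ps_sites`: `alignment_column`,
#'   `beb_posterior`, `presence_focal`, `presence_other`, one row per
#'   retained site.
#' @export
filter_ps_sites <- function(beb_table, alignment, focal_taxa,
                            beb_min = 0.95, presence_min = 0.5,
                            column_map = NULL) {
  stopifnot(all(c("site", "probability") %in% names(beb_table)))
  m <- aln_matrix(alignment)
  if (!all(focal_taxa %in% rownames(m))) stop("focal taxa missing from alignment")
  other_taxa <- setdiff(rownames(m), focal_taxa)
  if (length(other_taxa) == 0L) stop("no sequences outside the focal partition")
  site <- as.integer(beb_table$site)
  if (!is.null(column_map)) {
    if (any(site < 1L | site > length(column_map)))
      stop("BEB site index outside the filtered alignment")
    site <- column_map[site]
  }
  if (any(site < 1L | site > ncol(m))) stop("site index outside alignment")
  gap <- m == "-" | m == "." | m == "?"
  pres_f <- colMeans(!gap[focal_taxa, , drop = FALSE])
  pres_o <- colMeans(!gap[other_taxa, , drop = FALSE])
  out <- data.frame(alignment_column = site,
                    beb_posterior = beb_table$probability,
                    presence_focal = pres_f[site],
                    presence_other = pres_o[site])
  out <- out[out$beb_posterior >= beb_min &
               out$presence_focal >= presence_min &
               out$presence_other >= presence_min, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ps_sites", "data.frame")
  out
}

#' Carbon contribution of positively selected sites
#'
#' For each retained site, the mean side-chain carbon count over the focal
#' partition's residues minus that over the other partition's residues (gaps
#' excluded). Reports the number of sites with a negative difference (sites
#' contributing to a carbon decrease in the focal clade) and the average
#' change, scaled by default per alignment position (protein alignment
#' length) rather than per selected site.
#'
#' @param alignment Named character vector of aligned sequences or matrix.
#' @param ps_sites A [filter_ps_sites()] result (or data.frame with an
#'   `alignment_column` column).
#' @param focal_taxa,other_taxa Character vectors of sequence names.
#' @param table A [build_cost_table()] table.
#' @param gene_id Identifier carried into the result.
#' @param per Denominator for `avg_delta_carbons`: `"alignment"` (default;
#'   divide the summed site deltas by the alignment length) or `"site"`
#'   (divide by the number of selected sites).
#' @return Object of class `site_contribution`: `gene_id`, `n_ps_sites`,
#'   `avg_delta_carbons`, `n_decreasing`, `per`, plus `site_deltas` and
#'   `skipped_sites` (sites where a partition was all-gap).
#' @export
site_contribution <- function(alignment, ps_sites, focal_taxa, other_taxa,
                              table, gene_id = NA_character_,
                              per = c("alignment", "site")) {
  per <- match.arg(per)
  m <- aln_matrix(alignment)
  stopifnot(all(focal_taxa %in% rownames(m)), all(other_taxa %in% rownames(m)),
            length(focal_taxa) > 0L, length(other_taxa) > 0L)
  cols <- ps_sites$alignment_column
  mean_carbons <- function(chars) {
    chars <- chars[chars %in% AA_ALPHABET]
    if (length(chars) == 0L) return(NA_real_)
    mean(table$carbons[chars])
  }
  site_deltas <- vapply(cols, function(j) {
    mean_carbons(m[focal_taxa, j]) - mean_carbons(m[other_taxa, j])
  }, numeric(1))
  skipped <- cols[is.na(site_deltas)]
  ok <- !is.na(site_deltas)
  denom <- if (per == "alignment") ncol(m) else sum(ok)
  structure(list(gene_id = gene_id,
                 n_ps_sites = sum(ok),
                 avg_delta_carbons = sum(site_deltas[ok]) / denom,
                 n_decreasing = sum(site_deltas[ok] < 0),
                 per = per,
                 site_deltas = stats::setNames(site_deltas[ok], cols[ok]),
                 skipped_sites = skipped),
            class = "site_contribution")
}

#' @export
print.site_contribution <- function(x, ...) {
  cat(sprintf("<site_contribution> %s: %d PS sites, avg delta %+0.3f carbons (per %s), %d decreasing\n",
              ifelse(is.na(x$gene_id), "(unnamed)", x$gene_id), x$n_ps_sites,
              x$avg_delta_carbons, x$per, x$n_decreasing))
  invisible(x)
}

#' Read a BEB site table
#' @param file TSV with columns `site` and `probability` (codeml rst-style
#'   numbering).
#' @return data.frame.
#' @export
read_beb_table <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("site", "probability") %in% names(d)))
    stop("BEB table must have columns 'site' and 'probability'")
  d
}

# ---- group comparisons -------------------------------------------------------

#' Compare groups of values with standard tests
#'
#' Thin wrappers around the tests used for group comparisons of GC content
#' and cost statistics: Kruskal-Wallis across all groups, Dunn's post hoc
#' pairwise z-tests on ranks, Mann-Whitney (Wilcoxon rank-sum) and Student's
#' t for two groups -- with Bonferroni correction of pairwise p-values.
#' Groups with fewer than 2 values are excluded with a warning.
#'
#' @param values Numeric vector.
#' @param group Group labels (coerced to factor), same length as `values`.
#' @param test One of "kruskal_wallis", "dunn", "mann_whitney", "t_test".
#' @param correction "bonferroni" (default) or "none"; applied to pairwise
#'   tests.
#' @return For "kruskal_wallis": the `htest` object. For the pairwise tests:
#'   a data.frame with one row per group pair (`group1`, `group2`, statistic,
#'   `p_value`, `p_adjusted`).
#' @export
compare_groups <- function(values, group,
                           test = c("kruskal_wallis", "dunn", "mann_whitney", "t_test"),
                           correction = c("bonferroni", "none")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  group <- factor(group)
  small <- names(which(table(group) < 2L))
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 values: ",
            paste(small, collapse = ", "))
    keep <- !group %in% small
    values <- values[keep]
    group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (test == "kruskal_wallis")
    return(stats::kruskal.test(values, group))
  if (test == "dunn")
    return(dunn_test(values, group, correction))
  pairs <- utils::combn(levels(group), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- values[group == pr[1]]
    y <- values[group == pr[2]]
    h <- if (test == "mann_whitney") {
      suppressWarnings(stats::wilcox.test(x, y))
    } else {
      stats::t.test(x, y)
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               statistic = unname(h$statistic), p_value = h$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value,
                                    method = if (correction == "bonferroni") "bonferroni" else "none")
  out
}

# Dunn's post hoc test: pairwise z statistics on the joint ranks with the
# tie-corrected variance; p-values are two-sided and Bonferroni-adjustable
dunn_test <- function(values, group, correction = "bonferroni") {
  group <- factor(group)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, group, mean)
  n <- tapply(r, group, length)
  pairs <- utils::combn(levels(group), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    z <- unname((rbar[pr[1]] - rbar[pr[2]]) / se)
    data.frame(group1 = pr[1], group2 = pr[2], statistic = z,
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value,
                                    method = if (correction == "bonferroni") "bonferroni" else "none")
  out
}

#' Write bootstrap results to a TSV
#' @param results List of `bootstrap_result` objects.
#' @param file Output path; columns gene, virus, delta, p_value, length_nt.
#' @return `file`, invisibly.
#' @export
write_bootstrap_table <- function(results, file) {
  out <- do.call(rbind, lapply(results, function(x) {
    data.frame(gene = x$gene_id, virus = x$virus_id,
               delta_carbons_per_site = x$delta_carbons_per_site,
               p_value = x$p_value, alignment_length_nt = x$alignment_length_nt,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
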