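# Dataset dereplication and filtering: ANI-based OTU clustering,
# representative-region selection, minimum-gene filters, and tree-based
# retention of viral homologs.

#' Build an ANI matrix object
#'
#' @param values Square numeric matrix of average nucleotide identity
#'   percentages (0-100) with genome ids as dimnames. Symmetrized on load
#'   (mean of the two triangles); diagonal forced to 100. Missing values are
#'   treated as ANI 0 with a warning.
#' @return Object of class `ani_matrix`.
#' @export
ani_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)))
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  stopifnot(identical(rownames(values), colnames(values)))
  if (anyNA(values)) {
    warning("missing ANI pairs treated as ANI 0")
    values[is.na(values)] <- 0
  }
  if (any(values < 0 | values > 100)) stop("ANI values must be percentages in [0, 100]")
  values <- (values + t(values)) / 2
  diag(values) <- 100
  structure(list(taxa = rownames(values), values = values), class = "ani_matrix")
}

#' Read an ANI matrix from TSV
#'
#' Accepts either a square matrix with row and column names, or a long
#' three-column table (`query`, `reference`, `ani`).
#'
#' @param file Path to the TSV.
#' @return An [ani_matrix()].
#' @export
read_ani_matrix <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) == 3L && !is.numeric(d[[2]])) {
    taxa <- sort(unique(c(d[[1]], d[[2]])))
    m <- matrix(NA_real_, length(taxa), length(taxa), dimnames = list(taxa, taxa))
    m[cbind(match(d[[1]], taxa), match(d[[2]], taxa))] <- d[[3]]
    m[cbind(match(d[[2]], taxa), match(d[[1]], taxa))] <- d[[3]]
    diag(m) <- 100
    suppressWarnings(ani_matrix(m))
  } else {
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    ani_matrix(m)
  }
}

#' Cluster genomes into OTUs by complete-linkage ANI clustering
#'
#' Agglomerates genomes on the distance 100 - ANI with furthest-neighbor
#' (complete) linkage and cuts the dendrogram so that two genomes share an
#' OTU iff the maximum pairwise distance within their cluster is at most
#' 100 - cutoff (i.e. every within-OTU pair has ANI >= cutoff; pairs at
#' exactly the cutoff are merged).
#'
#' @param ani An [ani_matrix()].
#' @param cutoff ANI percentage threshold (default 95).
#' @return Object of class `otu_assignment`: list with `otu` (named integer
#'   vector, genome id -> OTU id), `linkage`, `cutoff`.
#' @export
cluster_otus <- function(ani, cutoff = 95) {
  stopifnot(inherits(ani, "ani_matrix"), cutoff >= 0, cutoff <= 100)
  n <- length(ani$taxa)
  if (n == 1L) {
    otu <- stats::setNames(1L, ani$taxa)
  } else {
    d <- stats::as.dist(100 - ani$values)
    hc <- stats::hclust(d, method = "complete")
    otu <- stats::cutree(hc, h = 100 - cutoff)
  }
  structure(list(otu = otu, linkage = "furthest-neighbor", cutoff = cutoff),
            class = "otu_assignment")
}

#' Pick one representative region per OTU
#'
#' Within each OTU, keeps the region with the largest number of labeled
#' genes; ties are broken by lexicographic region id.
#'
#' @param regions List of [gene_region()] objects.
#' @param genome_ids Character vector: the genome carrying each region.
#' @param otus An [cluster_otus()] result covering those genomes.
#' @return The subset of `regions` (one per OTU that has at least one
#'   region), named by OTU id.
#' @export
select_representative <- function(regions, genome_ids, otus) {
  stopifnot(length(regions) == length(genome_ids))
  ids <- otus$otu[genome_ids]
  if (anyNA(ids)) stop("some genomes are not in the OTU assignment")
  counts <- vapply(regions, function(r) length(r$gene_labels), integer(1))
  rids <- vapply(regions, function(r) as.character(r$region_id), character(1))
  picked <- lapply(split(seq_along(regions), ids), function(i) {
    i <- i[order(-counts[i], rids[i])]
    i[1]
  })
  out <- regions[unlist(picked)]
  names(out) <- names(picked)
  out
}

#' Drop regions with too few labeled genes
#'
#' @param regions List of [gene_region()] objects.
#' @param min_genes Minimum number of labeled genes to keep a region
#'   (default 9; the boundary is inclusive).
#' @return The filtered list.
#' @export
filter_min_genes <- function(regions, min_genes = 9L) {
  keep <- vapply(regions, function(r) length(r$gene_labels) >= min_genes, logical(1))
  regions[keep]
}

#' Retain viral homologs nested within a bacterial order
#'
#' A viral leaf is retained iff the smallest clade that contains it together
#' with at least one bacterial leaf (i) has all its bacterial members in a
#' single taxonomic order and (ii) has bootstrap support at least
#' `support_min`. On unrooted trees the test is run under every rooting
#' consistent with the bacterial order partition (each order monophyletic
#' among bacterial leaves, ignoring viral leaves), and a leaf is retained
#' only if it is retained under all such rootings; if no rooting satisfies
#' the partition, all rootings are considered (conservative).
#'
#' @param tree An `ape::phylo` tree. Internal `node.label`s, if present, are
#'   read as bootstrap support values (0-100; blank = unknown, treated as
#'   failing the threshold).
#' @param viral_leaves Character vector of viral tip labels.
#' @param leaf_order Named character vector mapping every bacterial tip label
#'   to its taxonomic order.
#' @param support_min Minimum support (default 60).
#' @return Character vector of retained viral tip labels.
#' @export
retain_nested_homologs <- function(tree, viral_leaves, leaf_order,
                                   support_min = 60) {
  stopifnot(inherits(tree, "phylo"))
  bact <- setdiff(tree$tip.label, viral_leaves)
  if (!all(bact %in% names(leaf_order)))
    stop("leaf_order must cover all bacterial leaves")
  if (ape::is.rooted(tree)) {
    return(retained_in_rooting(tree, viral_leaves, leaf_order, support_min))
  }
  # enumerate rootings: root on each internal edge and each tip edge
  rootings <- list()
  for (node in setdiff(unique(tree$edge[, 2]), seq_along(tree$tip.label))) {
    r <- tryCatch(ape::root(tree, node = node, resolve.root = TRUE),
                  error = function(e) NULL)
    if (!is.null(r)) rootings[[length(rootings) + 1L]] <- r
  }
  for (tip in tree$tip.label) {
    r <- tryCatch(ape::root(tree, outgroup = tip, resolve.root = TRUE),
                  error = function(e) NULL)
    if (!is.null(r)) rootings[[length(rootings) + 1L]] <- r
  }
  admissible <- Filter(function(r) orders_monophyletic(r, bact, leaf_order), rootings)
  if (length(admissible) == 0L) admissible <- rootings
  retained <- lapply(admissible, retained_in_rooting,
                     viral_leaves = viral_leaves, leaf_order = leaf_order,
                     support_min = support_min)
  Reduce(intersect, retained)
}

# clade-scan on a rooted tree
retained_in_rooting <- function(tree, viral_leaves, leaf_order, support_min) {
  ntip <- length(tree$tip.label)
  supports <- node_supports(tree)
  keep <- character(0)
  for (v in intersect(viral_leaves, tree$tip.label)) {
    node <- match(v, tree$tip.label)
    repeat {
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      if (length(parent) == 0L) break  # reached the root without bacteria
      tips <- tree$tip.label[clade_tips(tree, parent)]
      bact <- setdiff(tips, viral_leaves)
      if (length(bact) > 0L) {
        ords <- unique(leaf_order[bact])
        sup <- supports[parent - ntip]
        if (length(ords) == 1L && !is.na(sup) && sup >= support_min)
          keep <- c(keep, v)
        break
      }
      node <- parent
    }
  }
  keep
}

# tip indices descending from an internal node
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- c(tips, ch[ch <= ntip])
    todo <- c(todo, ch[ch > ntip])
  }
  tips
}

# numeric support per internal node; the root (no incoming edge) gets 100
# because it is not a hypothesis about the data
node_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(100, nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  if (!(root %in% tree$edge[, 2])) sup[1] <- 100
  sup
}

# are all orders monophyletic among bacterial leaves (viral leaves ignored)?
orders_monophyletic <- function(tree, bact, leaf_order) {
  for (ord in unique(leaf_order[bact])) {
    members <- bact[leaf_order[bact] == ord]
    if (length(members) < 2L) next
    mrca <- ape::getMRCA(tree, members)
    tips <- tree$tip.label[clade_tips(tree, mrca)]
    if (length(setdiff(intersect(tips, bact), members)) > 0L)
      return(FALSE)
  }
  TRUE
}

#' Keep the k viral homologs closest to the bacterial clade
#'
#' Ranks viral leaves by their minimum patristic distance to any bacterial
#' leaf, after collapsing sequence-identical viral homologs (identity is
#' compared on the ungapped amino-acid sequence), and returns at most `k`.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param viral_leaves Character vector of viral tip labels.
#' @param k Number to keep (default 5).
#' @param sequences Optional named character vector of (possibly gapped)
#'   sequences used to drop identical duplicates; if omitted, no
#'   deduplication is done.
#' @return Character vector of retained viral tip labels, closest first.
#' @export
top_k_closest_homologs <- function(tree, viral_leaves, k = 5L, sequences = NULL) {
  stopifnot(inherits(tree, "phylo"))
  viral_leaves <- intersect(viral_leaves, tree$tip.label)
  if (!is.null(sequences)) {
    seqs <- gsub("-", "", toupper(sequences[viral_leaves]), fixed = TRUE)
    viral_leaves <- viral_leaves[!duplicated(seqs)]
  }
  bact <- setdiff(tree$tip.label, viral_leaves)
  if (length(bact) == 0L) stop("no bacterial leaves in tree")
  dm <- ape::cophenetic.phylo(tree)
  dmin <- apply(dm[viral_leaves, bact, drop = FALSE], 1, min)
  head(viral_leaves[order(dmin, viral_leaves)], k)
}
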