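# Marginal maximum-likelihood ancestral states of a continuous trait under
# Brownian motion, via a two-pass (tip-to-root, root-to-tip) message-passing
# scheme: linear in the number of tips, and equal to the generalized
# least-squares estimates under the phylogenetic covariance.

#' Brownian-motion ancestral state reconstruction
#'
#' Estimates the trait value at every internal node of a rooted tree by
#' marginal maximum likelihood under Brownian motion. The estimate at a node
#' is the precision-weighted combination of the information arriving from all
#' adjacent subtrees (equivalently, the GLS ancestral estimate obtained by
#' rerooting at that node). Also returns the ML rate estimate.
#'
#' @param tree An `ape::phylo` tree (treated as rooted at its basal node)
#'   with branch lengths in any unit.
#'   Zero-length branches are floored at 1e-8 with a warning; negative branch
#'   lengths are an error.
#' @param tip_values Named numeric vector of trait values covering every tip.
#' @return Object of class `trait_reconstruction`: list with `tree`,
#'   `tip_values`, `node_values` (named by node number as in `tree$edge`),
#'   `sigma2` (ML Brownian rate), and `logLik`.
#' @export
bm_ancestral_states <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"))
  # a basal polytomy (ape's "unrooted") is fine: the basal node is treated as
  # the root, and under Brownian motion the marginal ML estimates at every
  # node are invariant to root placement
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 tips")
  if (!all(tree$tip.label %in% names(tip_values)))
    stop("tip_values must cover every tip")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  el <- tree$edge.length
  if (any(el == 0)) {
    warning("zero-length branch(es) floored at 1e-8")
    el[el == 0] <- 1e-8
  }
  nnode <- tree$Nnode
  nmax <- ntip + nnode
  x <- tip_values[tree$tip.label]

  # down[u] = (mean, var) of the trait at u given the data in u's subtree
  dmean <- dvar <- rep(NA_real_, nmax)
  dmean[seq_len(ntip)] <- x
  dvar[seq_len(ntip)] <- 0
  # messages through the incoming edge: var + edge length
  edge_of <- integer(nmax)          # row in edge matrix whose child is u
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  children <- split(tree$edge[, 2], tree$edge[, 1])

  ss <- 0                           # accumulates squared standardized contrasts
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (u in po) {
    ch <- children[[as.character(u)]]
    m <- dmean[ch[1]]; v <- dvar[ch[1]] + el[edge_of[ch[1]]]
    if (length(ch) > 1L) for (j in 2L:length(ch)) {
      m2 <- dmean[ch[j]]; v2 <- dvar[ch[j]] + el[edge_of[ch[j]]]
      ss <- ss + (m - m2)^2 / (v + v2)
      w1 <- 1 / v; w2 <- 1 / v2
      m <- (m * w1 + m2 * w2) / (w1 + w2)
      v <- 1 / (w1 + w2)
    }
    dmean[u] <- m; dvar[u] <- v
  }
  sigma2 <- ss / ntip

  # up[u] = (mean, var) at u given everything outside u's subtree
  root <- ntip + 1L
  umean <- uvar <- rep(NA_real_, nmax)
  node_values <- rep(NA_real_, nnode)
  names(node_values) <- as.character(root:nmax)
  node_values[as.character(root)] <- dmean[root]
  pre <- rev(po)
  for (u in pre) {
    ch <- children[[as.character(u)]]
    for (cc in ch) {
      # combine u's above-distribution with down-messages of cc's siblings
      parts_m <- numeric(0); parts_v <- numeric(0)
      if (u != root) { parts_m <- umean[u]; parts_v <- uvar[u] }
      for (sib in setdiff(ch, cc)) {
        parts_m <- c(parts_m, dmean[sib])
        parts_v <- c(parts_v, dvar[sib] + el[edge_of[sib]])
      }
      w <- 1 / parts_v
      m_star <- sum(parts_m * w) / sum(w)
      v_star <- 1 / sum(w)
      umean[cc] <- m_star
      uvar[cc] <- v_star + el[edge_of[cc]]
      if (cc > ntip) {
        w_d <- 1 / dvar[cc]; w_u <- 1 / uvar[cc]
        node_values[as.character(cc)] <-
          (dmean[cc] * w_d + umean[cc] * w_u) / (w_d + w_u)
      }
    }
  }
  # BM log-likelihood at the ML root state and sigma2 (Gaussian, n tips)
  ll <- if (sigma2 > 0) {
    # product over contrasts plus root term; recompute determinant part from
    # the downpass variances: each combination contributed var (v1+v2)
    -0.5 * (ntip * log(2 * pi * sigma2) + ll_logdet(tree, el) + ntip)
  } else Inf
  structure(list(tree = tree, tip_values = x, node_values = node_values,
                 sigma2 = sigma2, logLik = ll),
            class = "trait_reconstruction")
}

# log-determinant of the BM covariance (unit rate) via the same pruning
ll_logdet <- function(tree, el) {
  ntip <- length(tree$tip.label)
  nmax <- ntip + tree$Nnode
  dvar <- rep(NA_real_, nmax)
  dvar[seq_len(ntip)] <- 0
  edge_of <- integer(nmax)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  logdet <- 0
  for (u in po) {
    ch <- children[[as.character(u)]]
    v <- dvar[ch[1]] + el[edge_of[ch[1]]]
    if (length(ch) > 1L) for (j in 2L:length(ch)) {
      v2 <- dvar[ch[j]] + el[edge_of[ch[j]]]
      logdet <- logdet + log(v + v2)
      v <- 1 / (1 / v + 1 / v2)
    }
    dvar[u] <- v
  }
  # root factor: N(root mean; a, sigma2 * v_root), evaluated at the ML root
  logdet + log(dvar[ntip + 1L])
}

#' Per-branch change of a reconstructed trait
#'
#' For every branch, the child value minus the parent value (reconstructed
#' values at internal nodes, observed values at tips). Negative values mean
#' the trait decreased toward the child.
#'
#' @param recon A [bm_ancestral_states()] result.
#' @return data.frame with `parent`, `child` (node numbers), `child_label`
#'   (tip label or node number), and `delta`.
#' @export
branch_changes <- function(recon) {
  stopifnot(inherits(recon, "trait_reconstruction"))
  tree <- recon$tree
  ntip <- length(tree$tip.label)
  val <- function(node) {
    if (node <= ntip) unname(recon$tip_values[node])
    else unname(recon$node_values[as.character(node)])
  }
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  delta <- vapply(seq_len(nrow(tree$edge)),
                  function(i) val(child[i]) - val(parent[i]), numeric(1))
  data.frame(parent = parent, child = child,
             child_label = ifelse(child <= ntip, tree$tip.label[child],
                                  as.character(child)),
             delta = delta, stringsAsFactors = FALSE)
}

#' Carbon score of a reconstructed ancestral sequence
#'
#' Scores the ancestral sequence at one node of an
#' [ancestral_sequences][marginal_asr()] object with [score_protein()].
#'
#' @param seqs An `ancestral_sequences` object (see [marginal_asr()]).
#' @param node Node identifier (as named in `seqs$node_sequences`).
#' @param table A [build_cost_table()] table.
#' @return A `cost_score`.
#' @export
ancestral_carbon_of_node <- function(seqs, node, table) {
  node <- as.character(node)
  if (!node %in% names(seqs$node_sequences)) stop("node not reconstructed: ", node)
  score_protein(gsub("-", "", seqs$node_sequences[[node]], fixed = TRUE),
                table, protein_id = node)
}

#' Write node values and branch deltas to TSV
#' @param recon A [bm_ancestral_states()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trait_reconstruction <- function(recon, file) {
  bc <- branch_changes(recon)
  nv <- data.frame(node = names(recon$node_values),
                   value = unname(recon$node_values))
  utils::write.table(bc, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nv, paste0(file, ".nodes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
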