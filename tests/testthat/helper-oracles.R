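# Independent oracles used across the test suite. These deliberately take
# different computational routes from the package implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AA20, n, replace = TRUE, prob = freqs), collapse = "")
}

random_cds <- function(n_codons) {
  b <- c("A", "C", "G", "T")
  sense <- setdiff(apply(expand.grid(b, b, b)[, 3:1], 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# position-by-position GC tally, character arithmetic only
brute_gc <- function(seqs) {
  gc <- tot <- numeric(3)
  ncod <- 0
  for (s in seqs) {
    s <- toupper(s)
    if (nchar(s) >= 3 && substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
      s <- substr(s, 1, nchar(s) - 3)
    if (nchar(s) == 0) next
    ch <- strsplit(s, "")[[1]]
    ncod <- ncod + length(ch) / 3
    for (i in seq_along(ch)) {
      k <- ((i - 1) %% 3) + 1
      if (ch[i] %in% c("A", "C", "G", "T")) {
        tot[k] <- tot[k] + 1
        if (ch[i] %in% c("G", "C")) gc[k] <- gc[k] + 1
      }
    }
  }
  list(gc1 = gc[1] / tot[1], gc2 = gc[2] / tot[2], gc3 = gc[3] / tot[3],
       n_codons = ncod)
}

# marginal ML (= GLS) ancestral estimate at a node, by explicitly rerooting
# and solving the dense GLS problem
gls_ancestral <- function(tree, x, node) {
  ntip <- length(tree$tip.label)
  rt <- if (node == ntip + 1L) tree else
    ape::root(tree, node = node, resolve.root = TRUE)
  C <- ape::vcv(rt)
  xx <- x[rownames(C)]
  one <- rep(1, nrow(C))
  Ci <- solve(C)
  as.numeric((one %*% Ci %*% xx) / (one %*% Ci %*% one))
}

# transition matrix by truncated Taylor series (independent of the package's
# eigendecomposition route)
series_pmatrix <- function(Q, t, terms = 60) {
  P <- diag(20)
  term <- diag(20)
  for (k in 1:terms) {
    term <- term %*% (Q * t) / k
    P <- P + term
  }
  P
}

# exhaustive marginal ASR: enumerate all internal-node state assignments
# (only feasible for tiny trees), averaging over gamma categories
brute_marginal_asr <- function(aln, tree, model) {
  m <- do.call(rbind, strsplit(toupper(aln[tree$tip.label]), ""))
  rownames(m) <- tree$tip.label
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_rate_categories)
  pi <- model$stationary_freqs
  Q <- model$Q
  nsite <- ncol(m)
  internal <- root:(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  post <- array(0, dim = c(nnode, 20, nsite))
  sitelik <- numeric(nsite)
  for (r in rates) {
    P <- lapply(seq_len(nrow(tree$edge)),
                function(e) series_pmatrix(Q, tree$edge.length[e] * r))
    for (site in seq_len(nsite)) {
      obs <- match(m[, site], AA20)
      for (g in seq_len(nrow(grid))) {
        state_of <- function(nd) if (nd <= ntip) obs[nd] else grid[g, nd - ntip]
        pr <- pi[grid[g, 1]]
        ok <- TRUE
        for (e in seq_len(nrow(tree$edge))) {
          pa <- state_of(tree$edge[e, 1]); ch <- state_of(tree$edge[e, 2])
          if (is.na(ch)) next  # gap/unknown tip: sum over its states = 1
          pr <- pr * P[[e]][pa, ch]
          if (pr == 0) { ok <- FALSE; break }
        }
        if (!ok) next
        w <- pr / length(rates)
        sitelik[site] <- sitelik[site] + w
        for (nd in seq_len(nnode)) post[nd, grid[g, nd], site] <-
            post[nd, grid[g, nd], site] + w
      }
    }
  }
  for (site in seq_len(nsite)) post[, , site] <- post[, , site] / sitelik[site]
  list(posterior = post, loglik = sum(log(sitelik)),
       node_ids = as.character(internal))
}

# exhaustive two-state (absent/present) marginal reconstruction
brute_indel_posterior <- function(pres, tree, rate) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  grid <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  Pm <- function(t) {
    p <- 0.5 + 0.5 * exp(-2 * rate * t)
    matrix(c(p, 1 - p, 1 - p, p), 2, 2)
  }
  P <- lapply(seq_len(nrow(tree$edge)), function(e) Pm(tree$edge.length[e]))
  num <- matrix(0, nnode, 1)
  present_mass <- numeric(nnode)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    state_of <- function(nd) if (nd <= ntip) as.integer(pres[nd]) else grid[g, nd - ntip]
    pr <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      pa <- state_of(tree$edge[e, 1]); ch <- state_of(tree$edge[e, 2])
      pr <- pr * P[[e]][pa + 1, ch + 1]
    }
    total <- total + pr
    present_mass <- present_mass + pr * grid[g, ]
  }
  present_mass / total
}

# greedy complete-linkage agglomeration from scratch
brute_complete_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL; bestd <- Inf
    if (length(clusters) == 1L) break
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}

# are two cluster labelings the same partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# exact P(mean of L iid draws from `deltas` <= 0) by integer convolution
exact_bootstrap_p <- function(deltas) {
  stopifnot(all(deltas == round(deltas)))
  L <- length(deltas)
  offset <- 9L
  base <- numeric(2 * offset + 1)
  for (d in deltas) base[d + offset + 1] <- base[d + offset + 1] + 1 / L
  # support of base: sums from -9..9; L-fold convolution
  dist <- c(1)       # P(sum = 0) = 1, support starts at 0
  start <- 0L        # value of first cell
  for (i in seq_len(L)) {
    new <- numeric(length(dist) + length(base) - 1L)
    for (k in seq_along(base)) {
      if (base[k] == 0) next
      idx <- seq_along(dist) + (k - 1L)
      new[idx] <- new[idx] + dist * base[k]
    }
    dist <- new
    start <- start - offset
  }
  values <- start + seq_along(dist) - 1L
  sum(dist[values <= 0])
}

# BM simulation along a tree with an optional jump on the edge into one node
simulate_bm <- function(tree, sigma = 1, root_state = 0, jump_node = NULL,
                        jump = 0) {
  ntip <- length(tree$tip.label)
  nmax <- ntip + tree$Nnode
  x <- rep(NA_real_, nmax)
  x[ntip + 1L] <- root_state
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  el <- tree$edge.length[match(paste(pre[, 1], pre[, 2]), key)]
  for (e in seq_len(nrow(pre))) {
    pa <- pre[e, 1]; ch <- pre[e, 2]
    x[ch] <- x[pa] + stats::rnorm(1, 0, sigma * sqrt(el[e])) +
      if (!is.null(jump_node) && ch == jump_node) jump else 0
  }
  list(tips = stats::setNames(x[seq_len(ntip)], tree$tip.label),
       nodes = x[(ntip + 1L):nmax])
}
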