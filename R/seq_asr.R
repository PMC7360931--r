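# Marginal ancestral amino-acid sequence reconstruction under an empirical
# exchangeability model (LG by default) with discrete-Gamma rate
# heterogeneity, plus ML inference of ancestral indel (presence/absence)
# states. Residues and indels are reconstructed in two decoupled stages:
# gap/residue patterns first, then marginal residue posteriors at the
# ancestrally present positions.

# PAML residue order used by .dat matrix files
AA_PAML <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load an empirical amino-acid model from a PAML .dat file
#'
#' Parses the lower-triangular exchangeability matrix (190 values, PAML
#' residue order) followed by the 20 stationary frequencies, as in the files
#' distributed with PAML (LG, WAG, ...). Frequencies are renormalized to sum
#' to 1 and the matrix is reordered to the package's alphabetical residue
#' order.
#'
#' @param file Path to the `.dat` file. Defaults to the packaged LG matrix.
#' @param gamma_shape Gamma shape for among-site rate heterogeneity (may be
#'   re-estimated later); `Inf` means a single rate.
#' @param n_rate_categories Number of discrete Gamma categories (default 4).
#' @return A `substitution_model` (see [substitution_model()]).
#' @export
load_paml_matrix <- function(file = system.file("extdata", "lg.dat", package = "gtacarbon"),
                             gamma_shape = 1, n_rate_categories = 4L) {
  lines <- readLines(file)
  toks <- unlist(strsplit(trimws(lines), "\\s+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("malformed PAML matrix: non-numeric token #", bad, " ('", toks[bad], "')")
  }
  if (length(vals) < 210)
    stop("malformed PAML matrix: expected 190 exchangeabilities + 20 frequencies, got ",
         length(vals), " numbers")
  ex <- vals[1:190]
  freqs <- vals[191:210]
  S <- matrix(0, 20, 20, dimnames = list(AA_PAML, AA_PAML))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) { S[i, j] <- S[j, i] <- ex[k]; k <- k + 1L }
  names(freqs) <- AA_PAML
  substitution_model(S[AA_ALPHABET, AA_ALPHABET], freqs[AA_ALPHABET],
                     gamma_shape = gamma_shape,
                     n_rate_categories = n_rate_categories)
}

#' Write a substitution model to a PAML-style .dat file
#' @param model A `substitution_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_paml_matrix <- function(model, file) {
  S <- model$exchangeabilities[AA_PAML, AA_PAML]
  lines <- character(0)
  for (i in 2:20)
    lines <- c(lines, paste(formatC(S[i, 1:(i - 1)], format = "f", digits = 6),
                            collapse = " "))
  lines <- c(lines, "", paste(formatC(model$stationary_freqs[AA_PAML],
                                      format = "f", digits = 6), collapse = " "))
  writeLines(lines, file)
  invisible(file)
}

#' Construct an amino-acid substitution model
#'
#' Builds the normalized rate matrix Q = S diag(pi) (rows summing to zero,
#' mean rate 1 at stationarity) from a symmetric exchangeability matrix and
#' stationary frequencies, with discrete-Gamma rate heterogeneity.
#'
#' @param exchangeabilities Symmetric 20x20 matrix with residue dimnames.
#' @param stationary_freqs Named 20-vector (renormalized to sum to 1).
#' @param gamma_shape Positive shape; `Inf` = single rate.
#' @param n_rate_categories Number of equal-probability categories.
#' @param category_means If `TRUE` (default) category rates are conditional
#'   means; otherwise category medians (rescaled to mean 1).
#' @return Object of class `substitution_model`.
#' @export
substitution_model <- function(exchangeabilities, stationary_freqs,
                               gamma_shape = 1, n_rate_categories = 4L,
                               category_means = TRUE) {
  stopifnot(is.matrix(exchangeabilities), all(dim(exchangeabilities) == 20))
  ord <- AA_ALPHABET
  S <- exchangeabilities[ord, ord]
  if (max(abs(S - t(S))) > 1e-8) stop("exchangeability matrix must be symmetric")
  pi <- stationary_freqs[ord]
  if (any(pi < 0)) stop("negative stationary frequency")
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # symmetric form for a single eigendecomposition reused for all branches
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(exchangeabilities = S, stationary_freqs = pi, Q = Q,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 category_means = category_means,
                 eig = list(values = e$values,
                            U1 = e$vectors / sp,          # diag(1/sqrt(pi)) U
                            U2 = t(e$vectors * sp))),     # U' diag(sqrt(pi))
            class = "substitution_model")
}

# transition probability matrix for evolutionary distance t (expected
# substitutions/site at rate 1)
model_pmatrix <- function(model, t) {
  P <- model$eig$U1 %*% (exp(model$eig$values * t) * model$eig$U2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-Gamma category rates
#'
#' Equal-probability discretization of a Gamma(shape, rate = shape)
#' distribution (mean 1). With `means = TRUE` the category rate is the
#' conditional mean within each probability quantile; otherwise the category
#' median, rescaled so the mean rate is 1.
#'
#' @param shape Positive Gamma shape; `Inf` returns a single rate of 1.
#' @param k Number of categories.
#' @param means Conditional means (default) or medians.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L, means = TRUE) {
  if (!is.finite(shape)) return(rep(1, k))
  stopifnot(shape > 0, k >= 1)
  if (k == 1L) return(1)
  if (means) {
    q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
    p <- stats::pgamma(q, shape = shape + 1, rate = shape)
    r <- k * diff(p)
  } else {
    r <- stats::qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
    r <- r / mean(r)
  }
  r
}

# ---- alignment handling ----------------------------------------------------

# coerce aligned sequences (named character vector of equal-length strings,
# or a character matrix) to a character matrix [sequences x columns]
aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    stopifnot(is.character(alignment), !is.null(names(alignment)))
    w <- unique(nchar(alignment))
    if (length(w) != 1L) stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
  }
  if (is.null(rownames(m))) stop("alignment must have sequence names")
  m
}

aln_strings <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Filter alignment columns by occupancy
#'
#' Keeps columns in which at least `min_occupancy` of the sequences have a
#' non-gap character (boundary inclusive). For codon (nucleotide)
#' alignments, set `codon = TRUE`: occupancy is evaluated per codon triplet
#' and triplets are removed whole.
#'
#' @param alignment Named character vector of aligned sequences, or a
#'   character matrix.
#' @param min_occupancy Fraction in \[0, 1\].
#' @param codon Treat the alignment as codon triplets.
#' @return List with `alignment` (same representation as the input) and
#'   `column_map`: for each retained column, its original 1-based index (for
#'   codon alignments, indices of retained nucleotide columns).
#' @export
filter_columns <- function(alignment, min_occupancy, codon = FALSE) {
  was_strings <- !is.matrix(alignment)
  m <- aln_matrix(alignment)
  gap <- m == "-" | m == "." | m == "?"
  if (codon) {
    if (ncol(m) %% 3L != 0L) stop("codon alignment length not divisible by 3")
    ncod <- ncol(m) %/% 3L
    occ <- vapply(seq_len(ncod), function(i) {
      cols <- (3L * i - 2L):(3L * i)
      mean(rowSums(!gap[, cols, drop = FALSE]) == 3L)
    }, numeric(1))
    keep_cod <- which(occ >= min_occupancy)
    keep <- as.vector(vapply(keep_cod, function(i) (3L * i - 2L):(3L * i), integer(3)))
  } else {
    occ <- colMeans(!gap)
    keep <- which(occ >= min_occupancy)
  }
  out <- m[, keep, drop = FALSE]
  list(alignment = if (was_strings) aln_strings(out) else out,
       column_map = as.integer(keep))
}

# tip likelihood matrix [20 x ncol] for one sequence row; ambiguity codes and
# gaps become uninformative (all ones)
tip_likelihoods <- function(chars) {
  L <- matrix(0, 20, length(chars), dimnames = list(AA_ALPHABET, NULL))
  known <- chars %in% AA_ALPHABET
  L[cbind(match(chars[known], AA_ALPHABET), which(known))] <- 1
  amb <- list(B = c("N", "D"), Z = c("Q", "E"), J = c("I", "L"))
  for (code in names(amb)) {
    i <- which(chars == code)
    if (length(i)) L[amb[[code]], i] <- 1
  }
  other <- which(!known & !chars %in% names(amb))
  if (length(other)) L[, other] <- 1
  L
}

# ---- marginal residue reconstruction ---------------------------------------

#' Marginal ancestral sequence reconstruction
#'
#' Reconstructs amino-acid states at every internal node of a rooted tree by
#' marginal maximum likelihood: per site, conditional likelihoods are
#' computed with the pruning algorithm across discrete-Gamma rate categories,
#' and each node's posterior over the 20 residues is obtained by combining
#' the information below and above the node, mixing categories by their
#' posterior weight. Indel states are reconstructed first (see
#' [infer_indel_states()]); positions inferred absent at a node are rendered
#' as gaps in its sequence. The ML residue is reported per site; ties break
#' alphabetically.
#'
#' @param alignment Named character vector of aligned amino-acid sequences
#'   (or character matrix); names must cover every tip of `tree`.
#' @param tree An `ape::phylo` tree (treated as rooted at its basal node)
#'   with branch lengths in expected
#'   substitutions/site.
#' @param model A [substitution_model()] (default: packaged LG).
#' @param estimate_shape Re-estimate the Gamma shape by ML on the fixed tree
#'   before reconstructing (default `TRUE` when the model has finite shape).
#' @param indel_cutoff Posterior presence threshold for ancestral indel
#'   states (default 0.5); `NA` skips indel inference (ancestors have
#'   residues at every column).
#' @return Object of class `ancestral_sequences`: list with
#'   `node_sequences` (named by node number), `node_posteriors` (list of
#'   20 x ncol matrices), `indel_posterior` (node x column presence
#'   probabilities, or NULL), `site_loglik`, `logLik`, `gamma_shape`,
#'   `skipped_columns` (all-gap columns, reported but reconstructed as gaps),
#'   and `tree`.
#' @export
marginal_asr <- function(alignment, tree, model = load_paml_matrix(),
                         estimate_shape = is.finite(model$gamma_shape),
                         indel_cutoff = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  # trees with a basal polytomy (star trees, "unrooted" in ape's sense) are
  # handled by treating the basal node as the root; under a reversible model
  # the likelihood and marginal posteriors do not depend on root placement
  m <- aln_matrix(alignment)
  missing_tips <- setdiff(tree$tip.label, rownames(m))
  if (length(missing_tips))
    stop("leaf without sequence: ", paste(missing_tips, collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  nsite <- ncol(m)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L

  gapm <- m == "-" | m == "." | m == "?"
  allgap <- which(colSums(!gapm) == 0L)

  if (estimate_shape && is.finite(model$gamma_shape)) {
    f <- function(lsh) -sum(asr_loglik(m, tree, model, exp(lsh)))
    opt <- stats::optimize(f, lower = log(0.05), upper = log(100))
    model$gamma_shape <- exp(opt$minimum)
  }

  rates <- discrete_gamma_rates(model$gamma_shape, model$n_rate_categories,
                                model$category_means)
  k <- length(rates)
  pi <- model$stationary_freqs
  edge <- tree$edge
  el <- tree$edge.length
  if (is.null(el)) stop("tree must have branch lengths")
  children <- split(edge[, 2], edge[, 1])
  edge_of <- integer(ntip + nnode)
  edge_of[edge[, 2]] <- seq_len(nrow(edge))
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])

  # per category: down-pass conditional likelihoods and up-pass partials
  sitell_c <- matrix(-Inf, k, nsite)
  down_all <- vector("list", k)
  for (c_i in seq_len(k)) {
    P <- lapply(seq_len(nrow(edge)), function(e) model_pmatrix(model, el[e] * rates[c_i]))
    L <- vector("list", ntip + nnode)
    sc <- matrix(0, ntip + nnode, nsite)   # cumulative log scaling per node
    for (i in seq_len(ntip)) L[[i]] <- tip_likelihoods(m[i, ])
    for (u in po) {
      ch <- children[[as.character(u)]]
      acc <- NULL
      s <- numeric(nsite)
      for (cc in ch) {
        contrib <- P[[edge_of[cc]]] %*% L[[cc]]
        acc <- if (is.null(acc)) contrib else acc * contrib
        s <- s + sc[cc, ]
      }
      cmax <- apply(acc, 2, max)
      cmax[cmax == 0] <- 1
      L[[u]] <- acc / rep(cmax, each = 20)
      sc[u, ] <- s + log(cmax)
    }
    sitell_c[c_i, ] <- log(colSums(pi * L[[root]])) + sc[root, ]

    # up pass
    U <- vector("list", ntip + nnode)
    us <- matrix(0, ntip + nnode, nsite)
    U[[root]] <- matrix(pi, 20, nsite)
    for (u in rev(po)) {
      ch <- children[[as.character(u)]]
      contribs <- lapply(ch, function(cc) P[[edge_of[cc]]] %*% L[[cc]])
      names(contribs) <- as.character(ch)
      for (ci in seq_along(ch)) {
        cc <- ch[ci]
        T <- U[[u]]
        ssc <- us[u, ]
        for (sib in ch[-ci]) {
          T <- T * contribs[[as.character(sib)]]
          ssc <- ssc + sc[sib, ]
        }
        Ucc <- crossprod(P[[edge_of[cc]]], T)   # t(P) %*% T
        cmax <- apply(Ucc, 2, max)
        cmax[cmax == 0] <- 1
        if (cc > ntip) {
          U[[cc]] <- Ucc / rep(cmax, each = 20)
          us[cc, ] <- ssc + log(cmax)
        }
      }
    }
    # per-category posteriors at internal nodes (scales cancel per column)
    down_all[[c_i]] <- lapply(root:(ntip + nnode), function(u) {
      num <- L[[u]] * U[[u]]
      tot <- colSums(num); tot[tot == 0] <- 1
      sweep_cols(num, tot)
    })
  }

  # category posterior weights per site (equal 1/k priors)
  mx <- apply(sitell_c, 2, max)
  w <- exp(sweep(sitell_c, 2, mx))
  w <- sweep(w, 2, colSums(w), "/")
  catw <- w
  site_loglik <- mx + log(colMeans(exp(sweep(sitell_c, 2, mx))))

  post <- lapply(seq_len(nnode), function(ui) {
    acc <- matrix(0, 20, nsite, dimnames = list(AA_ALPHABET, NULL))
    for (c_i in seq_len(k)) acc <- acc + rep(catw[c_i, ], each = 20) * down_all[[c_i]][[ui]]
    acc
  })
  names(post) <- as.character(root:(ntip + nnode))

  # indel reconstruction
  indel <- NULL
  present <- matrix(TRUE, nnode, nsite, dimnames = list(names(post), NULL))
  if (!is.na(indel_cutoff) && any(gapm)) {
    indel <- infer_indel_states(m, tree, cutoff = indel_cutoff)
    present <- indel$states
  }
  if (length(allgap)) present[, allgap] <- FALSE

  node_sequences <- vapply(names(post), function(u) {
    ml <- AA_ALPHABET[apply(post[[u]], 2, which.max)]
    ml[!present[u, ]] <- "-"
    paste(ml, collapse = "")
  }, character(1))

  structure(list(node_sequences = node_sequences,
                 node_posteriors = post,
                 indel_posterior = if (is.null(indel)) NULL else indel$posterior,
                 site_loglik = site_loglik,
                 logLik = sum(site_loglik),
                 gamma_shape = model$gamma_shape,
                 skipped_columns = allgap,
                 tree = tree),
            class = "ancestral_sequences")
}

sweep_cols <- function(M, tot) M / rep(tot, each = nrow(M))

# total per-site log-likelihood under the model at a given gamma shape
asr_loglik <- function(m, tree, model, shape) {
  rates <- discrete_gamma_rates(shape, model$n_rate_categories, model$category_means)
  k <- length(rates)
  pi <- model$stationary_freqs
  edge <- tree$edge; el <- tree$edge.length
  ntip <- length(tree$tip.label)
  children <- split(edge[, 2], edge[, 1])
  edge_of <- integer(ntip + tree$Nnode)
  edge_of[edge[, 2]] <- seq_len(nrow(edge))
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  root <- ntip + 1L
  nsite <- ncol(m)
  sitell <- matrix(NA_real_, k, nsite)
  tipL <- lapply(seq_len(ntip), function(i) tip_likelihoods(m[i, ]))
  for (c_i in seq_len(k)) {
    P <- lapply(seq_len(nrow(edge)), function(e) model_pmatrix(model, el[e] * rates[c_i]))
    L <- vector("list", ntip + tree$Nnode)
    L[seq_len(ntip)] <- tipL
    sc <- matrix(0, ntip + tree$Nnode, nsite)
    for (u in po) {
      ch <- children[[as.character(u)]]
      acc <- NULL; s <- numeric(nsite)
      for (cc in ch) {
        contrib <- P[[edge_of[cc]]] %*% L[[cc]]
        acc <- if (is.null(acc)) contrib else acc * contrib
        s <- s + sc[cc, ]
      }
      cmax <- apply(acc, 2, max); cmax[cmax == 0] <- 1
      L[[u]] <- acc / rep(cmax, each = 20)
      sc[u, ] <- s + log(cmax)
    }
    sitell[c_i, ] <- log(colSums(pi * L[[root]])) + sc[root, ]
  }
  mx <- apply(sitell, 2, max)
  mx + log(colMeans(exp(sweep(sitell, 2, mx))))
}

# ---- indel (presence/absence) reconstruction --------------------------------

#' ML ancestral indel states
#'
#' Treats each alignment column's gap/residue pattern as a binary
#' presence/absence character evolving under a two-state continuous-time
#' model with equal gain and loss rates (rate estimated by ML on the fixed
#' tree), computes each internal node's marginal posterior probability of
#' presence by the pruning algorithm, and calls a position present when that
#' posterior is at least `cutoff`.
#'
#' @param alignment Named character vector of aligned sequences or character
#'   matrix (only the gap pattern is used); names must cover the tree tips.
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param cutoff Presence-posterior threshold (default 0.5).
#' @return List with `posterior` (internal-node x column matrix of presence
#'   probabilities), `states` (logical matrix, `posterior >= cutoff`), and
#'   `rate` (ML gain/loss rate).
#' @export
infer_indel_states <- function(alignment, tree, cutoff = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  m <- aln_matrix(alignment)
  m <- m[tree$tip.label, , drop = FALSE]
  pres <- !(m == "-" | m == "." | m == "?")   # TRUE = residue present
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  nsite <- ncol(pres)
  edge <- tree$edge; el <- tree$edge.length
  children <- split(edge[, 2], edge[, 1])
  edge_of <- integer(ntip + nnode)
  edge_of[edge[, 2]] <- seq_len(nrow(edge))
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])

  # P(t) for the symmetric 2-state model, stationary (1/2, 1/2):
  # stay = 1/2 + exp(-2 r t)/2
  run <- function(r, want_posterior = FALSE) {
    Pstay <- 0.5 + 0.5 * exp(-2 * r * el)
    # L: list of 2 x nsite matrices, rows = (absent, present)
    L <- vector("list", ntip + nnode)
    for (i in seq_len(ntip)) {
      Li <- matrix(0, 2, nsite)
      Li[1, !pres[i, ]] <- 1
      Li[2, pres[i, ]] <- 1
      L[[i]] <- Li
    }
    sc <- matrix(0, ntip + nnode, nsite)
    for (u in po) {
      ch <- children[[as.character(u)]]
      acc <- NULL; s <- numeric(nsite)
      for (cc in ch) {
        p <- Pstay[edge_of[cc]]
        Pm <- matrix(c(p, 1 - p, 1 - p, p), 2, 2)
        contrib <- Pm %*% L[[cc]]
        acc <- if (is.null(acc)) contrib else acc * contrib
        s <- s + sc[cc, ]
      }
      cmax <- apply(acc, 2, max); cmax[cmax == 0] <- 1
      L[[u]] <- acc / rep(cmax, each = 2)
      sc[u, ] <- s + log(cmax)
    }
    ll <- sum(log(colSums(0.5 * L[[root]])) + sc[root, ])
    if (!want_posterior) return(ll)
    # up pass
    U <- vector("list", ntip + nnode)
    U[[root]] <- matrix(0.5, 2, nsite)
    posterior <- matrix(NA_real_, nnode, nsite,
                        dimnames = list(as.character(root:(ntip + nnode)), NULL))
    num <- L[[root]] * U[[root]]
    posterior[1, ] <- num[2, ] / colSums(num)
    for (u in rev(po)) {
      ch <- children[[as.character(u)]]
      contribs <- lapply(ch, function(cc) {
        p <- Pstay[edge_of[cc]]
        matrix(c(p, 1 - p, 1 - p, p), 2, 2) %*% L[[cc]]
      })
      for (ci in seq_along(ch)) {
        cc <- ch[ci]
        T <- U[[u]]
        for (sj in seq_along(ch)[-ci]) T <- T * contribs[[sj]]
        p <- Pstay[edge_of[cc]]
        Pm <- matrix(c(p, 1 - p, 1 - p, p), 2, 2)
        Ucc <- crossprod(Pm, T)
        cmax <- apply(Ucc, 2, max); cmax[cmax == 0] <- 1
        Ucc <- Ucc / rep(cmax, each = 2)
        if (cc > ntip) {
          U[[cc]] <- Ucc
          num <- L[[cc]] * Ucc
          posterior[as.character(cc), ] <- num[2, ] / colSums(num)
        }
      }
    }
    posterior
  }

  if (any(pres) && any(!pres)) {
    opt <- stats::optimize(function(lr) -run(exp(lr)), lower = log(1e-4), upper = log(50))
    rate <- exp(opt$minimum)
  } else {
    rate <- 1e-4   # no variation in the presence pattern; rate is irrelevant
  }
  posterior <- run(rate, want_posterior = TRUE)
  list(posterior = posterior, states = posterior >= cutoff, rate = rate)
}

# ---- FASTA I/O (via ape) ----------------------------------------------------

#' Read aligned (or unaligned) protein sequences from FASTA
#' @param file Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_aa <- function(file) {
  x <- ape::read.FASTA(file, type = "AA")
  toupper(vapply(as.character(x), paste, character(1), collapse = ""))
}

#' Read nucleotide sequences from FASTA
#' @param file Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_nt <- function(file) {
  x <- ape::read.FASTA(file, type = "DNA")
  toupper(vapply(as.character(x), paste, character(1), collapse = ""))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  stopifnot(!is.null(names(seqs)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(file)
}

#' Write ancestral-sequence posteriors to TSV
#' @param asr An `ancestral_sequences` object.
#' @param file Output path; columns node, site, residue, probability.
#' @param min_prob Rows with probability below this are omitted (default 0.01).
#' @return `file`, invisibly.
#' @export
write_asr_posteriors <- function(asr, file, min_prob = 0.01) {
  rows <- list()
  for (u in names(asr$node_posteriors)) {
    P <- asr$node_posteriors[[u]]
    idx <- which(P >= min_prob, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    rows[[u]] <- data.frame(node = u, site = idx[, 2],
                            residue = AA_ALPHABET[idx[, 1]],
                            probability = P[idx], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$node, out$site, out$residue), ]
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
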