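lg <- load_paml_matrix()

test_that("the PAML matrix reader parses LG and validates structure", {
  expect_equal(sum(lg$stationary_freqs), 1, tolerance = 1e-6)
  expect_true(isSymmetric(lg$exchangeabilities))
  expect_equal(sum(lg$exchangeabilities > 0), 380)  # 190 pairs, both triangles
  # rate matrix rows sum to zero, mean rate 1
  expect_true(all(abs(rowSums(lg$Q)) < 1e-12))
  expect_equal(-sum(lg$stationary_freqs * diag(lg$Q)), 1, tolerance = 1e-12)

  # Poisson-style file: equal exchangeabilities and frequencies
  f <- tempfile(fileext = ".dat")
  lines <- vapply(2:20, function(i) paste(rep("1.0", i - 1), collapse = " "),
                  character(1))
  writeLines(c(lines, "", paste(rep("0.05", 20), collapse = " ")), f)
  pois <- load_paml_matrix(f)
  off <- pois$Q[upper.tri(pois$Q)]
  expect_true(max(off) - min(off) < 1e-12)

  # malformed file reports a parse error
  bad <- tempfile(fileext = ".dat")
  writeLines(c("0.4 x 0.3"), bad)
  expect_error(load_paml_matrix(bad), "non-numeric")
  writeLines(c("0.4 0.3"), bad)
  expect_error(load_paml_matrix(bad), "expected 190")
})

test_that("PAML matrix serialization round-trips", {
  f <- tempfile(fileext = ".dat")
  write_paml_matrix(lg, f)
  back <- load_paml_matrix(f)
  expect_equal(back$exchangeabilities, lg$exchangeabilities, tolerance = 1e-5)
  expect_equal(back$stationary_freqs, lg$stationary_freqs, tolerance = 1e-5)
})

test_that("discrete Gamma rates have mean one and collapse as shape grows", {
  for (shape in c(0.3, 1, 5)) {
    r <- discrete_gamma_rates(shape, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(Inf, 4), rep(1, 4))
  r4 <- discrete_gamma_rates(1e4, 4)
  expect_true(max(abs(r4 - 1)) < 0.05)
  rmed <- discrete_gamma_rates(1, 4, means = FALSE)
  expect_equal(mean(rmed), 1, tolerance = 1e-9)
})

test_that("unanimous tips give a near-certain ancestral residue", {
  tr <- ape::read.tree(text = "(t1:0.3,t2:0.7,t3:0.2,t4:1.1);")
  aln <- setNames(rep("A", 4), paste0("t", 1:4))
  a <- marginal_asr(aln, tr, lg, estimate_shape = FALSE)
  expect_equal(a$node_sequences[["5"]], "A")
  expect_gt(a$node_posteriors[["5"]]["A", 1], 0.99)
})

test_that("two-tip posterior matches the closed form with a series-expm oracle", {
  tr <- ape::read.tree(text = "(t1:0.2,t2:0.35);")
  aln <- c(t1 = "A", t2 = "C")
  single <- substitution_model(lg$exchangeabilities, lg$stationary_freqs,
                               gamma_shape = Inf)
  a <- marginal_asr(aln, tr, single, estimate_shape = FALSE)
  P1 <- series_pmatrix(single$Q, 0.2)
  P2 <- series_pmatrix(single$Q, 0.35)
  pi <- single$stationary_freqs
  want <- pi * P1[, "A"] * P2[, "C"]
  want <- want / sum(want)
  expect_equal(unname(a$node_posteriors[["3"]][, 1]), unname(want),
               tolerance = 1e-7)
})

test_that("posteriors and likelihood match exhaustive enumeration on 4 tips", {
  set.seed(51)
  tr <- ape::read.tree(text = "((t1:0.15,t2:0.4):0.2,(t3:0.3,t4:0.1):0.25);")
  aln <- c(t1 = "AW", t2 = "AF", t3 = "GW", t4 = "AW")
  a <- marginal_asr(aln, tr, lg, estimate_shape = FALSE)
  oracle <- brute_marginal_asr(aln, tr, lg)
  expect_equal(a$logLik, oracle$loglik, tolerance = 1e-9)
  for (j in seq_along(oracle$node_ids)) {
    nd <- oracle$node_ids[j]
    for (site in 1:2) {
      expect_equal(unname(a$node_posteriors[[nd]][, site]),
                   unname(oracle$posterior[j, , site]), tolerance = 1e-8)
    }
  }
})

test_that("gapped tip states are handled as missing data in the likelihood", {
  tr <- ape::read.tree(text = "((t1:0.15,t2:0.4):0.2,(t3:0.3,t4:0.1):0.25);")
  aln <- c(t1 = "A-", t2 = "AW", t3 = "A-", t4 = "AW")
  a <- marginal_asr(aln, tr, lg, estimate_shape = FALSE, indel_cutoff = NA)
  oracle <- brute_marginal_asr(aln, tr, lg)
  expect_equal(a$logLik, oracle$loglik, tolerance = 1e-9)
})

test_that("marginal posteriors are invariant to child order", {
  set.seed(52)
  tr <- ape::read.tree(text = "((t1:0.1,t2:0.2):0.1,(t3:0.15,t4:0.05):0.3);")
  aln <- c(t1 = "AWK", t2 = "GWK", t3 = "AFK", t4 = "AWH")
  a1 <- marginal_asr(aln, tr, lg, estimate_shape = FALSE)
  tr2 <- ape::read.tree(text = "((t4:0.05,t3:0.15):0.3,(t2:0.2,t1:0.1):0.1);")
  a2 <- marginal_asr(aln, tr2, lg, estimate_shape = FALSE)
  expect_equal(a1$logLik, a2$logLik, tolerance = 1e-12)
  expect_equal(a1$node_posteriors[["5"]], a2$node_posteriors[["5"]],
               tolerance = 1e-12)
})

test_that("the 4-category model converges to single-rate at huge shape", {
  tr <- ape::read.tree(text = "((t1:0.15,t2:0.4):0.2,(t3:0.3,t4:0.1):0.25);")
  aln <- c(t1 = "AWKLM", t2 = "AFKLM", t3 = "GWRLM", t4 = "AWKIM")
  m_hi <- substitution_model(lg$exchangeabilities, lg$stationary_freqs,
                             gamma_shape = 1e4)
  m_one <- substitution_model(lg$exchangeabilities, lg$stationary_freqs,
                              gamma_shape = Inf)
  a_hi <- marginal_asr(aln, tr, m_hi, estimate_shape = FALSE)
  a_one <- marginal_asr(aln, tr, m_one, estimate_shape = FALSE)
  dmax <- max(vapply(names(a_hi$node_posteriors), function(nd)
    max(abs(a_hi$node_posteriors[[nd]] - a_one$node_posteriors[[nd]])), numeric(1)))
  expect_lt(dmax, 1e-3)
})

test_that("ML residues are mostly correct on simulated LG+Gamma data", {
  set.seed(53)
  cfg <- simulation_config(n_tips = 8, carbon_shift = 0, tree_height = 0.35,
                           focal_height = 0.2, stem_length = 0.2,
                           protein_length = 120)
  acc <- replicate(20, {
    seed <- sample.int(1e6, 1)
    fam <- evolve_family(cfg, seed = seed)
    a <- marginal_asr(fam$alignment, fam$tree, lg, estimate_shape = FALSE)
    truth <- fam$node_sequences
    got <- a$node_sequences[names(truth)]
    mean(unlist(strsplit(got, "")) == unlist(strsplit(truth, "")))
  })
  expect_gte(mean(acc), 0.9)
})

test_that("indel states: constant patterns propagate, mixed match enumeration", {
  tr <- ape::read.tree(text = "((t1:0.15,t2:0.4):0.2,(t3:0.3,t4:0.1):0.25);")
  aln_all <- c(t1 = "AA", t2 = "AA", t3 = "AA", t4 = "AA")
  r <- infer_indel_states(aln_all, tr)
  expect_true(all(r$states))
  aln_gap <- c(t1 = "A-", t2 = "A-", t3 = "A-", t4 = "A-")
  r2 <- infer_indel_states(aln_gap, tr)
  expect_true(all(r2$states[, 1]))
  expect_true(all(!r2$states[, 2]))

  # mixed pattern: marginal posteriors equal exhaustive two-state enumeration
  aln_mix <- c(t1 = "A", t2 = "-", t3 = "A", t4 = "-")
  r3 <- infer_indel_states(aln_mix, tr)
  pres <- c(TRUE, FALSE, TRUE, FALSE)
  want <- brute_indel_posterior(pres, tr, r3$rate)
  expect_equal(unname(r3$posterior[, 1]), unname(want), tolerance = 1e-8)
})

test_that("ancestral sequences show gaps where presence posterior is low", {
  tr <- ape::read.tree(text = "((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1);")
  aln <- c(t1 = "AW", t2 = "AW", t3 = "A-", t4 = "A-")
  a <- marginal_asr(aln, tr, lg, estimate_shape = FALSE)
  # the clade of t3/t4 should lack the second position
  expect_equal(substr(a$node_sequences[["7"]], 2, 2), "-")
  expect_equal(substr(a$node_sequences[["6"]], 2, 2), "W")
})

test_that("column filtering respects the occupancy boundary and maps columns", {
  set.seed(54)
  m <- matrix("A", 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  m[1:7, 1] <- "-"   # occupancy 0.3
  m[1:5, 2] <- "-"   # occupancy 0.5
  aln <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  out <- filter_columns(aln, 0.5)
  expect_equal(out$column_map, c(2L, 3L))
  expect_equal(unname(nchar(out$alignment[1])), 2L)

  # random alignment: retained count equals a direct tally
  m2 <- matrix(sample(c("A", "-"), 200, replace = TRUE), 10, 20)
  rownames(m2) <- paste0("s", 1:10)
  out2 <- filter_columns(m2, 0.6)
  expect_equal(length(out2$column_map), sum(colMeans(m2 != "-") >= 0.6))

  # codon mode removes whole triplets
  cm <- matrix("A", 4, 6, dimnames = list(paste0("s", 1:4), NULL))
  cm[1:3, 4:6] <- "-"
  out3 <- filter_columns(cm, 0.5, codon = TRUE)
  expect_equal(out3$column_map, 1:3)
})

test_that("all-gap columns are recorded and reconstructed as gaps", {
  tr <- ape::read.tree(text = "((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1);")
  aln <- c(t1 = "A-W", t2 = "A-W", t3 = "A-W", t4 = "A-W")
  a <- marginal_asr(aln, tr, lg, estimate_shape = FALSE)
  expect_equal(a$skipped_columns, 2L)
  expect_equal(substr(a$node_sequences[["5"]], 2, 2), "-")
})

test_that("gamma shape is recovered in the right region by ML", {
  set.seed(55)
  cfg <- simulation_config(n_tips = 12, carbon_shift = 0, protein_length = 250,
                           gamma_shape = 0.5)
  fam <- evolve_family(cfg, seed = 99)
  a <- marginal_asr(fam$alignment, fam$tree, load_paml_matrix(gamma_shape = 1),
                    estimate_shape = TRUE)
  expect_lt(a$gamma_shape, 2.5)  # far from the no-heterogeneity regime
})

test_that("FASTA and posterior exports round-trip", {
  seqs <- c(n1 = "AW-K", n2 = "GWPK")
  f <- tempfile(fileext = ".faa")
  write_fasta(seqs, f)
  back <- read_fasta_aa(f)
  expect_equal(back, seqs)

  tr <- ape::read.tree(text = "((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1);")
  aln <- c(t1 = "AW", t2 = "AW", t3 = "AF", t4 = "AF")
  a <- marginal_asr(aln, tr, lg, estimate_shape = FALSE)
  fp <- tempfile(fileext = ".tsv")
  write_asr_posteriors(a, fp)
  tabp <- read.delim(fp)
  expect_true(all(tabp$probability >= 0.01 & tabp$probability <= 1))
  expect_true(all(tabp$residue %in% AA20))
})
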