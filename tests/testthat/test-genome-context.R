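test_that("OTU clustering merges and separates blocks as expected", {
  m <- matrix(99, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 100
  otu <- cluster_otus(ani_matrix(m), cutoff = 95)
  expect_equal(length(unique(otu$otu)), 1L)

  # two separable blocks
  m2 <- matrix(80, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  m2[1:3, 1:3] <- 99; m2[4:6, 4:6] <- 99; diag(m2) <- 100
  otu2 <- cluster_otus(ani_matrix(m2), cutoff = 95)
  expect_equal(length(unique(otu2$otu)), 2L)
  expect_equal(otu2$otu[["a"]], otu2$otu[["b"]])
  expect_false(otu2$otu[["a"]] == otu2$otu[["d"]])
})

test_that("cutoff extremes give singletons and one cluster", {
  set.seed(21)
  n <- 8
  m <- matrix(runif(n * n, 80, 99), n, n, dimnames = list(letters[1:n], letters[1:n]))
  m <- (m + t(m)) / 2; diag(m) <- 100
  a <- cluster_otus(ani_matrix(m), cutoff = 100)
  expect_equal(length(unique(a$otu)), n)
  b <- cluster_otus(ani_matrix(m), cutoff = 0)
  expect_equal(length(unique(b$otu)), 1L)
})

test_that("clustering equals brute-force complete linkage on random matrices", {
  set.seed(22)
  for (i in 1:8) {
    n <- 10
    ids <- sprintf("g%02d", 1:n)
    m <- matrix(runif(n * n, 85, 100), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2; diag(m) <- 100
    cutoff <- runif(1, 90, 98)
    got <- cluster_otus(ani_matrix(m), cutoff)$otu
    want <- brute_complete_linkage(100 - m, 100 - cutoff)
    expect_true(same_partition(got, want))
  }
})

test_that("pairs at exactly the ANI cutoff share an OTU", {
  m <- matrix(c(100, 95, 95, 100), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  otu <- cluster_otus(ani_matrix(m), cutoff = 95)
  expect_equal(otu$otu[["a"]], otu$otu[["b"]])
})

test_that("missing ANI pairs are treated as zero with a warning", {
  m <- matrix(c(100, NA, NA, 100), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(am <- ani_matrix(m), "missing")
  expect_equal(am$values["a", "b"], 0)
})

test_that("representative selection takes the largest region, ties by id", {
  regions <- list(gene_region("rB", 1:14, paste0("g", 1:14)),
                  gene_region("rA", 1:14, paste0("g", 1:14)),
                  gene_region("rC", 1:15, paste0("g", 1:15)))
  m <- matrix(99, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(m) <- 100
  otus <- cluster_otus(ani_matrix(m), 95)
  rep1 <- select_representative(regions, c("x", "y", "z"), otus)
  expect_length(rep1, 1L)
  expect_equal(rep1[[1]]$region_id, "rC")

  # tie on counts: lexicographically first id wins
  rep2 <- select_representative(regions[1:2], c("x", "y"), otus)
  expect_equal(rep2[[1]]$region_id, "rA")
})

test_that("minimum-gene filtering keeps the 9-gene boundary", {
  r8 <- gene_region("a", 1:8, paste0("g", 1:8))
  r9 <- gene_region("b", 1:9, paste0("g", 1:9))
  r17 <- gene_region("c", 1:17, paste0("g", 1:17))
  kept <- filter_min_genes(list(r8, r9, r17))
  expect_equal(vapply(kept, function(r) r$region_id, character(1)), c("b", "c"))
  # brute-force count on a random mix
  set.seed(23)
  sizes <- sample(5:17, 20, replace = TRUE)
  regs <- lapply(seq_along(sizes), function(i)
    gene_region(paste0("r", i), seq_len(sizes[i]), paste0("g", seq_len(sizes[i]))))
  expect_length(filter_min_genes(regs), sum(sizes >= 9))
})

test_that("viral homologs are retained only when nested in one order with support", {
  # ((v,(b1,b2))95,(b3,b4)); b1..b2 order Rhodobacterales, b3..b4 Rhizobiales
  tr <- ape::read.tree(text = "((virus:0.1,(b1:0.1,b2:0.1)90:0.1)95:0.1,(b3:0.1,b4:0.1)99:0.1);")
  ord <- c(b1 = "Rhodobacterales", b2 = "Rhodobacterales",
           b3 = "Rhizobiales", b4 = "Rhizobiales")
  expect_equal(retain_nested_homologs(tr, "virus", ord), "virus")
  # low support at the enclosing clade drops the leaf
  tr2 <- ape::read.tree(text = "((virus:0.1,(b1:0.1,b2:0.1)90:0.1)40:0.1,(b3:0.1,b4:0.1)99:0.1);")
  expect_length(retain_nested_homologs(tr2, "virus", ord), 0L)
  # virus sister to all bacteria is not nested
  tr3 <- ape::read.tree(text = "(virus:0.2,((b1:0.1,b2:0.1)90:0.1,(b3:0.1,b4:0.1)99:0.1)88:0.1);")
  expect_length(retain_nested_homologs(tr3, "virus", ord), 0L)
  # mixed orders in the smallest enclosing clade: dropped
  tr4 <- ape::read.tree(text = "((virus:0.1,(b1:0.1,b3:0.1)99:0.1)99:0.1,(b2:0.1,b4:0.1)99:0.1);")
  expect_length(retain_nested_homologs(tr4, "virus", ord), 0L)
})

test_that("retention matches an exhaustive clade-scan oracle on random trees", {
  set.seed(24)
  orders <- c("OrderA", "OrderB", "OrderC")
  for (i in 1:10) {
    nb <- 8; nv <- 3
    tr <- ape::rtree(nb + nv)
    tr$tip.label <- c(sprintf("b%02d", 1:nb), sprintf("v%02d", 1:nv))[sample(nb + nv)]
    tr$node.label <- as.character(sample(c(30, 50, 70, 95), tr$Nnode, replace = TRUE))
    viral <- grep("^v", tr$tip.label, value = TRUE)
    bact <- grep("^b", tr$tip.label, value = TRUE)
    ord <- setNames(sample(orders, nb, replace = TRUE), bact)
    got <- sort(retain_nested_homologs(tr, viral, ord, support_min = 60))

    # oracle: enumerate every clade, pick the smallest containing the viral
    # leaf and >= 1 bacterial leaf, check order purity and support
    ntip <- length(tr$tip.label)
    sup <- c(NA, as.numeric(tr$node.label[-1]))  # root support unused below
    sup[1] <- 100
    clades <- lapply(seq_len(tr$Nnode), function(j) {
      tips <- ape::extract.clade(tr, ntip + j)$tip.label
      tips
    })
    want <- character(0)
    for (v in viral) {
      cand <- which(vapply(clades, function(tp) v %in% tp && any(tp %in% bact),
                           logical(1)))
      if (length(cand) == 0) next
      smallest <- cand[which.min(lengths(clades[cand]))]
      btips <- intersect(clades[[smallest]], bact)
      if (length(unique(ord[btips])) == 1L && !is.na(sup[smallest]) &&
          sup[smallest] >= 60)
        want <- c(want, v)
    }
    expect_equal(got, sort(want))
  }
})

test_that("retention is monotone in the support threshold", {
  set.seed(25)
  tr <- ape::rtree(12)
  tr$tip.label <- c(sprintf("b%02d", 1:9), "v1", "v2", "v3")[sample(12)]
  tr$node.label <- as.character(sample(40:100, tr$Nnode, replace = TRUE))
  ord <- setNames(rep("OrderA", 9), grep("^b", tr$tip.label, value = TRUE))
  viral <- grep("^v", tr$tip.label, value = TRUE)
  r60 <- retain_nested_homologs(tr, viral, ord, support_min = 60)
  r90 <- retain_nested_homologs(tr, viral, ord, support_min = 90)
  expect_true(all(r90 %in% r60))
})

test_that("top-k closest homologs rank by patristic distance after dedup", {
  tr <- ape::read.tree(text = "((v1:0.1,b1:0.1):0.1,((v2:0.5,b2:0.1):0.1,v3:2.0):0.1);")
  out <- top_k_closest_homologs(tr, c("v1", "v2", "v3"), k = 5)
  expect_equal(length(out), 3L)   # fewer than k: all kept
  expect_equal(out[1], "v1")
  # brute-force ranking oracle
  dm <- ape::cophenetic.phylo(tr)
  want <- names(sort(apply(dm[c("v1", "v2", "v3"), c("b1", "b2")], 1, min)))
  expect_equal(out, want)
  # k truncates
  expect_equal(top_k_closest_homologs(tr, c("v1", "v2", "v3"), k = 2),
               want[1:2])
  # sequences identical after gap removal are collapsed before ranking
  seqs <- c(v1 = "AAW-", v2 = "AAGW", v3 = "AA-W")
  out2 <- top_k_closest_homologs(tr, c("v1", "v2", "v3"), k = 5, sequences = seqs)
  expect_equal(sort(out2), c("v1", "v2"))
})

test_that("ANI matrices round-trip through long and square TSV", {
  am <- generate_ani_matrix(c(3, 2), seed = 31)
  # square
  f1 <- tempfile(fileext = ".tsv")
  write.table(data.frame(taxon = am$taxa, am$values, check.names = FALSE),
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ani_matrix(f1)
  expect_equal(back$values, am$values, tolerance = 1e-12)
  # long format
  pairs <- t(combn(am$taxa, 2))
  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(query = pairs[, 1], reference = pairs[, 2],
                         ani = am$values[pairs]),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- suppressWarnings(read_ani_matrix(f2))
  expect_equal(back2$values[pairs], am$values[pairs], tolerance = 1e-12)
})
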