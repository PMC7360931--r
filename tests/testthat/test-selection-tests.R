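tab <- build_cost_table()

test_that("net carbon change is the shared-column mean difference", {
  expect_equal(net_carbon_change("AWGK", "AWGK", tab), 0)
  expect_equal(net_carbon_change("WW", "GG", tab), 9)
  expect_equal(net_carbon_change("GG", "WW", tab), -9)
  # gapped columns are excluded from both sequences
  expect_equal(net_carbon_change("W-A", "GW-", tab), 9)
  expect_error(net_carbon_change("--A", "W--", tab), "no shared")
  expect_error(net_carbon_change("AW", "AWK", tab), "equal length")

  set.seed(61)
  for (i in 1:5) {
    v <- random_protein(40); a <- random_protein(40)
    vc <- strsplit(v, "")[[1]]; ac <- strsplit(a, "")[[1]]
    want <- mean(tab$carbons[vc] - tab$carbons[ac])
    expect_equal(net_carbon_change(v, a, tab), want)
  }
})

test_that("bootstrap p hits the degenerate extremes and is seed-deterministic", {
  b1 <- bootstrap_net_change("AWGK", "AWGK", tab, n = 500, seed = 3)
  expect_equal(b1$p_value, 1)            # all replicate deltas are 0 (<= 0)
  b2 <- bootstrap_net_change("WWWW", "GGGG", tab, n = 500, seed = 3)
  expect_equal(b2$p_value, 0)            # every column delta strictly positive
  expect_equal(b2$alignment_length_nt, 12L)

  b3 <- bootstrap_net_change("AWFGK", "GWKFA", tab, n = 2000, seed = 7)
  b4 <- bootstrap_net_change("AWFGK", "GWKFA", tab, n = 2000, seed = 7)
  expect_identical(b3$replicates, b4$replicates)
  expect_identical(b3$p_value, b4$p_value)

  # column order leaves the observed delta unchanged and p statistically so
  b5 <- bootstrap_net_change("KGFWA", "AFKWG", tab, n = 2000, seed = 7)
  expect_equal(b5$delta_carbons_per_site, b3$delta_carbons_per_site)
})

test_that("bootstrap p approaches the exact convolution probability", {
  # 12-column toy pair with mixed-sign deltas
  viral <- "WAGFKAPGWQHA"
  anc <- "GWAFAKGPAQAH"
  deltas <- tab$carbons[strsplit(viral, "")[[1]]] -
    tab$carbons[strsplit(anc, "")[[1]]]
  p_exact <- exact_bootstrap_p(unname(deltas))
  b <- bootstrap_net_change(viral, anc, tab, n = 1e5, seed = 11)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(b$p_value - p_exact), 3 * se)
})

test_that("cumulative test reduces to the single-gene bootstrap", {
  pairs <- list(gA = list(list(viral = "AWFGK", ancestral = "GWKFA", virus_id = "v1")))
  cu <- cumulative_net_change(pairs, tab, n = 2000, seed = 7)
  single <- bootstrap_net_change("AWFGK", "GWKFA", tab, n = 2000, seed = 7)
  expect_equal(cu$delta_carbons_per_site, single$delta_carbons_per_site)
  expect_identical(cu$p_value, single$p_value)
  expect_equal(cu$alignment_length_nt, single$alignment_length_nt)
})

test_that("cumulative test picks the conservative homolog and pools columns", {
  pairs <- list(
    g1 = list(list(viral = "WWWW", ancestral = "GGGG", virus_id = "big"),
              list(viral = "AAAA", ancestral = "GGGG", virus_id = "small")),
    g2 = list(list(viral = "GGGG", ancestral = "AAAA", virus_id = "down")))
  cu <- cumulative_net_change(pairs, tab, n = 100, seed = 1)
  expect_equal(cu$selected$virus_id, c("small", "down"))
  # per-gene deltas +1 and -1 on equal lengths cancel
  expect_equal(cu$delta_carbons_per_site, 0)
  # pooled-column oracle on unequal lengths
  pairs2 <- list(g1 = list(list(viral = "WW", ancestral = "GG")),
                 g2 = list(list(viral = "GGGGGG", ancestral = "AAAAAA")))
  cu2 <- cumulative_net_change(pairs2, tab, n = 10, seed = 1)
  expect_equal(cu2$delta_carbons_per_site, (2 * 9 + 6 * (-1)) / 8)
})

test_that("PS-site filtering applies the three-part rule with boundaries", {
  aln <- c(f1 = "AWG", f2 = "AW-", o1 = "GWG", o2 = "GWG")
  beb <- data.frame(site = 1:3, probability = c(0.99, 0.94, 0.96))
  ps <- filter_ps_sites(beb, aln, focal_taxa = c("f1", "f2"))
  # site 1: kept; site 2: beb 0.94 < 0.95 dropped; site 3: focal presence 0.5 kept
  expect_equal(ps$alignment_column, c(1L, 3L))
  ps2 <- filter_ps_sites(beb, aln, focal_taxa = c("f1", "f2"), presence_min = 0.6)
  expect_equal(ps2$alignment_column, 1L)
  # beb exactly at the threshold is kept
  beb3 <- data.frame(site = 1, probability = 0.95)
  expect_equal(nrow(filter_ps_sites(beb3, aln, c("f1", "f2"))), 1L)
  # site index outside the alignment errors
  beb4 <- data.frame(site = 9, probability = 0.99)
  expect_error(filter_ps_sites(beb4, aln, c("f1", "f2")), "outside")
  # a column map translates filtered-alignment numbering
  beb5 <- data.frame(site = 2, probability = 0.99)
  ps5 <- filter_ps_sites(beb5, aln, c("f1", "f2"), column_map = c(1L, 3L))
  expect_equal(ps5$alignment_column, 3L)
})

test_that("site contributions measure partition carbon differences", {
  aln <- c(f1 = "A", f2 = "A", o1 = "F", o2 = "F")
  ps <- data.frame(alignment_column = 1L)
  sc <- site_contribution(aln, ps, c("f1", "f2"), c("o1", "o2"), tab, per = "site")
  expect_equal(sc$avg_delta_carbons, 1 - 7)
  expect_equal(sc$n_decreasing, 1L)

  # identical partitions contribute nothing
  aln2 <- c(f1 = "AWK", o1 = "AWK")
  ps2 <- data.frame(alignment_column = 1:3)
  sc2 <- site_contribution(aln2, ps2, "f1", "o1", tab)
  expect_equal(sc2$avg_delta_carbons, 0)
  expect_equal(sc2$n_decreasing, 0L)

  # conservation: summed site deltas equal the PS-restricted partition
  # difference computed independently
  set.seed(62)
  m <- matrix(sample(AA20, 6 * 30, replace = TRUE), 6, 30,
              dimnames = list(c(paste0("f", 1:3), paste0("o", 1:3)), NULL))
  aln3 <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  cols <- sort(sample(30, 8))
  ps3 <- data.frame(alignment_column = cols)
  sc3 <- site_contribution(aln3, ps3, paste0("f", 1:3), paste0("o", 1:3), tab)
  want <- sum(vapply(cols, function(j)
    mean(tab$carbons[m[1:3, j]]) - mean(tab$carbons[m[4:6, j]]), numeric(1)))
  expect_equal(sum(sc3$site_deltas), want)
  expect_equal(sc3$avg_delta_carbons, want / 30)
  # per-site variant divides by the number of selected sites instead
  sc4 <- site_contribution(aln3, ps3, paste0("f", 1:3), paste0("o", 1:3), tab,
                           per = "site")
  expect_equal(sc4$avg_delta_carbons, want / 8)

  # all-gap partitions cause the site to be skipped, with a record
  aln5 <- c(f1 = "-W", o1 = "AW")
  ps5 <- data.frame(alignment_column = 1:2)
  sc5 <- site_contribution(aln5, ps5, "f1", "o1", tab)
  expect_equal(sc5$skipped_sites, 1L)
  expect_equal(sc5$n_ps_sites, 1L)
})

test_that("planted sweep sites are recovered by the PS accounting", {
  fam <- evolve_family(simulation_config(n_tips = 24), seed = 63)
  beb <- data.frame(site = fam$planted_sites, probability = 0.99)
  ps <- filter_ps_sites(beb, fam$alignment, focal_taxa = fam$focal_tips)
  sc <- site_contribution(fam$alignment, ps, fam$focal_tips,
                          setdiff(names(fam$alignment), fam$focal_tips), tab)
  expect_equal(sc$n_ps_sites, length(fam$planted_sites))
  expect_lt(sc$avg_delta_carbons, 0)
  expect_gt(sc$n_decreasing / sc$n_ps_sites, 0.6)
})

test_that("group comparison wrappers behave on identical and shifted groups", {
  vals <- rep(c(1, 2, 3), 4)
  grp <- rep(c("a", "b"), each = 6)
  kw <- compare_groups(c(vals, vals)[1:12], grp, test = "kruskal_wallis")
  expect_equal(unname(kw$statistic), 0)

  dn <- compare_groups(c(vals, vals)[1:12], grp, test = "dunn")
  expect_equal(dn$statistic, 0)
  expect_equal(dn$p_adjusted, 1)

  # Bonferroni arithmetic: m tests multiply the raw p
  set.seed(64)
  vals2 <- rnorm(40)
  grp2 <- rep(letters[1:4], each = 10)
  mw <- compare_groups(vals2, grp2, test = "mann_whitney")
  expect_equal(nrow(mw), 6L)
  expect_equal(mw$p_adjusted, pmin(1, mw$p_value * 6))

  tt <- compare_groups(vals2, grp2, test = "t_test", correction = "none")
  expect_equal(tt$p_adjusted, tt$p_value)

  expect_warning(
    compare_groups(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c"),
                   test = "kruskal_wallis"),
    "fewer than 2")
  expect_error(suppressWarnings(compare_groups(c(1, 2), c("a", "b"))), "2 groups")
})

test_that("Dunn's z follows the rank-sum formula and detects a large shift", {
  set.seed(65)
  x <- c(rnorm(15), rnorm(15, 3), rnorm(15))
  g <- rep(c("a", "b", "c"), each = 15)
  dn <- compare_groups(x, g, test = "dunn")
  # independent recomputation of one pair's z from the definition
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (2 / 15))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(dn$statistic[dn$group1 == "a" & dn$group2 == "b"], z_ab)
  expect_lt(dn$p_adjusted[dn$group1 == "a" & dn$group2 == "b"], 0.01)
  expect_gt(dn$p_adjusted[dn$group1 == "a" & dn$group2 == "c"], 0.05)
})

test_that("bootstrap tables serialize the Table-1 style columns", {
  b <- bootstrap_net_change("WWWW", "GGGG", tab, n = 50, seed = 1,
                            gene_id = "g6", virus_id = "phage_X")
  f <- tempfile(fileext = ".tsv")
  write_bootstrap_table(list(b), f)
  got <- read.delim(f)
  expect_equal(got$gene, "g6")
  expect_equal(got$delta_carbons_per_site, 9)
  expect_equal(got$alignment_length_nt, 12L)

  fb <- tempfile(fileext = ".tsv")
  write.table(data.frame(site = 1:3, probability = c(0.99, 0.5, 0.96)),
              fb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_beb_table(fb)), 3L)
})
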