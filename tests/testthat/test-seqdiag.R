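toy_aln <- function(...) as_alignment(c(...))

test_that("site masking removes the union of ranges", {
  set.seed(50)
  aln <- matrix(sample(c("A", "C", "G", "T"), 4 * 975, replace = TRUE),
                4, 975, dimnames = list(paste0("t", 1:4), NULL))
  mask <- parse_site_mask(system.file("extdata", "mask_12s.txt",
                                      package = "decrange"))
  res <- apply_site_mask(aln, mask)
  expect_equal(res$removed, 127)
  expect_equal(ncol(res$alignment), 848)

  # empty mask is the identity
  none <- apply_site_mask(aln, matrix(integer(0), 0, 2))
  expect_equal(ncol(none$alignment), 975)
  expect_equal(none$removed, 0)

  # overlapping ranges are unioned
  ov <- apply_site_mask(aln, rbind(c(5, 10), c(8, 12)))
  expect_equal(ov$removed, 8)

  expect_error(apply_site_mask(aln, rbind(c(900, 1000))), "outside")

  # removed + remaining = original for random masks
  for (i in 1:5) {
    st <- sort(sample(900, 4))
    m <- cbind(st, pmin(st + sample(0:30, 4), 975))
    r <- apply_site_mask(aln, m)
    expect_equal(r$removed + ncol(r$alignment), 975)
  }
})

test_that("uncorrected-p distances honor the deletion rules", {
  a <- toy_aln(s1 = "ACGT", s2 = "ACGA")
  expect_equal(pdistance(a)$distance["s1", "s2"], 0.25)

  b <- toy_aln(s1 = "AC-T", s2 = "ACGT")
  pb <- pdistance(b)
  expect_equal(pb$distance["s1", "s2"], 0)
  expect_equal(pb$effective_sites["s1", "s2"], 3)

  idn <- toy_aln(s1 = "ACGTACGT", s2 = "ACGTACGT")
  expect_equal(pdistance(idn)$distance["s1", "s2"], 0)

  # zero effective overlap is NA and flagged, never 0
  z <- toy_aln(s1 = "AC--", s2 = "--GT", s3 = "ACGT")
  pz <- pdistance(z)
  expect_true(is.na(pz$distance["s1", "s2"]))
  expect_equal(nrow(pz$undefined_pairs), 1)

  # complete deletion equals pairwise when nothing is missing
  set.seed(51)
  cl <- matrix(sample(c("A", "C", "G", "T"), 5 * 300, replace = TRUE),
               5, 300, dimnames = list(paste0("t", 1:5), NULL))
  expect_equal(pdistance(cl, "complete")$distance,
               pdistance(cl, "pairwise")$distance)

  # cross-check against ape's raw pairwise-deletion distance
  amb <- cl
  amb[1, 1:30] <- "N"
  amb[2, 10:40] <- "-"
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(amb)),
                                 model = "raw", pairwise.deletion = TRUE))
  mine <- pdistance(amb)$distance
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("group mean distances average cross pairs", {
  D <- matrix(0.131, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  groups <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  M <- group_mean_distance(D, groups)
  expect_equal(M["g1", "g2"], 0.131)
  expect_equal(M["g1", "g1"], 0.131)

  # permuting taxa leaves the means unchanged
  set.seed(52)
  D2 <- matrix(runif(16, 0, 0.3), 4, 4)
  D2 <- (D2 + t(D2)) / 2; diag(D2) <- 0
  dimnames(D2) <- list(letters[1:4], letters[1:4])
  perm <- sample(letters[1:4])
  expect_equal(group_mean_distance(D2, groups),
               group_mean_distance(D2[perm, perm], groups))

  # singleton group: within-group mean absent
  g3 <- c(a = "g1", b = "g1", c = "g1", d = "solo")
  expect_true(is.na(group_mean_distance(D2, g3)["solo", "solo"]))
  expect_error(group_mean_distance(D2, groups[1:3]), "ungrouped")
})

test_that("saturation table pairs divergence with substitution counts", {
  set.seed(53)
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  var <- base
  var[1:3] <- ifelse(base[1:3] == "A", "C", "A")
  aln <- rbind(s1 = base, s2 = var)
  tab <- saturation_table(aln, codon_pos = rep_len(1:3, 300))
  expect_equal(tab$percent_divergence, 1.0)
  expect_equal(tab$substitutions, 3)

  same <- rbind(s1 = base, s2 = base)
  tab0 <- saturation_table(same, codon_pos = rep_len(1:3, 300))
  expect_equal(tab0$substitutions, 0)
  expect_equal(tab0$percent_divergence, 0)

  expect_error(saturation_table(aln), "codon")

  # substitutions rise with simulated divergence
  phy <- parse_newick("(a:0.02,b:0.02);")
  sims <- lapply(c(1, 5, 15, 40), function(k) {
    tr <- phy; tr$edge.length <- tr$edge.length * k
    simulate_alignment(tr, length = 2000, seed = 53 + k)
  })
  tabs <- do.call(rbind, lapply(sims, saturation_table,
                                third_position = FALSE))
  expect_gt(cor(tabs$percent_divergence, tabs$substitutions,
                method = "spearman"), 0.9)
})

test_that("base composition heterogeneity test matches the hand formula", {
  # toy 2x4 table: (10,10,10,10) vs (40,0,0,0)
  aln <- rbind(s1 = rep(c("A", "C", "G", "T"), 10),
               s2 = rep("A", 40))
  res <- base_composition_test(aln)
  counts <- rbind(c(10, 10, 10, 10), c(40, 0, 0, 0))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(res$statistic, sum((counts - expected)^2 / expected),
               tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(unname(rowSums(res$frequencies)), c(1, 1))

  idn <- rbind(s1 = rep(c("A", "C", "G", "T"), 5),
               s2 = rep(c("A", "C", "G", "T"), 5),
               s3 = rep(c("A", "C", "G", "T"), 5))
  r0 <- base_composition_test(idn)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$df, 6)
})

test_that("informative site counts follow the two-by-two rule and add up", {
  aln <- rbind(s1 = c("A", "A", "G"),
               s2 = c("A", "A", "G"),
               s3 = c("C", "A", "G"),
               s4 = c("C", "C", "G"))
  # col 1: A,A,C,C informative; col 2: A,A,A,C not; col 3: constant
  expect_equal(count_informative_sites(aln), 1)

  set.seed(54)
  phy <- simulate_yule_tree(8, 0.5)
  a1 <- simulate_alignment(phy, 300, rate_scale = 0.05, seed = 1)
  a2 <- simulate_alignment(phy, 200, rate_scale = 0.05, seed = 2)
  expect_equal(count_informative_sites(cbind(a1, a2[rownames(a1), ])),
               count_informative_sites(a1) + count_informative_sites(a2))
})

test_that("g1 skewness detects simulated signal and is zero for symmetry", {
  expect_equal(decrange:::moment_skewness(c(1, 2, 3)), 0)
  expect_equal(decrange:::moment_skewness(c(-5, 0, 5)), 0, tolerance = 1e-12)

  # textbook Fitch length
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- rbind(a = "A", b = "A", c = "C", d = "C")
  expect_equal(fitch_length(phy, aln), 1)

  set.seed(55)
  tree <- simulate_yule_tree(8, 0.5)
  sig <- simulate_alignment(tree, 400, rate_scale = 0.08, seed = 3)
  g_sig <- g1_statistic(sig, n_trees = 400, seed = 4)
  expect_lt(g_sig$g1, -0.2)

  shuf <- apply(sig, 2, sample)
  rownames(shuf) <- rownames(sig)
  g_null <- g1_statistic(shuf, n_trees = 400, seed = 5)
  expect_lt(abs(g_null$g1), 0.25)
  expect_lt(g_sig$g1, g_null$g1)  # signal more left-skewed than noise
})
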