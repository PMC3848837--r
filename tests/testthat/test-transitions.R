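truth_calls <- function(phy, h) {
  ntot <- ape::Ntip(phy) + phy$Nnode
  st <- h$node_states
  st[ape::Ntip(phy) + 1] <- h$root_range
  data.frame(node = seq_len(ntot), range = st, prob = 1,
             certain = TRUE, stringsAsFactors = FALSE)
}

test_that("branch range calls take the best marginal and honor the threshold", {
  set.seed(40)
  hub <- hub_space()
  case <- random_case(hub, 5)
  anc <- ancestral_splits(case$phy, case$tips, hub, case$d, case$e)
  calls <- classify_branch_ranges(anc, threshold = 0.75)
  bm <- anc$branch_marginals
  for (k in seq_len(nrow(calls))) {
    b <- bm[bm$node == calls$node[k], ]
    if (!nrow(b)) next  # root call comes from root_states
    expect_equal(calls$prob[k], max(b$prob))
    expect_equal(calls$certain[k], calls$prob[k] >= 0.75)
  }
  # a marginal exactly at the threshold counts as certain (>=)
  pstar <- calls$prob[1]
  at <- classify_branch_ranges(anc, threshold = pstar)
  expect_true(at$certain[at$node == calls$node[1]])
})

test_that("transition polarity is attributed through uncertain ancestors", {
  phy <- parse_newick("(((x:1,s1:1):1,s2:2):1,s3:3);")
  # node ids: tips x=1,s1=2,s2=3,s4=4; root=5; p2=6 (age 2); p1=7 (age 1)
  calls <- data.frame(
    node = 1:7,
    range = c("B", "A", "A", "A", "A", "A", "A"),
    prob = c(0.99, 0.95, 0.9, 0.9, 0.86, 0.95, 0.63),
    certain = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ev <- detect_transitions(calls, phy, focal = c("A", "B"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$polarity, "A->B")
  expect_equal(ev$depth, "ii")      # certain origin two branches back
  expect_equal(ev$earliest, 2)
  expect_equal(ev$latest, 0)
  expect_equal(ev$support, 0.95)

  # all calls certain and identical: nothing to report
  flat <- calls
  flat$range <- "A"
  flat$certain <- TRUE
  expect_equal(nrow(detect_transitions(flat, phy)), 0)

  # uncertainty deeper than three branches yields uncertain polarity
  deep <- parse_newick("((((x:1,s1:1):1,s2:2):1,s3:3):1,s4:4);")
  calls2 <- data.frame(
    node = 1:9,
    range = c("B", "A", "A", "A", "A", "A", "A", "A", "A"),
    prob = c(0.99, 0.9, 0.9, 0.9, 0.9, 0.5, 0.5, 0.5, 0.5),
    certain = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  ev2 <- detect_transitions(calls2, deep, focal = c("A", "B"))
  ev2 <- ev2[ev2$node == 1, ]
  # candidate parent ranges all imply an Amazon source, so polarity is
  # still emitted, with a note
  expect_equal(ev2$polarity, "A->B")
  expect_match(ev2$note, "candidate")
})

test_that("simulated single-event histories are recovered with the right polarity", {
  set.seed(41)
  two <- two_area_space()
  hits <- 0; total <- 0; tries <- 0
  while (total < 100 && tries < 4000) {
    tries <- tries + 1
    phy <- simulate_yule_tree(6, lambda = 0.5)
    h <- simulate_dec_history(phy, two, d = 0.08, e = 0, root_range = "A")
    if (nrow(h$events) != 1) next
    total <- total + 1
    ev <- detect_transitions(truth_calls(phy, h), phy, focal = c("A", "B"))
    ev <- ev[ev$node == h$events$node[1], ]
    if (nrow(ev) == 1 && ev$polarity == "A->B") {
      hits <- hits + 1
      # the window must bracket the true event time
      ages <- node_ages(phy)
      parent <- phy$edge[phy$edge[, 2] == h$events$node[1], 1]
      true_age <- ages[parent] - h$events$time_from_top[1]
      expect_gte(ev$earliest + 1e-9, true_age)
      expect_lte(ev$latest, true_age + 1e-9)
    }
  }
  expect_gte(total, 100)
  expect_gte(hits / total, 0.9)
})

test_that("type bins partition ages with the documented boundaries", {
  expect_equal(assign_type(2.5)$type, 3)   # boundary inclusive below
  expect_equal(assign_type(7.5)$type, 2)
  expect_equal(assign_type(21.1)$type, 1)
  expect_equal(assign_type(0)$type, 3)
  expect_error(assign_type(-1), "non-negative")

  ages <- c(0, runif(200, 0, 30), 2.5, 7.5, 2.5000001, 7.5000001)
  ty <- assign_type(ages)
  expect_true(all(ty$type %in% 1:3))
  expect_true(all(ty$age > ty$min_age | ty$age == 0))
  expect_true(all(ty$age <= ty$max_age))

  bins <- transition_type_bins()
  expect_equal(bins$max_age[match(3, bins$type)], 2.5)
  expect_equal(bins$max_age[match(2, bins$type)], 7.5)
})
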