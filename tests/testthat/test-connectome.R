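# helper: one seed->target connection with controlled synapse count and
# relative input percentage (via the totals argument)
selection_decision <- function(synapses, pct) {
  tab <- synapse_table(data.frame(
    pre_id = "seed.1", pre_type = "seed", post_id = "T.1", post_type = "T",
    roi = "LH", side = "unknown", weight = synapses))
  totals <- c(T = synapses / pct * 100)
  select_downstream_types(tab, "seed", totals = totals)$decision
}

test_that("partner selection matches the boundary-line rule", {
  expect_equal(selection_decision(60, 0.1), "include")
  expect_equal(selection_decision(10, 10), "exclude")
  # line through (10, 4) and (50, 0.5): threshold at 30 synapses is 2.25%
  expect_equal(selection_decision(30, 2.30), "include")
  expect_equal(selection_decision(30, 2.20), "exclude")
  # closures: 51 included irrespective, 11 tested against the line
  expect_equal(selection_decision(51, 0.01), "include")
  expect_equal(selection_decision(11, 4.0), "include")
  expect_equal(selection_decision(11, 3.8), "exclude")
})

test_that("partner selection is monotone in count and fraction", {
  set.seed(13)
  rank_of <- c(exclude = 0, include = 1)
  for (i in 1:50) {
    s <- sample(2:80, 1)
    pct <- runif(1, 0.05, 8)
    base_rank <- rank_of[selection_decision(s, pct)]
    expect_gte(rank_of[selection_decision(s + sample(1:20, 1), pct)],
               base_rank)
    expect_gte(rank_of[selection_decision(s, pct + runif(1, 0, 4))],
               base_rank)
  }
})

test_that("selection computes fractions from the table and filters ROIs", {
  tab <- generate_toy_connectome(data.frame(
    pre_type = c("seed", "seed", "other"),
    post_type = c("A", "B", "A"),
    weight = c(60, 9, 60),
    roi = c("LH", "SIP", "LH")))
  sel <- select_downstream_types(tab, "seed")
  expect_equal(sel$decision[sel$post_type == "A"], "include")
  expect_equal(sel$fraction_pct[sel$post_type == "A"], 50)
  expect_equal(sel$decision[sel$post_type == "B"], "exclude")
  sel_lh <- select_downstream_types(tab, "seed", roi_filter = "LH")
  expect_false("B" %in% sel_lh$post_type)
  expect_error(select_downstream_types(tab, "nonexistent"), "seed")
})

test_that("input selectivity follows the 25%/50% cascade", {
  labels <- data.frame(
    pre_type = c("PN_DA1", "PN_DL3", "Sens1"),
    pathway = c("uniglomerular-PN", "uniglomerular-PN", "sensory"),
    glomerulus = c("DA1", "DL3", NA))
  build <- function(da1, other, sens) {
    generate_toy_connectome(data.frame(
      pre_type = c("PN_DA1", "PN_DL3", "Sens1"),
      post_type = "T", weight = c(da1, other, sens)))
  }
  expect_equal(classify_input_selectivity(build(50, 50, 30), "T",
                                          labels)$class, "multimodal")
  expect_equal(classify_input_selectivity(build(60, 40, 10), "T",
                                          labels)$class, "DA1-selective")
  expect_equal(classify_input_selectivity(build(40, 60, 10), "T",
                                          labels)$class, "mixed-olfactory")
  # scale invariance
  expect_equal(classify_input_selectivity(build(60 * 7, 40 * 7, 10 * 7), "T",
                                          labels)$class, "DA1-selective")
  # no olfactory input -> unclassifiable
  sens_only <- generate_toy_connectome(data.frame(
    pre_type = "Sens1", post_type = "T", weight = 100))
  expect_equal(classify_input_selectivity(sens_only, "T", labels)$class,
               "unclassifiable")
})

test_that("weak partners are excluded before classification", {
  labels <- data.frame(
    pre_type = c("PN_DA1", "Sens1"),
    pathway = c("uniglomerular-PN", "sensory"),
    glomerulus = c("DA1", NA))
  # sensory partner at 10 synapses and <=0.5% of inputs: not considered
  tab <- generate_toy_connectome(data.frame(
    pre_type = c("PN_DA1", "Sens1"), post_type = "T",
    weight = c(1990, 10)))
  res <- classify_input_selectivity(tab, "T", labels)
  expect_equal(res$sensory_input, 0)
  expect_equal(res$class, "DA1-selective")
})

test_that("contra/ipsi profiles reproduce planted ratios", {
  spec <- data.frame(
    pre_type = c("ORN_DA1", "ORN_DA1", "ORN_DL3", "ORN_DL3", "LN1", "LN1"),
    post_type = c("LN1", "LN1", "LN1", "LN1", "PN_DA1", "PN_DL3"),
    weight = c(1901, 359, 40, 40, 300, 100),
    side = c("contra", "ipsi", "contra", "ipsi", "unknown", "unknown"))
  tab <- generate_toy_connectome(spec)
  prof <- contra_ipsi_profile(tab, "LN1")
  da1 <- prof[prof$glomerulus == "DA1", ]
  expect_equal(da1$ratio, 1901 / 359, tolerance = 1e-12)
  expect_equal(round(da1$ratio, 2), 5.3)
  expect_equal(prof$ratio[prof$glomerulus == "DL3"], 1)
  expect_equal(da1$pn_output_fraction, 300 / 400)
  expect_equal(da1$contra, 1901)
})

test_that("unknown sides and zero ipsi counts are handled", {
  spec <- data.frame(
    pre_type = c("ORN_DA1", "ORN_DA1", "ORN_DX", "ORN_DZ"),
    post_type = "LN1",
    weight = c(50, 10, 20, 30),
    side = c("contra", "ipsi", "unknown", "contra"))
  tab <- generate_toy_connectome(spec)
  expect_warning(prof <- contra_ipsi_profile(tab, "LN1"), "DX")
  expect_false("DX" %in% prof$glomerulus)
  dz <- prof[prof$glomerulus == "DZ", ]
  expect_true(is.na(dz$ratio))
  expect_false(dz$ratio_defined)
  all_unknown <- generate_toy_connectome(data.frame(
    pre_type = "ORN_DA1", post_type = "LN1", weight = 5, side = "unknown"))
  expect_error(contra_ipsi_profile(all_unknown, "LN1"), "side-labeled")
})

test_that("branch-count test matches the closed-form t statistic", {
  counts <- c(9, 9, 8, 10, 7, 10)
  res <- branch_count_test(counts)
  expect_equal(res$mean, mean(counts))
  expect_equal(round(res$mean, 2), 8.83)
  t_manual <- (mean(counts) - 1) / (sd(counts) / sqrt(length(counts)))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-4)
  ones <- branch_count_test(c(1, 1, 1, 1))
  expect_equal(ones$p_value, 1)
  expect_equal(ones$mean, 1)
  twos <- branch_count_test(c(2, 2, 2))
  expect_equal(twos$p_value, 0)
  expect_error(branch_count_test(9))
})

test_that("Ward clustering recovers planted blocks", {
  set.seed(14)
  n <- 12
  truth <- rep(1:3, each = 4)
  sim <- matrix(0.05, n, n)
  for (k in 1:3) sim[truth == k, truth == k] <- 0.9
  diag(sim) <- 1
  sim <- sim + matrix(runif(n * n, 0, 0.01), n, n)
  sim <- (sim + t(sim)) / 2
  labels <- ward_cluster(sim, k = 3)
  expect_true(same_partition(labels, truth))
  expect_equal(length(unique(ward_cluster(sim, k = 1))), 1)
  tree <- attr(labels, "tree")
  expect_true(all(diff(tree$height) >= -1e-9))
  expect_error(ward_cluster(matrix(1, 2, 3)), "square")
  asym <- sim; asym[1, 2] <- asym[1, 2] + 1
  expect_error(ward_cluster(asym), "symmetric")
})

test_that("toy connectomes preserve planted totals and validate input", {
  spec <- data.frame(pre_type = "A", post_type = "B", weight = 17,
                     n_pre = 3, n_post = 2)
  tab <- generate_toy_connectome(spec)
  expect_equal(sum(tab$weight), 17)
  expect_equal(length(unique(tab$pre_id)), 3)
  expect_equal(length(unique(tab$post_id)), 2)
  expect_error(generate_toy_connectome(data.frame(pre_type = "A",
                                                  post_type = "B",
                                                  weight = 0.5)), "integer")
  expect_error(synapse_table(data.frame(pre_id = 1)), "missing columns")
  expect_error(generate_toy_connectome(data.frame(
    pre_type = "A", post_type = "B", weight = 3, side = "up")), "side")
})
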