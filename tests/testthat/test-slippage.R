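test_that("synapomorphic ranks follow node depth on the focal path", {
  hyp <- ladder_hypothesis()  # one character per on-path node
  r <- synapomorphic_ranks(hyp, "homology")
  expect_equal(r$syn_rank[match(c("w", "x", "y", "z"), r$character_id)],
               c(1, 2, 3, 4))
  # two characters on the same node share a midrank
  hyp2 <- ladder_hypothesis(c(w = "n1", v = "n1", x = "n2"))
  r2 <- synapomorphic_ranks(hyp2, "homology")
  expect_equal(r2$syn_rank[match(c("w", "v"), r2$character_id)], c(1.5, 1.5))
  expect_equal(r2$syn_rank[r2$character_id == "x"], 3)
})

test_that("homoplasy treatment reassigns contested characters", {
  hyp <- ladder_hypothesis(contested = c(y = "n1"))
  hom <- synapomorphic_ranks(hyp, "homology")
  hpl <- synapomorphic_ranks(hyp, "homoplasy")
  expect_equal(hom$depth[hom$character_id == "y"], 3)
  expect_equal(hpl$depth[hpl$character_id == "y"], 1)
  # recomputed by hand on the toy tree: depths w=1,x=2,y=1,z=4 under
  # homoplasy -> midranks 1.5, 3, 1.5, 4
  expect_equal(hpl$syn_rank[match(c("w", "x", "y", "z"),
                                  hpl$character_id)],
               c(1.5, 3, 1.5, 4))
  # homoplasy without any contested characters is an error
  expect_error(synapomorphic_ranks(ladder_hypothesis(), "homoplasy"),
               "no contested")
})

test_that("uninformative-character filtering removes only the extreme depths", {
  hyp <- ladder_hypothesis(c(w = "n1", x = "n2", y = "n3", z = "n4",
                             v = "n2"))
  ranking <- synapomorphic_ranks(hyp, "homology")
  dr <- decay_rank_table(make_milestones(c("w", "x", "y", "z", "v"),
                                         1:5, 2:6, 3:7, c(8, 12, 19, 30, 47)))
  flt <- filter_informative(ranking, dr)
  expect_setequal(flt$ranking$character_id, c("x", "y", "v"))
  # survivors are re-ranked over the restriction
  expect_equal(sort(flt$decay_ranks$decay_rank), 1:3)
  expect_equal(flt$ranking$syn_rank[flt$ranking$character_id == "y"], 3)
  expect_equal(sum(flt$ranking$syn_rank), 6)
  # fewer than 3 survivors is an error
  hyp2 <- ladder_hypothesis(c(w = "n1", x = "n2", z = "n4"))
  r2 <- synapomorphic_ranks(hyp2, "homology")
  expect_error(filter_informative(r2, dr), "fewer than 3")
})

test_that("filtering never removes a character at an intermediate depth", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    depths <- sample(1:4, n, TRUE)
    ids <- paste0("c", 1:n)
    hyp <- ladder_hypothesis(stats::setNames(paste0("n", depths), ids))
    ranking <- synapomorphic_ranks(hyp, "homology")
    dr <- decay_rank_table(make_milestones(ids, 1:n, 1:n + 1, 1:n + 2,
                                           1:n + 3))
    intermediate <- ids[depths > 1 & depths < 4]
    if (length(intermediate) < 3) next
    flt <- filter_informative(ranking, dr)
    expect_true(all(intermediate %in% flt$ranking$character_id))
    expect_false(any(ids[depths %in% c(1, 4)] %in% flt$ranking$character_id))
  }
})

test_that("spearman matches the midrank+Pearson oracle to 1e-12", {
  set.seed(3)
  for (rep in 1:60) {
    n <- sample(4:25, 1)
    x <- sample(1:6, n, TRUE)        # heavy ties
    y <- stats::rnorm(n)
    if (stats::sd(x) == 0) next
    st <- spearman_test(x, y, p_method = "t_approx")
    expect_equal(st$r_s, oracle_spearman(x, y), tolerance = 1e-12)
    # and against the standard library estimate
    expect_equal(st$r_s,
                 unname(suppressWarnings(
                   stats::cor.test(x, y, method = "spearman")$estimate)),
                 tolerance = 1e-12)
  }
  expect_equal(spearman_test(1:5, 1:5 * 2)$r_s, 1)
  expect_equal(spearman_test(1:5, 5:1)$r_s, -1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant ranks")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("exact permutation p equals full enumeration, with and without ties", {
  cases <- list(
    list(x = c(3, 1, 4, 1, 5, 9), y = c(2, 7, 1, 8, 2, 8)),  # ties both sides
    list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 5, 3, 4)),
    list(x = c(1, 1, 2, 3, 4, 5, 6), y = c(7, 3, 5, 1, 6, 2, 4)))
  for (cs in cases) {
    st <- spearman_test(cs$x, cs$y, p_method = "exact")
    expect_equal(st$p_value, oracle_exact_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("Monte Carlo p agrees with exact p within 3 standard errors at n = 7", {
  x <- c(2, 6, 1, 7, 4, 3, 5)
  y <- c(3, 5, 2, 7, 6, 1, 4)
  exact <- spearman_test(x, y, p_method = "exact")$p_value
  mc <- spearman_test(x, y, p_method = "monte_carlo", n_perm = 20000,
                      seed = 99)$p_value
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(mc - exact), 3 * se)
  # seeded Monte Carlo is reproducible and leaves the global RNG untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1)
  mc2 <- spearman_test(x, y, p_method = "monte_carlo", n_perm = 2000,
                       seed = 99)$p_value
  expect_equal(stats::runif(1), before)
  mc3 <- spearman_test(x, y, p_method = "monte_carlo", n_perm = 2000,
                       seed = 99)$p_value
  expect_identical(mc2, mc3)
})

test_that("the battery yields one test per hypothesis-treatment pair", {
  sim <- simulate_experiment(decay_sim_config(seed = 5))
  ranks <- decay_rank_table(milestone_times(aggregate_states(sim$scores)))
  hyps <- example_hypotheses(sim$scores$characters, n_hypotheses = 4,
                             seed = 2)
  bat <- run_test_battery(ranks, hyps)
  expect_equal(nrow(bat), 8L)  # 4 hypotheses x {homology, homoplasy}
  expect_setequal(unique(bat$treatment), c("homology", "homoplasy"))
  expect_true(all(abs(bat$r_s) <= 1))
  expect_true(all(bat$p_value > 0 & bat$p_value <= 1))
  expect_true(all(bat$n_characters >= 3))
  # without contested characters there is one test per hypothesis
  plain <- lapply(hyps, function(h) {
    phylo_hypothesis(h$tree, h$focal, h$assignments,
                     hypothesis_id = h$hypothesis_id)
  })
  expect_equal(nrow(run_test_battery(ranks, plain)), 4L)
})

test_that("battery results are invariant to character and hypothesis order", {
  sim <- simulate_experiment(decay_sim_config(seed = 9))
  ranks <- decay_rank_table(milestone_times(aggregate_states(sim$scores)))
  hyps <- example_hypotheses(sim$scores$characters, seed = 4)
  b1 <- run_test_battery(ranks, hyps, p_method = "monte_carlo",
                         n_perm = 500, seed = 17)
  ranks_shuffled <- ranks[sample(nrow(ranks)), ]
  b2 <- run_test_battery(ranks_shuffled, rev(hyps),
                         p_method = "monte_carlo", n_perm = 500, seed = 17)
  expect_equal(b1, b2)
})

test_that("perfect rank agreement across every hypothesis gives r_s = 1", {
  hyp <- ladder_hypothesis()
  ranking <- synapomorphic_ranks(hyp, "homology")
  dr <- decay_rank_table(make_milestones(c("w", "x", "y", "z"),
                                         1:4, 2:5, 3:6, c(8, 12, 19, 30)))
  bat <- run_test_battery(dr, list(hyp))
  expect_equal(bat$r_s, 1)
})

test_that("cross-taxon rank comparison re-ranks the shared character set", {
  m <- make_milestones(paste0("c", 1:6), 1:6, 2:7, 3:8, c(2, 5, 8, 12, 19, 30))
  ra <- decay_rank_table(m)
  expect_equal(compare_taxa_ranks(ra, ra)$r_s, 1)
  # shared subset only, reversed order in taxon b
  m2 <- make_milestones(paste0("c", c(1:4, 7)), 5:1, 6:2, 7:3, c(30, 19, 12, 5, 2))
  rb <- decay_rank_table(m2)
  cmp <- compare_taxa_ranks(ra, rb)
  expect_setequal(cmp$characters, paste0("c", 1:4))
  expect_equal(cmp$r_s, -1)
  rc <- decay_rank_table(make_milestones(c("q1", "q2", "q3"),
                                         1:3, 2:4, 3:5, 4:6))
  expect_error(compare_taxa_ranks(ra, rc), "share no characters")
})
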