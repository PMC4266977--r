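test_that("specimen conditions aggregate to the five-state ordinal coding", {
  chars <- toy_characters()
  agg <- function(cond) {
    rec <- data.frame(specimen_id = paste0("s", seq_along(cond)),
                      character_id = "gut", day = 3, condition = cond)
    aggregate_character_state(decay_scores(rec, chars), "gut", 3)
  }
  expect_identical(agg(c(0, 0)), 0L)
  expect_identical(agg(c(0, 1)), 1L)
  expect_identical(agg(c(1, 1)), 2L)
  expect_identical(agg(c(1, 2)), 3L)
  expect_identical(agg(c(0, 2)), 3L)
  expect_identical(agg(c(2, 2)), 4L)
  expect_identical(agg(c(0, 1, 2)), 3L)
  # not-scored specimens are excluded; a fully unscored day is "no data"
  expect_identical(agg(c(NA, 1)), 2L)
  expect_true(is.na(agg(c(NA, NA))))
})

test_that("aggregation is monotone in any single specimen's condition", {
  # replacing one condition by a strictly worse one never lowers the state
  base_sets <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  states <- apply(base_sets, 1L, function(cond) {
    decaylab:::.aggregate_conditions(as.integer(cond))
  })
  for (i in seq_len(nrow(base_sets))) {
    for (j in 1:3) {
      cond <- as.integer(base_sets[i, ])
      if (cond[j] < 2L) {
        worse <- cond
        worse[j] <- worse[j] + 1L
        expect_gte(decaylab:::.aggregate_conditions(worse), states[i])
      }
    }
  }
})

test_that("milestones are the first sampled day reaching each state", {
  s <- data.frame(character_id = "x", day = c(1, 2, 4, 8, 16),
                  state = 0:4)
  m <- milestone_times(s)
  expect_equal(unlist(m[1, c("t_onset_decay", "t_complete_decay",
                             "t_onset_loss", "t_complete_loss")],
                      use.names = FALSE),
               c(2, 4, 8, 16))
  expect_true(m$monotone)

  # never-decaying series is censored at all four milestones
  s0 <- data.frame(character_id = "x", day = c(1, 4, 16), state = 0L)
  m0 <- milestone_times(s0)
  expect_true(all(is.na(m0[1, c("t_onset_decay", "t_complete_decay",
                                "t_onset_loss", "t_complete_loss")])))

  # a series that skips state 2 still yields complete-decay via >= threshold
  s2 <- data.frame(character_id = "x", day = c(1, 4, 12), state = c(0, 1, 4))
  m2 <- milestone_times(s2)
  expect_equal(m2$t_complete_decay, 12)
  expect_equal(m2$t_complete_loss, 12)

  # non-monotone series (destructive sampling) flagged but still scanned
  s3 <- data.frame(character_id = "x", day = c(1, 4, 12), state = c(3, 1, 4))
  m3 <- milestone_times(s3)
  expect_false(m3$monotone)
  expect_equal(m3$t_onset_loss, 1)
})

test_that("end-to-end milestones match the paper-style day-12 loss pattern", {
  sc <- toy_scores()
  m <- milestone_times(aggregate_states(sc))
  gut <- m[m$character_id == "gut", ]
  expect_equal(gut$t_onset_loss, 4)   # first day with some specimens lost
  expect_equal(gut$t_complete_loss, 16)
  claws <- m[m$character_id == "claws", ]
  expect_true(all(is.na(claws[, c("t_onset_decay", "t_complete_decay",
                                  "t_onset_loss", "t_complete_loss")])))
})

test_that("decay ranks follow the four-key tie-break hierarchy", {
  # primary key: complete loss
  m <- make_milestones(c("A", "B"), c(1, 1), c(2, 2), c(4, 4), c(8, 34))
  r <- decay_rank_table(m)
  expect_equal(r$decay_rank[match(c("A", "B"), r$character_id)], c(1, 2))

  # tie on complete loss broken by onset of loss
  m <- make_milestones(c("A", "B"), c(1, 1), c(2, 2), c(8, 12), c(34, 34))
  r <- decay_rank_table(m)
  expect_equal(r$decay_rank[match(c("A", "B"), r$character_id)], c(1, 2))

  # then complete decay, then onset of decay
  m <- make_milestones(c("A", "B"), c(1, 2), c(4, 4), c(8, 8), c(34, 34))
  r <- decay_rank_table(m)
  expect_equal(r$decay_rank[match(c("A", "B"), r$character_id)], c(1, 2))

  # censored-vs-censored at one level falls through to the next
  m <- make_milestones(c("A", "B"), c(1, 3), c(2, 4), c(NA, NA), c(NA, NA))
  r <- decay_rank_table(m)
  expect_equal(r$decay_rank[match(c("A", "B"), r$character_id)], c(1, 2))

  # fully censored characters (jaws/claws) are tied last with midranks
  m <- make_milestones(c("gut", "jaws", "claws"),
                       c(1, NA, NA), c(2, NA, NA), c(4, NA, NA),
                       c(8, NA, NA))
  r <- decay_rank_table(m)
  expect_equal(r$decay_rank[r$character_id == "gut"], 1)
  expect_equal(r$decay_rank[r$character_id %in% c("jaws", "claws")],
               c(2.5, 2.5))
  expect_equal(length(unique(r$tie_group[r$character_id %in%
                                           c("jaws", "claws")])), 1L)
})

test_that("ranks are permutation-invariant and midranks sum to n(n+1)/2", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    pool <- c(2, 8, 34, NA)
    m <- make_milestones(paste0("c", 1:n),
                         sample(pool, n, TRUE), sample(pool, n, TRUE),
                         sample(pool, n, TRUE), sample(pool, n, TRUE))
    r1 <- decay_rank_table(m)
    perm <- sample(n)
    r2 <- decay_rank_table(m[perm, ])
    expect_equal(r1$decay_rank[order(r1$character_id)],
                 r2$decay_rank[order(r2$character_id)])
    expect_equal(sum(r1$decay_rank), n * (n + 1) / 2)
  }
})

test_that("rank dominance: componentwise-earlier milestones rank strictly first", {
  set.seed(7)
  pool <- c(2, 8, 34, 109, NA)
  for (rep in 1:50) {
    a <- sample(pool, 4, TRUE)
    shift <- sample(c(0, 6, 24), 4, TRUE)
    b <- ifelse(is.na(a), NA, a + shift)
    b[sample(4, 1)] <- NA  # worsen one milestone to censored
    af <- ifelse(is.na(a), Inf, a)
    bf <- ifelse(is.na(b), Inf, b)
    if (!(all(af <= bf) && any(af < bf))) next
    m <- make_milestones(c("A", "B"), c(a[1], b[1]), c(a[2], b[2]),
                         c(a[3], b[3]), c(a[4], b[4]))
    r <- decay_rank_table(m)
    expect_lt(r$decay_rank[r$character_id == "A"],
              r$decay_rank[r$character_id == "B"])
  }
})

test_that("decay stages partition days with half-open boundaries", {
  sch <- decay_stage_scheme()
  expect_equal(assign_decay_stage(0), "1")
  expect_equal(assign_decay_stage(5), "2")
  expect_equal(assign_decay_stage(150), "5")
  expect_equal(assign_decay_stage(2), "2")    # shared endpoint goes right
  expect_equal(assign_decay_stage(109), "5")
  expect_equal(assign_decay_stage(500), "5")  # last stage open-ended
  expect_error(assign_decay_stage(-1), "non-negative")
  # no gaps, no overlaps: every day in [0, 400] gets exactly one stage
  days <- seq(0, 400, by = 0.5)
  stages <- assign_decay_stage(days, sch)
  expect_true(all(!is.na(stages)))
  expect_true(all(diff(as.integer(stages)) >= 0))
})
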