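# Suppression engine: equivalence classes, closeness distances, release
# decisions, guarantees, incremental mode.

test_that("equivalence classes partition records by key tuple", {
  expect_identical(partition_equivalence_classes(toy_dataset(0), "gender"),
                   list())
  one <- partition_equivalence_classes(toy_dataset(7), "gender")
  expect_identical(length(one), 1L)
  expect_identical(one[[1]]$size, 7L)

  d <- toy_dataset(5, gender = c("male", "male", "female", "female",
                                 "diverse"))
  cls <- partition_equivalence_classes(d, "gender")
  expect_setequal(vapply(cls, `[[`, integer(1), "size"), c(2L, 2L, 1L))
  expect_error(partition_equivalence_classes(d, character()), "empty")
})

test_that("classes match the pairwise brute-force oracle on random data", {
  keys <- c("age_group", "gender", "quarter_first_diagnosis")
  for (seed in 1:5) {
    d <- random_toy_dataset(120, seed = seed)
    cls <- partition_equivalence_classes(d, keys)
    oracle <- bf_classes(as.data.frame(d), keys)
    got <- lapply(cls, function(cl) sort(match(cl$member_ids, d$case_id)))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
  }
})

test_that("closeness distances follow the stated formulas", {
  p <- c(a = 0.5, b = 0.5)
  expect_identical(closeness_distance(p, p), 0)
  expect_identical(closeness_distance(p, p, ordinal = TRUE), 0)
  # nominal: class all in A vs 50/50 reference -> half-L1 = 0.5
  expect_equal(closeness_distance(c(a = 1, b = 0), p), 0.5)
  # ordinal 3 levels: all mass at the extremes -> 1
  expect_equal(closeness_distance(c(l1 = 1, l2 = 0, l3 = 0),
                                  c(l1 = 0, l2 = 0, l3 = 1),
                                  ordinal = TRUE), 1)
  # distances are symmetric, bounded by 1, zero iff equal
  set.seed(42)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    p <- prop.table(runif(m)); q <- prop.table(runif(m))
    names(p) <- names(q) <- paste0("c", seq_len(m))
    for (ord in c(FALSE, TRUE)) {
      d_pq <- closeness_distance(p, q, ordinal = ord)
      expect_equal(d_pq, closeness_distance(q, p, ordinal = ord))
      expect_true(d_pq > 0 && d_pq <= 1)
      expect_identical(closeness_distance(p, p, ordinal = ord), 0)
    }
    expect_equal(closeness_distance(p, q), sum(abs(p - q)) / 2)
  }
  expect_error(closeness_distance(c(a = 1), c(b = 1)), "same ordered category")
})

test_that("datasets below k are suppressed entirely", {
  d <- toy_dataset(10)
  rel <- anonymize(d, privacy_config(k = 11))
  expect_identical(rel$released_ids, character(0))
  expect_setequal(rel$suppressed_ids, d$case_id)
  expect_true(all(rel$class_decisions$decision == "suppressed_k"))
})

test_that("classes matching the overall sensitive distributions are released", {
  # two classes of 11; sensitive values identically distributed in both
  d <- toy_dataset(22, gender = rep(c("male", "female"), each = 11),
                   patient_status_end_acute = rep(
                     c("dead", rep("discharged", 10)), 2))
  rel <- anonymize(d, privacy_config(k = 11))
  expect_setequal(rel$released_ids, d$case_id)
  expect_true(all(rel$class_decisions$decision == "released"))
})

test_that("an outlying class is suppressed by t-closeness at the hand-computed distance", {
  # 110 records: one class of 11 all dead, nine other classes all discharged
  d <- toy_dataset(110,
                   age_group = rep(c("18-39", "40-59", "60-79", ">=80",
                                     "<=17", "18-39", "40-59", "60-79",
                                     ">=80", "<=17"), each = 11),
                   gender = rep(c("male", "female"), each = 55),
                   patient_status_end_acute = c(rep("dead", 11),
                                                rep("discharged", 99)))
  # overall: 10% dead; the all-dead class has half-L1 = (|1-0.1|+|0-0.9|)/2 = 0.9
  rel <- anonymize(d, privacy_config(k = 11, t = 0.5))
  dec <- rel$class_decisions
  bad <- dec[dec$decision == "suppressed_t", ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$offending_variable, "patient_status_end_acute")
  expect_equal(bad$max_distance, 0.9)
  expect_identical(length(rel$released_ids), 99L)
})

test_that("the t boundary is inclusive: distance exactly t is releasable", {
  # one class of 10 all dead + one class of 10 all discharged:
  # each class is at exactly 0.5 from the 50/50 overall distribution
  d <- toy_dataset(20, gender = rep(c("male", "female"), each = 10),
                   patient_status_end_acute = rep(c("dead", "discharged"),
                                                  each = 10))
  rel <- anonymize(d, privacy_config(k = 10, t = 0.5))
  expect_setequal(rel$released_ids, d$case_id)
})

test_that("release decisions match the brute-force oracle on random instances", {
  keys <- c("age_group", "gender", "quarter_first_diagnosis")
  sens <- c("patient_status_end_acute", "intensive_care")
  cfg <- privacy_config(k = 5, t = 0.3, key_variables = keys,
                        sensitive_variables = sens)
  sizes <- c(50, 80, 120, 160, 200, 75)
  for (seed in seq_along(sizes)) {
    d <- random_toy_dataset(sizes[seed], seed = seed)
    rel <- anonymize(d, cfg)
    oracle <- bf_release_decisions(as.data.frame(d), keys, sens,
                                   k = 5, t = 0.3)
    released_oracle <- sort(unlist(lapply(oracle, function(cl)
      if (cl$decision == "released") d$case_id[cl$members] else character())))
    expect_identical(sort(rel$released_ids), released_oracle)
    # per-class (size, decision) multisets agree
    expect_identical(
      sort(paste(rel$class_decisions$size, rel$class_decisions$decision)),
      sort(vapply(oracle, function(cl)
        paste(length(cl$members), cl$decision), character(1))))
  }
})

test_that("every release satisfies both guarantees under brute-force recheck", {
  cfg <- privacy_config(k = 11, t = 0.5)
  schema <- puf_schema()
  d <- generate_cohort(default_generator_config(n_total = 2500, seed = 13))
  rel <- anonymize(d, cfg)
  pub <- released_data(d, rel)
  cls <- bf_classes(as.data.frame(pub), cfg$key_variables)
  expect_true(all(lengths(cls) >= cfg$k))
  for (cl in cls) {
    for (si in seq_along(cfg$sensitive_variables)) {
      v <- cfg$sensitive_variables[si]
      dd <- bf_distance(pub[[v]][cl], d[[v]], schema[[v]]$categories,
                        isTRUE(cfg$ordinal[[v]]))
      expect_lte(dd, cfg$t)
    }
  }
})

test_that("incremental release is monotone and audits frozen classes", {
  cfg <- privacy_config(k = 11, t = 0.5)
  # step 1: one class of 10 (below k), nothing published
  d1 <- toy_dataset(10)
  r1 <- incremental_release(NULL, d1, cfg)
  expect_identical(r1$released_ids, character(0))
  # step 2: class grows to 11, published in full
  d2 <- toy_dataset(11)
  r2 <- incremental_release(r1, d2, cfg)
  expect_setequal(r2$released_ids, d2$case_id)
  expect_identical(r2$release_index, 2L)
  # no new records: release unchanged
  r3 <- incremental_release(r2, d2, cfg)
  expect_setequal(r3$released_ids, r2$released_ids)
  # superset precondition
  expect_error(incremental_release(r2, d1, cfg), "superset")
})

test_that("a class that drifts out of t is frozen, not retracted", {
  cfg <- privacy_config(k = 5, t = 0.3,
                        key_variables = "gender",
                        sensitive_variables = "patient_status_end_acute")
  # release 1: two balanced classes, everything published
  d1 <- toy_dataset(20, gender = rep(c("male", "female"), each = 10),
                    patient_status_end_acute = rep(c("dead", "discharged"),
                                                   10))
  r1 <- incremental_release(NULL, d1, cfg)
  expect_setequal(r1$released_ids, d1$case_id)
  # release 2: 60 new all-discharged female records shift the reference;
  # the male class (50% dead) is now far from the overall distribution
  d2 <- toy_dataset(80,
                    gender = c(rep(c("male", "female"), each = 10),
                               rep("female", 60)),
                    patient_status_end_acute = c(
                      rep(c("dead", "discharged"), 10),
                      rep("discharged", 60)))
  r2 <- incremental_release(r1, d2, cfg)
  # nothing retracted
  expect_true(all(r1$released_ids %in% r2$released_ids))
  expect_identical(length(r2$frozen_classes), 1L)
  frozen_dec <- r2$class_decisions[r2$class_decisions$decision ==
                                     "released_frozen", ]
  expect_identical(nrow(frozen_dec), 1L)
  # the frozen class publishes only its previously released members
  male_ids <- d2$case_id[d2$gender == "male"]
  expect_setequal(intersect(r2$released_ids, male_ids),
                  intersect(r1$released_ids, male_ids))
})

test_that("a class never reaching k stays unpublished across releases", {
  cfg <- privacy_config(k = 11, t = 0.5, key_variables = "gender",
                        sensitive_variables = "intensive_care")
  prev <- NULL
  for (n_f in c(3, 6, 9)) {
    d <- toy_dataset(20 + n_f,
                     gender = c(rep("male", 20), rep("female", n_f)))
    prev <- incremental_release(prev, d, cfg)
    expect_identical(sum(d$gender[match(prev$released_ids, d$case_id)] ==
                           "female"), 0L)
  }
})

test_that("released fractions never decrease along nested growth prefixes", {
  d <- generate_cohort(default_generator_config(n_total = 2000, seed = 29))
  st_prefixes <- growth_prefixes(d, 400)
  cfg <- privacy_config(k = 11, t = 0.5)
  prev <- NULL
  released_sets <- list()
  for (p in st_prefixes) {
    prev <- incremental_release(prev, p, cfg)
    released_sets[[length(released_sets) + 1L]] <- prev$released_ids
  }
  for (i in seq_len(length(released_sets) - 1))
    expect_true(all(released_sets[[i]] %in% released_sets[[i + 1]]))
  # incremental publishes at least as much as independent per-prefix runs
  for (i in seq_along(st_prefixes)) {
    indep <- anonymize(st_prefixes[[i]], cfg)
    expect_gte(length(released_sets[[i]]), length(indep$released_ids))
  }
})
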