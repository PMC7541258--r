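test_that("mutation classification respects the None < missense < LOF lattice", {
  expect_equal(classify_mutation(character(0)), "None")
  expect_equal(classify_mutation("missense"), "missense")
  expect_equal(classify_mutation(c("missense", "frameshift")), "LOF")
  expect_equal(classify_mutation("splice"), "LOF")
  expect_error(classify_mutation("synonymous"), "unknown mutation event")
  # adding events never lowers the class
  set.seed(71)
  lattice <- c(None = 0, missense = 1, LOF = 2)
  events <- c("missense", "nonsense", "frameshift", "splice")
  for (i in 1:25) {
    e <- sample(events, sample(0:3, 1))
    extra <- sample(events, 1)
    expect_gte(lattice[classify_mutation(c(e, extra))],
               lattice[classify_mutation(e)])
  }
})

test_that("categorical association compares the extreme-median groups", {
  types <- rep(c("N", "C", "M"), c(8, 10, 12))
  expr <- c(stats::rnorm(8, 1), stats::rnorm(10, 5), stats::rnorm(12, 9))
  set.seed(72)
  cohort <- toy_cohort(expr, types = types)
  res <- categorical_association(cohort, "GA", "sample_type")
  expect_equal(res$low_group, "N")
  expect_equal(res$high_group, "M")
  expect_equal(res$n_low, 8)
  expect_equal(res$n_high, 12)
  expect_lt(res$p, 0.01)
  # monotone transforms do not change the rank-sum p
  cohort2 <- toy_cohort(exp(expr), types = types)
  expect_equal(categorical_association(cohort2, "GA", "sample_type")$p, res$p)
})

test_that("groups at or below the size threshold are dropped", {
  # a group of exactly 5 is excluded (strict '>')
  types <- rep(c("N", "C", "M"), c(5, 10, 12))
  cohort <- toy_cohort(seq_along(types), types = types)
  res <- categorical_association(cohort, "GA", "sample_type")
  expect_true(res$low_group %in% c("C", "M"))
  expect_false("N" %in% c(res$low_group, res$high_group))
  # dropping to fewer than 2 groups gives an undefined result with a reason
  types2 <- rep(c("N", "C"), c(5, 10))
  cohort2 <- toy_cohort(seq_along(types2), types = types2)
  res2 <- categorical_association(cohort2, "GA", "sample_type")
  expect_true(is.na(res2$p))
  expect_match(res2$reason, "fewer than 2 groups")
})

test_that("exchangeable groups are not significant", {
  types <- rep(c("A", "B"), each = 6)
  cohort <- toy_cohort(rep(c(1, 2, 3, 4, 5, 6), 2), types = types)
  expect_equal(categorical_association(cohort, "GA", "sample_type")$p, 1)
})

test_that("mutation association reproduces the exact enumeration example", {
  mut <- data.frame(sample_idx = 1:3, gene = "MUT", event = "missense",
                    stringsAsFactors = FALSE)
  cohort <- toy_cohort(c(10, 12, 14, 1, 2, 3), mutations = mut)
  res <- mutation_association(cohort, "GA", "MUT", alpha = 0.1)
  expect_equal(nrow(res), 1)  # no LOF samples -> class omitted
  expect_equal(res$class, "missense")
  expect_equal(res$n, 3)
  expect_equal(res$p, 2 / 20)
  expect_equal(res$delta_median, 12 - 2)
  expect_equal(res$direction, "higher")
  expect_false(res$selected)  # strict p < alpha at p == alpha
  # every sample mutated -> no None group
  mut_all <- data.frame(sample_idx = 1:6, gene = "MUT", event = "missense",
                        stringsAsFactors = FALSE)
  cohort_all <- toy_cohort(1:6, mutations = mut_all)
  expect_error(mutation_association(cohort_all, "GA", "MUT"), "None group")
})

test_that("combined mutation grouping excludes LOF-only samples from both groups", {
  mut <- data.frame(
    sample_idx = c(1, 2, 3, 6, 6),
    gene = c("A", "B", "A", "A", "B"),
    event = c("missense", "missense", "nonsense", "frameshift", "missense"),
    stringsAsFactors = FALSE)
  cohort <- toy_cohort(c(5, 6, 7, 1, 2, 8), mutations = mut)
  res <- combined_mutation_test(cohort, "GA", c("A", "B"))
  # samples 1, 2 and 6 carry a missense class; 4 and 5 are fully unmutated;
  # sample 3 is LOF-only and falls in neither group
  expect_equal(res$n_mut, 3)
  expect_equal(res$n_none, 2)
  expect_equal(res$p, enumerate_ranksum_p(c(5, 6, 8), c(1, 2)))
  # a gene set with no mutated samples leaves the missense group empty
  res2 <- combined_mutation_test(cohort, "GA", "ZZZ")
  expect_true(is.na(res2$p))
  expect_equal(res2$n_mut, 0)
  expect_error(combined_mutation_test(cohort, "GA", character(0)), "nonempty")
})

test_that("numerical association recovers monotone relationships", {
  cohort <- toy_cohort(1:10, numerical = (1:10)^2)
  res <- numerical_association(cohort, "GA", "feat")
  expect_equal(res$rho, 1)
  cohort2 <- toy_cohort(1:10, numerical = -(1:10)^3)
  expect_equal(numerical_association(cohort2, "GA", "feat")$rho, -1)
  cohort3 <- toy_cohort(1:3, numerical = c(1, 2, 3))
  expect_error(numerical_association(cohort3, "GA", "feat"), "at least 4")
})

test_that("percentile survival split sizes follow the strict threshold", {
  cohort <- toy_cohort(1:10, os_time = rep(c(2, 4), 5),
                       os_event = rep(1L, 10))
  res <- survival_split_logrank(cohort, "GA", percentile = 80)
  expect_equal(res$n_high, 2)
  expect_equal(res$n_low, 8)
  # no events -> undefined with reason
  res2 <- survival_split_logrank(
    toy_cohort(1:10, os_time = rep(5, 10), os_event = rep(0L, 10)), "GA")
  expect_true(is.na(res2$p))
  expect_match(res2$reason, "no events")
})

test_that("identical event-time multisets in both groups give a null log-rank", {
  # median split of 8 samples; both groups have event times 1..4
  cohort <- toy_cohort(c(1, 2, 3, 4, 11, 12, 13, 14),
                       os_time = c(1, 2, 3, 4, 1, 2, 3, 4),
                       os_event = rep(1L, 8))
  res <- survival_split_logrank(cohort, "GA", percentile = 50)
  expect_equal(res$n_high, 4)
  expect_equal(res$chi_sq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("log-rank chi-square matches the independent O-E tabulation", {
  set.seed(73)
  for (rep in 1:5) {
    x <- stats::rnorm(12)
    time <- round(stats::rexp(12, 0.2), 3)
    event <- stats::rbinom(12, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1L
    cohort <- toy_cohort(x, os_time = time, os_event = as.integer(event))
    res <- survival_split_logrank(cohort, "GA", percentile = 60)
    thr <- stats::quantile(x, 0.6, type = 7, names = FALSE)
    oracle <- logrank_chisq_oracle(time, event, x > thr)
    expect_equal(res$chi_sq, oracle, tolerance = 1e-8)
    expect_equal(res$p, stats::pchisq(oracle, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("the mutation report adds a labelled BH column without changing selection", {
  set.seed(74)
  mut <- data.frame(sample_idx = c(1:4, 5:8), gene = rep(c("A", "B"), each = 4),
                    event = "missense", stringsAsFactors = FALSE)
  cohort <- toy_cohort(stats::rnorm(20), mutations = mut)
  rep_tab <- mutation_association_report(cohort, "GA", c("A", "B"))
  expect_equal(nrow(rep_tab), 2)
  expect_true(all(c("p", "p_bh", "selected") %in% names(rep_tab)))
  expect_equal(rep_tab$selected, rep_tab$p < 0.1)
  expect_true(all(rep_tab$p_bh >= rep_tab$p))
})

test_that("the association battery returns every table on a simulated cohort", {
  cfg <- sim_config(n_mrs = 20, n_genes = 400, regulon_size_range = c(5, 10),
                    pair_regulon_size = 20, pair_common_size = 12,
                    n_active_up = 4, n_active_down = 2, seed = 5)
  sim <- simulate_interactome(cfg)
  cohort <- simulate_expression_cohort(cfg, sim$truth)
  genes <- rownames(cohort$expression)
  bat <- association_battery(cohort, genes)
  expect_equal(nrow(bat$categorical), 2)
  expect_equal(nrow(bat$numerical), 2)
  expect_equal(nrow(bat$survival), 2)
  expect_true(all(bat$mutation$class %in% c("missense", "LOF")))
  # sample types are planted N < C < M for the designated genes
  expect_equal(bat$categorical$low_group, c("N", "N"))
  expect_equal(bat$categorical$high_group, c("M", "M"))
})

test_that("two-gene group report recovers the planted contrasts", {
  set.seed(75)
  n <- 60
  types <- rep(c("N", "C", "M"), each = 20)
  mu <- rep(c(0, 2, 4), each = 20)
  a <- mu + stats::rnorm(n, 0, 0.5)
  b <- mu + 0.8 * (a - mu) + stats::rnorm(n, 0, 0.3)
  cohort <- toy_cohort(a, expr_b = b, types = types)
  rep2 <- expression_group_report(cohort, "GA", "GB")
  expect_gt(rep2$pearson_r, 0.9)
  expect_equal(nrow(rep2$group_tests), 4)
  expect_true(all(rep2$group_tests$p < 0.01))
})
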