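small_cfg <- function(...) {
  sim_config(n_mrs = 60, n_genes = 1500, regulon_size_range = c(10, 25),
             pair_regulon_size = 60, pair_common_size = 12, ...)
}

test_that("generators are pure functions of the configuration", {
  cfg <- small_cfg(seed = 9)
  a <- simulate_interactome(cfg)
  b <- simulate_interactome(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  sa <- simulate_de_datasets(a$network, a$truth, cfg)
  sb <- simulate_de_datasets(b$network, b$truth, cfg)
  expect_identical(sa, sb)
  ca <- simulate_expression_cohort(cfg, a$truth)
  cb <- simulate_expression_cohort(cfg, b$truth)
  expect_identical(ca, cb)
  # different seeds give different data
  other <- simulate_interactome(small_cfg(seed = 10))
  expect_false(identical(other$network, a$network))
  s_other <- simulate_de_datasets(a$network, a$truth, small_cfg(seed = 10))
  expect_false(identical(s_other, sa))
})

test_that("named substreams isolate the generators from each other", {
  cfg1 <- small_cfg(seed = 9)
  cfg2 <- small_cfg(seed = 9, n_N = 50, n_missense = 10)
  n1 <- simulate_interactome(cfg1)
  n2 <- simulate_interactome(cfg2)
  # changing cohort-only settings does not perturb the network
  expect_identical(as.data.frame(n1$network), as.data.frame(n2$network))
  expect_identical(simulate_de_datasets(n1$network, n1$truth, cfg1),
                   simulate_de_datasets(n2$network, n2$truth, cfg2))
})

test_that("edge attributes match the configured distributions", {
  cfg <- sim_config(n_mrs = 300, n_genes = 5000,
                    regulon_size_range = c(30, 60), seed = 3)
  net <- simulate_interactome(cfg)$network
  expect_gt(nrow(net), 9000)
  expect_true(all(abs(net$mor) >= 0.3 & abs(net$mor) <= 1))
  expect_true(all(net$likelihood > 0.1 & net$likelihood <= 1))
  # positive-MOR fraction within 2 points of the configured 70%
  expect_lt(abs(mean(net$mor > 0) - 0.7), 0.02)
  # regulon sizes inside the configured range (the pair is configured larger)
  sizes <- table(net$regulator)
  expect_true(all(sizes >= 30 & sizes <= 60 | sizes == 60))
})

test_that("the designated pair is eligible with positively shared targets", {
  cfg <- small_cfg(seed = 21)
  sim <- simulate_interactome(cfg)
  pair <- sim$truth$synergistic_pair
  part <- partition_regulons(sim$network, pair$mr1, pair$mr2)
  expect_equal(nrow(part$common), cfg$pair_common_size)
  expect_true(eligible_pair(part$size1, part$size2, nrow(part$common)))
  expect_true(all(part$common$mor1 > 0))
  expect_true(all(part$common$mor2 > 0))
  # pair members are planted activated MRs
  expect_true(all(c(pair$mr1, pair$mr2) %in%
                    names(sim$truth$active_mrs[sim$truth$active_mrs > 0])))
})

test_that("zero planted effects give pure-noise signatures", {
  cfg <- small_cfg(seed = 13, effect_size = 0, mr_self_de = 0,
                   pair_extra_effect = 0)
  sim <- simulate_interactome(cfg)
  sigs <- simulate_de_datasets(sim$network, sim$truth, cfg)
  pooled <- unlist(lapply(sigs, function(s) s$scores))
  expect_lt(abs(mean(pooled)), 0.05)
  expect_lt(abs(stats::sd(pooled) - 1), 0.05)
  # independent across datasets
  expect_lt(abs(stats::cor(sigs[[1]]$scores, sigs[[2]]$scores)), 0.1)
})

test_that("planted MR effects surface in their targets and own gene", {
  cfg <- small_cfg(seed = 29)
  sim <- simulate_interactome(cfg)
  sigs <- simulate_de_datasets(sim$network, sim$truth, cfg)
  up <- names(sim$truth$active_mrs[sim$truth$active_mrs > 0])
  dn <- names(sim$truth$active_mrs[sim$truth$active_mrs < 0])
  s <- sigs[[1]]$scores
  # the MR's own gene is shifted past the consistency threshold
  expect_true(all(s[up] > 3 - 4 * cfg$dataset_noise_sd))
  expect_gt(mean(s[up]), 4)
  expect_lt(mean(s[dn]), -4)
})

test_that("cohort structure carries the planted clinical signal", {
  cfg <- small_cfg(seed = 17, n_N = 200, n_C = 40, n_M = 40)
  sim <- simulate_interactome(cfg)
  cohort <- simulate_expression_cohort(cfg, sim$truth)
  ga <- sim$truth$planted_correlation$gene_a
  gb <- sim$truth$planted_correlation$gene_b
  types <- cohort$categorical$sample_type
  xa <- cohort$expression[ga, ]
  # group means ordered N < C < M
  expect_lt(mean(xa[types == "N"]), mean(xa[types == "C"]))
  expect_lt(mean(xa[types == "C"]), mean(xa[types == "M"]))
  # planted within-group correlation on the unmutated normal samples
  unmut <- setdiff(cohort$samples, unique(cohort$mutations$sample))
  cell <- intersect(cohort$samples[types == "N"], unmut)
  r_hat <- stats::cor(cohort$expression[ga, cell], cohort$expression[gb, cell])
  expect_lt(abs(r_hat - cfg$planted_correlation), 0.15)
  # mutation class counts follow the configuration
  cls <- mutation_classes(cohort, names(sim$truth$mutation_effects)[1])
  expect_equal(sum(cls == "missense"), cfg$n_missense)
  expect_equal(sum(cls == "LOF"), cfg$n_lof)
  # survival fields are complete and consistent
  expect_equal(length(cohort$os_time), length(cohort$samples))
  expect_true(all(cohort$os_time >= 0))
  expect_true(all(cohort$os_event %in% 0:1))
})

test_that("generated artifacts satisfy the consuming validators for random configs", {
  set.seed(99)
  for (i in 1:5) {
    cfg <- sim_config(n_mrs = sample(20:50, 1), n_genes = sample(800:1500, 1),
                      regulon_size_range = sort(sample(5:30, 2)),
                      pair_regulon_size = 40, pair_common_size = 11,
                      n_active_up = 5, n_active_down = 2,
                      n_N = sample(10:40, 1), n_C = 20, n_M = 20,
                      seed = i)
    sim <- simulate_interactome(cfg)
    expect_s3_class(sim$network, "regulatory_network")  # constructor validates
    sigs <- simulate_de_datasets(sim$network, sim$truth, cfg)
    expect_true(all(vapply(sigs, function(s) all(is.finite(s$scores)),
                           logical(1))))
    cohort <- simulate_expression_cohort(cfg, sim$truth)
    expect_s3_class(cohort, "cohort_table")
  }
  expect_error(sim_config(pair_regulon_size = 200, pair_common_size = 12,
                          n_genes = 1000, n_mrs = 50),
               "eligib|universe")
})

test_that("bundles are byte-identical across reruns", {
  cfg <- small_cfg(seed = 33)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  }
  # the bundle reloads into equivalent objects
  net <- read_interactome(file.path(d1, "interactome.tsv"))
  expect_equal(nrow(net), sum(table(net$regulator)))
  cohort <- read_cohort(file.path(d1, "cohort"))
  expect_equal(length(cohort$samples), cfg$n_N + cfg$n_C + cfg$n_M)
})
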