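#' Derive a named substream seed from a master seed
#'
#' Each generator draws from its own substream so that, e.g., changing the
#' cohort size never perturbs the simulated network. The substream seed is a
#' deterministic 31-bit hash of the master seed and the stream name.
#'
#' @param seed master integer seed.
#' @param name stream name.
#' @return integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  m <- 2147483647
  val <- as.double(seed %% m)
  for (c in utf8ToInt(name)) {
    val <- (val * 31 + c) %% m
  }
  as.integer(val)
}

#' Configuration of the synthetic-data generators
#'
#' Defaults encode the benchmark conditions the pipeline is designed for:
#' 5000 regulators over 20000 genes with ARACNe-like regulon sizes (uniform
#' 50-150 targets), 18 planted activated and 3 planted suppressed MRs with
#' activity effect size 2, a designated synergistic pair sharing a block of
#' 12 positively-regulated common targets with an extra DE boost, 5 discovery
#' plus 5 validation datasets with unit noise, and a 90-sample cohort (30
#' normal / 30 tumour / 30 metastatic) with a planted expression correlation
#' of 0.8 between the pair genes, a +2 mutation-linked expression shift and
#' survival tied to expression.
#'
#' @param n_mrs number of regulators.
#' @param n_genes size of the gene universe (regulators are the first
#'   `n_mrs` genes).
#' @param regulon_size_range integer range of regulon sizes (uniform).
#' @param mor_positive_fraction fraction of positive-MOR edges.
#' @param n_active_up,n_active_down numbers of planted activated/suppressed
#'   MRs.
#' @param effect_size activity effect of planted MRs (signed by direction).
#' @param mr_self_de DE shift applied to a planted MR's own gene (its sign
#'   follows the MR's direction); kept well above the consistency threshold
#'   of 3.
#' @param pair_regulon_size regulon size of each designated pair MR.
#' @param pair_common_size number of shared targets of the pair (must pass
#'   [eligible_pair()] at the default thresholds).
#' @param pair_extra_effect additional DE effect on the pair's common
#'   targets.
#' @param n_discovery,n_validation numbers of simulated datasets.
#' @param dataset_noise_sd per-dataset gene noise standard deviation.
#' @param n_N,n_C,n_M cohort group sizes (normal / tumour / metastatic).
#' @param group_mean_step expression mean increment per group (N, C, M get
#'   0, 1, 2 steps).
#' @param planted_correlation within-group expression correlation of the
#'   designated gene pair.
#' @param within_group_sd within-group expression standard deviation.
#' @param mutation_shift expression shift of mutated samples for the planted
#'   mutated gene.
#' @param n_missense,n_lof numbers of samples given missense / LOF mutations.
#' @param survival_hazard_ratio hazard multiplier for the top-20% expression
#'   group.
#' @param baseline_hazard exponential baseline hazard of survival times.
#' @param censor_time administrative censoring time.
#' @param seed master integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_mrs = 5000L, n_genes = 20000L,
                       regulon_size_range = c(50L, 150L),
                       mor_positive_fraction = 0.7,
                       n_active_up = 18L, n_active_down = 3L,
                       effect_size = 2,
                       mr_self_de = 6,
                       pair_regulon_size = 60L, pair_common_size = 12L,
                       pair_extra_effect = 1,
                       n_discovery = 5L, n_validation = 5L,
                       dataset_noise_sd = 1,
                       n_N = 30L, n_C = 30L, n_M = 30L,
                       group_mean_step = 1,
                       planted_correlation = 0.8,
                       within_group_sd = 1,
                       mutation_shift = 2, n_missense = 30L, n_lof = 5L,
                       survival_hazard_ratio = 2,
                       baseline_hazard = 0.1, censor_time = 15,
                       seed = 1L) {
  cfg <- list(n_mrs = as.integer(n_mrs), n_genes = as.integer(n_genes),
              regulon_size_range = as.integer(regulon_size_range),
              mor_positive_fraction = mor_positive_fraction,
              n_active_up = as.integer(n_active_up),
              n_active_down = as.integer(n_active_down),
              effect_size = effect_size, mr_self_de = mr_self_de,
              pair_regulon_size = as.integer(pair_regulon_size),
              pair_common_size = as.integer(pair_common_size),
              pair_extra_effect = pair_extra_effect,
              n_discovery = as.integer(n_discovery),
              n_validation = as.integer(n_validation),
              dataset_noise_sd = dataset_noise_sd,
              n_N = as.integer(n_N), n_C = as.integer(n_C),
              n_M = as.integer(n_M),
              group_mean_step = group_mean_step,
              planted_correlation = planted_correlation,
              within_group_sd = within_group_sd,
              mutation_shift = mutation_shift,
              n_missense = as.integer(n_missense), n_lof = as.integer(n_lof),
              survival_hazard_ratio = survival_hazard_ratio,
              baseline_hazard = baseline_hazard, censor_time = censor_time,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_mrs >= 2L, n_genes >= n_mrs,
              length(regulon_size_range) == 2L,
              regulon_size_range[1L] >= 2L,
              regulon_size_range[1L] <= regulon_size_range[2L],
              mor_positive_fraction >= 0, mor_positive_fraction <= 1,
              n_active_up + n_active_down <= n_mrs,
              n_active_up >= 2L,
              pair_common_size >= 1L,
              pair_common_size < pair_regulon_size,
              n_discovery >= 2L, n_validation >= 1L,
              dataset_noise_sd > 0,
              n_N >= 2L, n_C >= 2L, n_M >= 2L,
              abs(planted_correlation) < 1,
              within_group_sd > 0,
              survival_hazard_ratio > 0, baseline_hazard > 0,
              censor_time > 0)
  })
  if (cfg$n_genes < cfg$regulon_size_range[2L] + 2L ||
      cfg$n_genes < cfg$pair_common_size +
        2L * (cfg$pair_regulon_size - cfg$pair_common_size) + 2L) {
    stop("infeasible config: gene universe too small for the regulon sizes")
  }
  if (!eligible_pair(cfg$pair_regulon_size, cfg$pair_regulon_size,
                     cfg$pair_common_size)) {
    stop("infeasible config: designated pair would not pass eligibility")
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(n_genes) sprintf("g%05d", seq_len(n_genes))

#' Simulate a regulon interactome with planted truth
#'
#' Regulators are the first `n_mrs` genes of the universe. Regulon sizes are
#' uniform over `regulon_size_range`; MOR signs are positive with the
#' configured fraction and magnitudes uniform on (0.3, 1); likelihood weights
#' are uniform on (0.1, 1). A designated pair of activated MRs shares a
#' common-target block sized to pass [eligible_pair()], with positive MORs on
#' the common targets for both MRs and disjoint unique targets.
#'
#' @param cfg a [sim_config].
#' @return list with `network` (a [regulatory_network]) and `truth` (class
#'   `sim_truth`): `active_mrs` (named signed effects), `synergistic_pair`
#'   (`mr1`, `mr2`, `extra_effect`), `planted_correlation` (`gene_a`,
#'   `gene_b`, `r`), `mutation_effects` (named shifts), `survival_hazard_ratio`
#'   and `seed`.
#' @export
simulate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "network"))
  genes <- sim_gene_ids(cfg$n_genes)
  n <- cfg$n_mrs
  sizes <- sample(seq.int(cfg$regulon_size_range[1L],
                          cfg$regulon_size_range[2L]),
                  n, replace = TRUE)
  act_idx <- sample.int(n, cfg$n_active_up + cfg$n_active_down)
  up_idx <- act_idx[seq_len(cfg$n_active_up)]
  down_idx <- act_idx[cfg$n_active_up + seq_len(cfg$n_active_down)]
  p1 <- up_idx[1L]
  p2 <- up_idx[2L]
  sizes[c(p1, p2)] <- cfg$pair_regulon_size
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == p1 || i == p2) next
    ti <- sample.int(cfg$n_genes - 1L, sizes[i])
    ti[ti >= i] <- ti[ti >= i] + 1L
    targets[[i]] <- ti
  }
  # designated pair: shared common block, disjoint unique blocks
  pool <- sample(setdiff(seq_len(cfg$n_genes), c(p1, p2)))
  n_uniq <- cfg$pair_regulon_size - cfg$pair_common_size
  common_idx <- pool[seq_len(cfg$pair_common_size)]
  u1_idx <- pool[cfg$pair_common_size + seq_len(n_uniq)]
  u2_idx <- pool[cfg$pair_common_size + n_uniq + seq_len(n_uniq)]
  targets[[p1]] <- c(common_idx, u1_idx)
  targets[[p2]] <- c(common_idx, u2_idx)
  reg_idx <- rep.int(seq_len(n), lengths(targets))
  tar_idx <- unlist(targets)
  n_edges <- length(tar_idx)
  mor_sign <- ifelse(stats::runif(n_edges) < cfg$mor_positive_fraction, 1, -1)
  mor <- mor_sign * stats::runif(n_edges, 0.3, 1)
  lik <- stats::runif(n_edges, 0.1, 1)
  # common targets of the pair are positively regulated by both MRs
  pair_common_edge <- (reg_idx == p1 | reg_idx == p2) &
    tar_idx %in% common_idx
  mor[pair_common_edge] <- abs(mor[pair_common_edge])
  net <- regulatory_network(data.frame(
    regulator = genes[reg_idx], target = genes[tar_idx],
    mor = mor, likelihood = lik, stringsAsFactors = FALSE))
  effects <- c(stats::setNames(rep(cfg$effect_size, cfg$n_active_up),
                               genes[up_idx]),
               stats::setNames(rep(-cfg$effect_size, cfg$n_active_down),
                               genes[down_idx]))
  truth <- structure(list(
    active_mrs = effects,
    synergistic_pair = list(mr1 = genes[p1], mr2 = genes[p2],
                            extra_effect = cfg$pair_extra_effect),
    planted_correlation = list(gene_a = genes[p1], gene_b = genes[p2],
                               r = cfg$planted_correlation),
    mutation_effects = stats::setNames(cfg$mutation_shift,
                                       genes[cfg$n_genes]),
    survival_hazard_ratio = cfg$survival_hazard_ratio,
    seed = cfg$seed), class = "sim_truth")
  list(network = net, truth = truth)
}

#' Simulate DE signatures with shared planted biology
#'
#' Builds a per-gene effect vector -- each planted MR adds
#' `effect * mor * likelihood` to its targets, the pair's common targets gain
#' an extra `extra_effect * mean(mor1, mor2)`, and each planted MR's own gene
#' is shifted by `mr_self_de` in its activity direction -- then draws each
#' dataset as `effects + N(0, dataset_noise_sd)` noise, independently per
#' dataset and gene. Discovery datasets are labelled `D1..`, validation
#' `V1..`.
#'
#' @param net simulated [regulatory_network].
#' @param truth matching `sim_truth`.
#' @param cfg the [sim_config] used to build them.
#' @return named list of [de_signature]s (discovery first).
#' @export
simulate_de_datasets <- function(net, truth, cfg) {
  stopifnot(inherits(net, "regulatory_network"),
            inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "signatures"))
  genes <- sim_gene_ids(cfg$n_genes)
  effects <- stats::setNames(numeric(cfg$n_genes), genes)
  for (mr in names(truth$active_mrs)) {
    d <- truth$active_mrs[[mr]]
    idx <- net$regulator == mr
    add <- d * net$mor[idx] * net$likelihood[idx]
    tg <- net$target[idx]
    effects[tg] <- effects[tg] + add
  }
  part <- partition_regulons(net, truth$synergistic_pair$mr1,
                             truth$synergistic_pair$mr2)
  extra <- truth$synergistic_pair$extra_effect *
    (part$common$mor1 + part$common$mor2) / 2
  effects[part$common$target] <- effects[part$common$target] + extra
  self_shift <- sign(truth$active_mrs) * cfg$mr_self_de
  effects[names(truth$active_mrs)] <-
    effects[names(truth$active_mrs)] + self_shift
  ids <- c(paste0("D", seq_len(cfg$n_discovery)),
           paste0("V", seq_len(cfg$n_validation)))
  platforms <- c(rep("microarray", cfg$n_discovery),
                 rep("rnaseq", cfg$n_validation))
  sigs <- vector("list", length(ids))
  names(sigs) <- ids
  for (j in seq_along(ids)) {
    scores <- effects + stats::rnorm(cfg$n_genes, 0, cfg$dataset_noise_sd)
    sigs[[j]] <- de_signature(ids[j], platforms[j], scores)
  }
  sigs
}

#' Simulate an expression cohort with planted clinical structure
#'
#' Generates normal (N), tumour (C) and metastatic (M) groups whose means for
#' the two designated genes increase N < C < M by `group_mean_step`; within
#' groups the two genes are bivariate normal with the planted correlation.
#' The planted mutated gene receives missense and LOF mutation events
#' assigned uniformly across samples, and mutated samples' expression of both
#' designated genes is shifted by the planted effect. Survival times are
#' exponential, with the hazard multiplied by `survival_hazard_ratio` for
#' samples in the top 20% of the first designated gene's expression, and
#' administratively censored at `censor_time`. A `covariate_1` numerical
#' feature is drawn independently of expression.
#'
#' @param cfg a [sim_config].
#' @param truth matching `sim_truth` (from [simulate_interactome()]).
#' @return a [cohort_table].
#' @export
simulate_expression_cohort <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(substream_seed(cfg$seed, "cohort"))
  n <- cfg$n_N + cfg$n_C + cfg$n_M
  samples <- sprintf("S%04d", seq_len(n))
  type <- rep(c("N", "C", "M"), times = c(cfg$n_N, cfg$n_C, cfg$n_M))
  ga <- truth$planted_correlation$gene_a
  gb <- truth$planted_correlation$gene_b
  r <- truth$planted_correlation$r
  za <- stats::rnorm(n)
  zb <- r * za + sqrt(1 - r^2) * stats::rnorm(n)
  mu <- (match(type, c("N", "C", "M")) - 1L) * cfg$group_mean_step
  xa <- mu + cfg$within_group_sd * za
  xb <- mu + cfg$within_group_sd * zb
  # mutation events, uniform over samples; mutated samples shifted
  mut_rows <- list()
  mutated <- logical(n)
  for (mg in names(truth$mutation_effects)) {
    pick <- sample.int(n, cfg$n_missense + cfg$n_lof)
    mis <- pick[seq_len(cfg$n_missense)]
    lof <- pick[cfg$n_missense + seq_len(cfg$n_lof)]
    mut_rows[[length(mut_rows) + 1L]] <- data.frame(
      sample = samples[mis], gene = mg, event = "missense",
      stringsAsFactors = FALSE)
    if (cfg$n_lof > 0L) {
      lof_event <- sample(.lof_events, cfg$n_lof, replace = TRUE)
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        sample = samples[lof], gene = mg, event = lof_event,
        stringsAsFactors = FALSE)
      # some LOF samples also carry a missense event (classified LOF)
      also_mis <- lof[stats::runif(cfg$n_lof) < 0.5]
      if (length(also_mis) > 0L) {
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          sample = samples[also_mis], gene = mg, event = "missense",
          stringsAsFactors = FALSE)
      }
    }
    shift <- truth$mutation_effects[[mg]]
    xa[pick] <- xa[pick] + shift
    xb[pick] <- xb[pick] + shift
    mutated[pick] <- TRUE
  }
  mutations <- if (length(mut_rows) > 0L) {
    do.call(rbind, mut_rows)
  } else {
    NULL
  }
  expr <- rbind(xa, xb)
  rownames(expr) <- c(ga, gb)
  colnames(expr) <- samples
  # survival tied to the first designated gene's expression
  thr <- stats::quantile(xa, 0.8, type = 7, names = FALSE)
  hr <- ifelse(xa > thr, truth$survival_hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = cfg$baseline_hazard * hr)
  os_time <- pmin(t_event, cfg$censor_time)
  os_event <- as.integer(t_event <= cfg$censor_time)
  covariate <- stats::rnorm(n)
  cohort_table(expr,
               categorical = data.frame(sample = samples, sample_type = type,
                                        stringsAsFactors = FALSE),
               numerical = data.frame(sample = samples,
                                      covariate_1 = covariate,
                                      stringsAsFactors = FALSE),
               mutations = mutations,
               os_time = stats::setNames(os_time, samples),
               os_event = stats::setNames(os_event, samples))
}

#' Write a full synthetic input bundle to a directory
#'
#' Simulates the interactome, the DE datasets and the cohort, and writes
#' `interactome.tsv`, `signatures/<id>.tsv`, `cohort/` (see [write_cohort()]),
#' `truth.json` and `config.yaml`. Identical configurations give
#' byte-identical bundles.
#'
#' @param cfg a [sim_config].
#' @param dir output directory (created if absent).
#' @return invisible list with the generated objects and file paths.
#' @export
simulate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_interactome(cfg)
  sigs <- simulate_de_datasets(sim$network, sim$truth, cfg)
  cohort <- simulate_expression_cohort(cfg, sim$truth)
  write_interactome(sim$network, file.path(dir, "interactome.tsv"))
  dir.create(file.path(dir, "signatures"), showWarnings = FALSE)
  sig_paths <- vapply(sigs, function(s) {
    p <- file.path(dir, "signatures", paste0(s$dataset_id, ".tsv"))
    write_de_signature(s, p)
    p
  }, character(1))
  write_cohort(cohort, file.path(dir, "cohort"))
  truth_json <- list(
    active_mrs = as.list(sim$truth$active_mrs),
    synergistic_pair = sim$truth$synergistic_pair,
    planted_correlation = sim$truth$planted_correlation,
    mutation_effects = as.list(sim$truth$mutation_effects),
    survival_hazard_ratio = sim$truth$survival_hazard_ratio,
    seed = sim$truth$seed)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(list(network = sim$network, truth = sim$truth,
                 signatures = sigs, cohort = cohort,
                 paths = list(interactome = file.path(dir, "interactome.tsv"),
                              signatures = sig_paths,
                              cohort = file.path(dir, "cohort"),
                              truth = file.path(dir, "truth.json"),
                              config = file.path(dir, "config.yaml"))))
}
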