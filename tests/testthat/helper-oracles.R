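# Independent oracles used to cross-check the package's statistics.

# Exact rank-sum p by enumeration of all group assignments (tie-free input).
enumerate_ranksum_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(pooled), nx)
  sums <- colSums(matrix(r[sets], nrow = nx))
  p_ge <- mean(sums >= w_obs - 1e-9)
  p_le <- mean(sums <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# All ordered k-tuples of distinct values from 1..n (rows of a matrix).
ordered_tuples <- function(n, k) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  keep <- rep(TRUE, nrow(grid))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        keep <- keep & grid[, i] != grid[, j]
      }
    }
  }
  grid[keep, , drop = FALSE]
}

# Brute-force permutation p of the weighted NES: all assignments of k of the
# n signature genes' z-scores to the regulon's targets.
permutation_nes_p <- function(z, a) {
  k <- length(a)
  tuples <- ordered_tuples(length(z), k)
  nes_all <- (matrix(z[tuples], nrow = nrow(tuples)) %*% a) / sqrt(sum(a^2))
  function(nes_obs) mean(abs(nes_all) >= abs(nes_obs) - 1e-12)
}

# Independent two-group log-rank chi-square via the O-E-V tabulation.
logrank_chisq_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- group == unique(group)[1L]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o_minus_e^2 / v
}

# Small deterministic interactome used across tests.
toy_network <- function() {
  regulatory_network(data.frame(
    regulator = c("A", "A", "A", "B", "B", "B", "C", "C"),
    target = c("g1", "g2", "g3", "g2", "g3", "g4", "g5", "g6"),
    mor = c(1, -0.5, 0.8, 1, 0.6, -0.9, 1, 1),
    likelihood = c(0.9, 0.8, 0.5, 0.7, 0.4, 0.6, 0.5, 0.5),
    stringsAsFactors = FALSE))
}

toy_signature <- function(id = "T1", scores = NULL) {
  if (is.null(scores)) {
    scores <- stats::setNames(c(2.5, -1.0, 0.5, -3.0, 1.5, 0.2, -0.7, 4.0),
                              c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"))
  }
  de_signature(id, "microarray", scores)
}

random_network <- function(n_mrs, n_genes, size_range, seed) {
  set.seed(seed)
  genes <- sprintf("t%04d", seq_len(n_genes))
  mrs <- sprintf("R%03d", seq_len(n_mrs))
  rows <- lapply(seq_len(n_mrs), function(i) {
    k <- sample(size_range[1]:size_range[2], 1)
    data.frame(regulator = mrs[i], target = sample(genes, k),
               mor = stats::runif(k, -1, 1),
               likelihood = stats::runif(k, 0.1, 1),
               stringsAsFactors = FALSE)
  })
  regulatory_network(do.call(rbind, rows))
}

# Cohort with explicit pieces; defaults give three sample-type groups.
toy_cohort <- function(expr_a, expr_b = NULL, types = NULL, mutations = NULL,
                       os_time = NULL, os_event = NULL, numerical = NULL) {
  n <- length(expr_a)
  samples <- sprintf("P%03d", seq_len(n))
  expr <- rbind(GA = expr_a,
                GB = if (is.null(expr_b)) rev(expr_a) else expr_b)
  colnames(expr) <- samples
  categorical <- data.frame(sample = samples,
                            sample_type = if (is.null(types))
                              rep("C", n) else types,
                            stringsAsFactors = FALSE)
  if (!is.null(mutations)) {
    mutations$sample <- samples[mutations$sample_idx]
    mutations <- mutations[c("sample", "gene", "event")]
  }
  num_df <- data.frame(sample = samples, stringsAsFactors = FALSE)
  if (!is.null(numerical)) num_df$feat <- numerical
  cohort_table(expr, categorical = categorical, numerical = num_df,
               mutations = mutations,
               os_time = if (is.null(os_time)) NULL else
                 stats::setNames(os_time, samples),
               os_event = if (is.null(os_event)) NULL else
                 stats::setNames(os_event, samples))
}
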