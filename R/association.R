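.mutation_events <- c("missense", "nonsense", "frameshift", "splice")
.lof_events <- c("nonsense", "frameshift", "splice")

#' Sample cohort container
#'
#' Bundles per-sample expression, categorical and numerical features, somatic
#' mutation events and overall-survival data for the clinical association
#' battery.
#'
#' @param expression numeric matrix, genes x samples (column names are sample
#'   ids).
#' @param categorical data.frame of categorical features with a `sample`
#'   column; optional.
#' @param numerical data.frame of numerical features with a `sample` column;
#'   optional.
#' @param mutations data.frame with columns `sample`, `gene`, `event` (each
#'   row one mutation event; events among missense, nonsense, frameshift,
#'   splice); optional.
#' @param os_time named numeric vector of overall-survival times (days or any
#'   consistent unit), non-negative; optional.
#' @param os_event named 0/1 vector of event indicators; every sample with
#'   `os_event == 1` must have a time.
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(expression, categorical = NULL, numerical = NULL,
                         mutations = NULL, os_time = NULL, os_event = NULL) {
  stopifnot(is.matrix(expression), is.numeric(expression))
  samples <- colnames(expression)
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("expression must have unique sample column names")
  }
  check_feature_df <- function(df, what) {
    if (is.null(df)) {
      return(data.frame(sample = samples, stringsAsFactors = FALSE))
    }
    stopifnot(is.data.frame(df), "sample" %in% names(df))
    if (!all(df$sample %in% samples)) {
      stop(sprintf("%s table refers to unknown sample", what))
    }
    df
  }
  categorical <- check_feature_df(categorical, "categorical")
  numerical <- check_feature_df(numerical, "numerical")
  if (is.null(mutations)) {
    mutations <- data.frame(sample = character(0), gene = character(0),
                            event = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample", "gene", "event") %in% names(mutations)))
  if (nrow(mutations) > 0L) {
    if (!all(mutations$event %in% .mutation_events)) {
      stop("unknown mutation event: ",
           setdiff(mutations$event, .mutation_events)[1L])
    }
    if (!all(mutations$sample %in% samples)) {
      stop("mutation table refers to unknown sample")
    }
  }
  if (is.null(os_time)) os_time <- stats::setNames(numeric(0), character(0))
  if (is.null(os_event)) os_event <- stats::setNames(integer(0), character(0))
  if (!all(names(os_time) %in% samples) || !all(names(os_event) %in% samples)) {
    stop("survival data refers to unknown sample")
  }
  if (any(os_time < 0, na.rm = TRUE)) {
    stop("os_time must be non-negative")
  }
  if (!all(os_event %in% c(0L, 1L))) {
    stop("os_event must be 0 or 1")
  }
  ev1 <- names(os_event)[os_event == 1L]
  if (!all(ev1 %in% names(os_time)[is.finite(os_time)])) {
    stop("every sample with os_event = 1 must have an os_time")
  }
  structure(list(samples = samples, expression = expression,
                 categorical = categorical, numerical = numerical,
                 mutations = mutations, os_time = os_time,
                 os_event = os_event),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort: %d samples, %d genes, %d mutation events, %d with OS\n",
              length(x$samples), nrow(x$expression), nrow(x$mutations),
              length(x$os_time)))
  invisible(x)
}

cohort_expr <- function(cohort, gene, samples = cohort$samples) {
  if (!(gene %in% rownames(cohort$expression))) {
    stop(sprintf("gene '%s' not in cohort expression", gene))
  }
  cohort$expression[gene, samples]
}

#' Classify a sample's mutation events for one gene
#'
#' `None` when the event set is empty; `LOF` when any loss-of-function event
#' (nonsense, frameshift or splice) is present -- a sample carrying both a
#' missense and a LOF mutation is classified LOF; otherwise `missense`.
#'
#' @param events character vector of mutation events (possibly empty).
#' @return `"None"`, `"missense"` or `"LOF"`.
#' @export
classify_mutation <- function(events) {
  events <- as.character(events)
  if (length(events) > 0L && !all(events %in% .mutation_events)) {
    stop("unknown mutation event: ",
         setdiff(events, .mutation_events)[1L])
  }
  if (length(events) == 0L) {
    "None"
  } else if (any(events %in% .lof_events)) {
    "LOF"
  } else {
    "missense"
  }
}

#' Mutation class of every sample for one gene
#'
#' @param cohort a [cohort_table].
#' @param gene mutated gene id.
#' @return named character vector (sample -> class) over all cohort samples.
#' @export
mutation_classes <- function(cohort, gene) {
  stopifnot(inherits(cohort, "cohort_table"))
  mut <- cohort$mutations[cohort$mutations$gene == gene, , drop = FALSE]
  cls <- vapply(cohort$samples, function(s) {
    classify_mutation(mut$event[mut$sample == s])
  }, character(1))
  names(cls) <- cohort$samples
  cls
}

#' Association of gene expression with a categorical feature
#'
#' Drops feature groups with at most `min_group` samples (strict `>` to
#' retain), sorts the remaining groups by median expression, and compares the
#' lowest- and highest-median groups with a two-sided Wilcoxon rank-sum test.
#'
#' @param cohort a [cohort_table].
#' @param gene gene id.
#' @param feature categorical feature name.
#' @param min_group retained groups must have strictly more samples than this
#'   (default 5).
#' @return list with `low_group`, `high_group`, `n_low`, `n_high`, `p`;
#'   when fewer than two groups survive, `p` is `NA` and `reason` explains.
#' @export
categorical_association <- function(cohort, gene, feature, min_group = 5L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!(feature %in% names(cohort$categorical))) {
    stop(sprintf("unknown categorical feature '%s'", feature))
  }
  lab <- cohort$categorical[[feature]]
  samp <- cohort$categorical$sample
  ok <- !is.na(lab) & nzchar(as.character(lab))
  lab <- as.character(lab[ok])
  samp <- samp[ok]
  sizes <- table(lab)
  keep_groups <- names(sizes)[sizes > min_group]
  if (length(keep_groups) < 2L) {
    return(list(low_group = NA_character_, high_group = NA_character_,
                n_low = NA_integer_, n_high = NA_integer_, p = NA_real_,
                reason = "fewer than 2 groups exceed the size threshold"))
  }
  med <- vapply(keep_groups, function(g) {
    stats::median(cohort_expr(cohort, gene, samp[lab == g]))
  }, numeric(1))
  ord <- order(med, keep_groups)
  low <- keep_groups[ord[1L]]
  high <- keep_groups[ord[length(ord)]]
  x_low <- cohort_expr(cohort, gene, samp[lab == low])
  x_high <- cohort_expr(cohort, gene, samp[lab == high])
  list(low_group = low, high_group = high,
       n_low = length(x_low), n_high = length(x_high),
       p = rank_sum_test(x_low, x_high, "two.sided")$p)
}

#' Association of MR expression with mutation classes of a gene
#'
#' For each mutation class (missense, LOF) with at least one sample, compares
#' the MR's expression in that class against the unmutated (`None`) group
#' with a two-sided Wilcoxon rank-sum test, and reports the median expression
#' difference, its direction and whether the association is selected at
#' `p < alpha` (strict).
#'
#' @param cohort a [cohort_table].
#' @param mr_gene gene whose expression is tested.
#' @param mutated_gene gene whose mutation classes define the groups.
#' @param alpha selection threshold on the raw p-value (default 0.1).
#' @return data.frame with columns `class`, `n`, `delta_median`, `direction`
#'   (`"higher"`/`"lower"`), `p`, `selected`; classes without samples are
#'   omitted.
#' @export
mutation_association <- function(cohort, mr_gene, mutated_gene, alpha = 0.1) {
  cls <- mutation_classes(cohort, mutated_gene)
  none <- names(cls)[cls == "None"]
  if (length(none) == 0L) {
    stop("empty None group: every sample is mutated for ", mutated_gene)
  }
  x_none <- cohort_expr(cohort, mr_gene, none)
  rows <- list()
  for (cl in c("missense", "LOF")) {
    s <- names(cls)[cls == cl]
    if (length(s) == 0L) next
    x <- cohort_expr(cohort, mr_gene, s)
    p <- rank_sum_test(x, x_none, "two.sided")$p
    dm <- stats::median(x) - stats::median(x_none)
    rows[[cl]] <- data.frame(
      class = cl, n = length(s), delta_median = dm,
      direction = if (dm >= 0) "higher" else "lower",
      p = p, selected = p < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined mutation-group test over a gene set
#'
#' Group A holds the samples with a missense mutation class for at least one
#' gene of the set; group B holds the samples classified `None` for every
#' gene of the set. Samples whose only mutations in the set are LOF fall in
#' neither group. The two groups' expression of `mr_gene` is compared with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param cohort a [cohort_table].
#' @param mr_gene gene whose expression is tested.
#' @param gene_set nonempty character vector of mutated genes.
#' @return list with `n_mut`, `n_none`, `p` (`NA` with a `reason` when either
#'   group is empty).
#' @export
combined_mutation_test <- function(cohort, mr_gene, gene_set) {
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0L) {
    stop("gene_set must be nonempty")
  }
  cls <- vapply(gene_set, function(g) mutation_classes(cohort, g),
                character(length(cohort$samples)))
  cls <- matrix(cls, nrow = length(cohort$samples),
                dimnames = list(cohort$samples, gene_set))
  any_missense <- apply(cls == "missense", 1L, any)
  all_none <- apply(cls == "None", 1L, all)
  g_mut <- cohort$samples[any_missense]
  g_none <- cohort$samples[all_none]
  if (length(g_mut) == 0L || length(g_none) == 0L) {
    return(list(n_mut = length(g_mut), n_none = length(g_none), p = NA_real_,
                reason = "missense or fully-unmutated group is empty"))
  }
  p <- rank_sum_test(cohort_expr(cohort, mr_gene, g_mut),
                     cohort_expr(cohort, mr_gene, g_none), "two.sided")$p
  list(n_mut = length(g_mut), n_none = length(g_none), p = p)
}

#' Spearman association of gene expression with a numerical feature
#'
#' @param cohort a [cohort_table].
#' @param gene gene id.
#' @param feature numerical feature name.
#' @return list with `rho` and `p` (asymptotic t approximation).
#' @export
numerical_association <- function(cohort, gene, feature) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!(feature %in% names(cohort$numerical))) {
    stop(sprintf("unknown numerical feature '%s'", feature))
  }
  v <- cohort$numerical[[feature]]
  samp <- cohort$numerical$sample
  x <- cohort_expr(cohort, gene, samp)
  ok <- is.finite(v) & is.finite(x)
  if (sum(ok) < 4L) {
    stop("numerical association needs at least 4 paired observations")
  }
  ct <- suppressWarnings(
    stats::cor.test(x[ok], v[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Log-rank survival test on a percentile expression split
#'
#' Splits the samples with survival data at the given percentile of the
#' gene's expression (linear-interpolation quantile); the high group holds
#' samples with expression strictly above the threshold, ties go low. The two
#' groups are compared with the standard two-group log-rank test (1 df).
#'
#' @param cohort a [cohort_table].
#' @param gene gene id.
#' @param percentile split percentile in (0, 100) (default 80).
#' @return list with `n_high`, `n_low`, `chi_sq`, `p`; when a group has fewer
#'   than 2 samples or there are no events, `p` is `NA` and `reason`
#'   explains.
#' @export
survival_split_logrank <- function(cohort, gene, percentile = 80) {
  stopifnot(inherits(cohort, "cohort_table"),
            percentile > 0, percentile < 100)
  samp <- names(cohort$os_time)[is.finite(cohort$os_time)]
  samp <- samp[samp %in% names(cohort$os_event)]
  x <- cohort_expr(cohort, gene, samp)
  thr <- stats::quantile(x, percentile / 100, type = 7, names = FALSE)
  high <- x > thr
  n_high <- sum(high)
  n_low <- sum(!high)
  ev <- cohort$os_event[samp]
  if (n_high < 2L || n_low < 2L) {
    return(list(n_high = n_high, n_low = n_low, chi_sq = NA_real_,
                p = NA_real_, reason = "a split group has fewer than 2 samples"))
  }
  if (sum(ev) == 0L) {
    return(list(n_high = n_high, n_low = n_low, chi_sq = NA_real_,
                p = NA_real_, reason = "no events observed"))
  }
  sd <- survival::survdiff(
    survival::Surv(cohort$os_time[samp], ev) ~ high, rho = 0)
  chi <- unname(sd$chisq)
  list(n_high = n_high, n_low = n_low, chi_sq = chi,
       p = stats::pchisq(chi, df = 1L, lower.tail = FALSE))
}

#' Mutation association report over many genes
#'
#' Runs [mutation_association()] of one MR against each gene of a list and
#' stacks the per-class rows, adding a Benjamini-Hochberg adjusted p column
#' (`p_bh`) as optional extra output; selection itself uses the raw p-values,
#' as in the rest of the battery.
#'
#' @param cohort a [cohort_table].
#' @param mr_gene gene whose expression is tested.
#' @param mutated_genes character vector of mutated genes to test.
#' @param alpha raw-p selection threshold (default 0.1).
#' @return data.frame with columns `gene`, `class`, `n`, `delta_median`,
#'   `direction`, `p`, `selected`, `p_bh`.
#' @export
mutation_association_report <- function(cohort, mr_gene, mutated_genes,
                                        alpha = 0.1) {
  rows <- lapply(mutated_genes, function(g) {
    res <- mutation_association(cohort, mr_gene, g, alpha = alpha)
    if (is.null(res) || nrow(res) == 0L) {
      return(NULL)
    }
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(0), class = character(0),
                      n = integer(0), delta_median = numeric(0),
                      direction = character(0), p = numeric(0),
                      selected = logical(0), p_bh = numeric(0)))
  }
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Run the full clinical association battery for a set of genes
#'
#' For each gene: every categorical feature ([categorical_association()]),
#' every numerical feature ([numerical_association()]), every mutated gene in
#' the cohort ([mutation_association_report()]) and the percentile-split
#' log-rank survival test ([survival_split_logrank()]).
#'
#' @param cohort a [cohort_table].
#' @param genes character vector of genes (must be in the expression matrix).
#' @param alpha mutation selection threshold (default 0.1).
#' @param percentile survival split percentile (default 80).
#' @param min_group categorical group-size threshold (default 5).
#' @return list of data.frames `categorical`, `numerical`, `mutation`,
#'   `survival`.
#' @export
association_battery <- function(cohort, genes, alpha = 0.1, percentile = 80,
                                min_group = 5L) {
  stopifnot(inherits(cohort, "cohort_table"))
  cat_features <- setdiff(names(cohort$categorical), "sample")
  num_features <- setdiff(names(cohort$numerical), "sample")
  mut_genes <- sort(unique(cohort$mutations$gene))
  cat_rows <- list()
  for (g in genes) {
    for (f in cat_features) {
      res <- categorical_association(cohort, g, f, min_group = min_group)
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        gene = g, feature = f, low_group = res$low_group,
        high_group = res$high_group, n_low = res$n_low, n_high = res$n_high,
        p = res$p, stringsAsFactors = FALSE)
    }
  }
  num_rows <- list()
  for (g in genes) {
    for (f in num_features) {
      res <- numerical_association(cohort, g, f)
      num_rows[[length(num_rows) + 1L]] <- data.frame(
        gene = g, feature = f, rho = res$rho, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  mut_rows <- list()
  for (g in genes) {
    rep <- mutation_association_report(cohort, g, mut_genes, alpha = alpha)
    if (nrow(rep) > 0L) {
      mut_rows[[length(mut_rows) + 1L]] <-
        cbind(data.frame(mr_gene = g, stringsAsFactors = FALSE), rep)
    }
  }
  surv_rows <- list()
  for (g in genes) {
    res <- survival_split_logrank(cohort, g, percentile = percentile)
    surv_rows[[length(surv_rows) + 1L]] <- data.frame(
      gene = g, n_high = res$n_high, n_low = res$n_low,
      chi_sq = res$chi_sq, p = res$p, stringsAsFactors = FALSE)
  }
  list(categorical = do.call(rbind, cat_rows),
       numerical = do.call(rbind, num_rows),
       mutation = if (length(mut_rows) > 0L) do.call(rbind, mut_rows) else
         NULL,
       survival = do.call(rbind, surv_rows))
}

#' Expression summary of two genes across sample-type groups
#'
#' Convenience report for a two-gene expression table with sample types:
#' Pearson correlation of the two genes across all samples, plus two-sided
#' rank-sum p-values for each gene between consecutive group pairs.
#'
#' @param cohort a [cohort_table].
#' @param gene_a,gene_b gene ids.
#' @param feature categorical feature holding the group labels (default
#'   `"sample_type"`).
#' @param groups ordered group labels (default `c("N", "C", "M")`).
#' @return list with `pearson_r` and data.frame `group_tests` (`gene`,
#'   `group1`, `group2`, `p`).
#' @export
expression_group_report <- function(cohort, gene_a, gene_b,
                                    feature = "sample_type",
                                    groups = c("N", "C", "M")) {
  stopifnot(inherits(cohort, "cohort_table"))
  xa <- cohort_expr(cohort, gene_a)
  xb <- cohort_expr(cohort, gene_b)
  r <- stats::cor(xa, xb, method = "pearson")
  lab <- cohort$categorical[[feature]]
  samp <- cohort$categorical$sample
  rows <- list()
  for (g in seq_len(length(groups) - 1L)) {
    s1 <- samp[lab == groups[g]]
    s2 <- samp[lab == groups[g + 1L]]
    if (length(s1) == 0L || length(s2) == 0L) next
    for (gene in c(gene_a, gene_b)) {
      p <- rank_sum_test(cohort_expr(cohort, gene, s1),
                         cohort_expr(cohort, gene, s2), "two.sided")$p
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group1 = groups[g], group2 = groups[g + 1L], p = p,
        stringsAsFactors = FALSE)
    }
  }
  list(pearson_r = r, group_tests = do.call(rbind, rows))
}
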