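#' Differential-expression signature
#'
#' One DE signature holds a single per-gene score for one dataset: the
#' moderated t-statistic for microarray data, or the signed -log10 adjusted
#' p-value for RNA-seq (see [rnaseq_de_score()]).
#'
#' @param dataset_id dataset label.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param scores named numeric vector, one finite score per gene.
#' @return object of class `de_signature`.
#' @export
de_signature <- function(dataset_id, platform = c("microarray", "rnaseq"),
                         scores) {
  platform <- match.arg(platform)
  if (!is.numeric(scores) || is.null(names(scores)) ||
      any(!nzchar(names(scores)))) {
    stop("scores must be a numeric vector named by gene id")
  }
  if (anyDuplicated(names(scores))) {
    stop("duplicate gene in signature: ",
         names(scores)[duplicated(names(scores))][1L])
  }
  if (length(scores) > 0L && !all(is.finite(scores))) {
    stop("signature scores must be finite")
  }
  structure(list(dataset_id = as.character(dataset_id),
                 platform = platform, scores = scores),
            class = "de_signature")
}

#' @export
print.de_signature <- function(x, ...) {
  cat(sprintf("DE signature '%s' (%s): %d genes\n",
              x$dataset_id, x$platform, length(x$scores)))
  invisible(x)
}

#' Collapse probe-level statistics to gene-level scores
#'
#' Probes without an assigned gene id are discarded. When a gene has several
#' probes, the probe with the highest absolute t-statistic is kept; on an
#' |t| tie the probe with the larger signed t wins, and on a further tie the
#' lexicographically smallest probe id, so the result does not depend on
#' input order.
#'
#' @param records data.frame with columns `probe_id`, `gene` (may be `NA` or
#'   empty) and `t` (finite).
#' @return named numeric vector of per-gene scores (empty input gives an
#'   empty vector).
#' @export
collapse_probes <- function(records) {
  if (nrow(records) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  stopifnot(all(c("probe_id", "gene", "t") %in% names(records)))
  if (!all(is.finite(records$t))) {
    stop("probe t-statistics must be finite")
  }
  gene <- as.character(records$gene)
  keep <- !is.na(gene) & nzchar(gene)
  records <- records[keep, , drop = FALSE]
  gene <- gene[keep]
  if (nrow(records) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  ord <- order(gene, -abs(records$t), -records$t,
               as.character(records$probe_id))
  records <- records[ord, , drop = FALSE]
  gene <- gene[ord]
  first <- !duplicated(gene)
  stats::setNames(records$t[first], gene[first])
}

#' Read a probe-level statistics table
#'
#' TSV with columns `probe_id`, `gene` (may be empty for unassigned probes)
#' and `t` (the per-probe moderated t-statistic), ready for
#' [collapse_probes()].
#'
#' @param path file path.
#' @return data.frame with columns `probe_id`, `gene`, `t`.
#' @export
read_probe_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = c("character", "character", "numeric"),
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = "")
  if (!identical(names(tab), c("probe_id", "gene", "t"))) {
    stop("probe file must have columns probe_id, gene, t")
  }
  tab
}

#' DE score for an RNA-seq gene
#'
#' The RNA-seq DE measurement is `-S * log10(adjusted p)`, where `S` is the
#' regulation direction (+1 up, -1 down), so small adjusted p-values give
#' large scores whose sign matches the direction. Adjusted p-values of 0 are
#' floored at 1e-300 to keep the score finite.
#'
#' @param direction +1 (up-regulated) or -1 (down-regulated); vectorized.
#' @param adj_p adjusted p-value in \[0, 1\]; vectorized.
#' @return numeric DE score(s).
#' @export
rnaseq_de_score <- function(direction, adj_p) {
  if (!all(direction %in% c(-1, 1))) {
    stop("direction must be +1 or -1")
  }
  if (!is.numeric(adj_p) || any(!is.finite(adj_p)) ||
      any(adj_p < 0 | adj_p > 1)) {
    stop("adj_p must be in [0, 1]")
  }
  -direction * log10(pmax(adj_p, 1e-300))
}

#' Average DE score of a gene across datasets
#'
#' Arithmetic mean over the signatures in which the gene is scored; datasets
#' missing the gene do not contribute.
#'
#' @param signatures list of [de_signature] objects.
#' @param gene gene id.
#' @return numeric scalar.
#' @export
average_de <- function(signatures, gene) {
  vals <- unlist(lapply(signatures, function(s) {
    if (gene %in% names(s$scores)) unname(s$scores[[gene]]) else NULL
  }))
  if (is.null(vals) || length(vals) == 0L) {
    stop(sprintf("gene '%s' is absent from every signature", gene))
  }
  mean(vals)
}

#' Per-gene average DE over a set of signatures
#'
#' @param signatures list of [de_signature] objects.
#' @param genes genes to average; defaults to the union of all scored genes.
#'   Genes absent from every signature are dropped.
#' @return named numeric vector of averages.
#' @export
average_de_table <- function(signatures, genes = NULL) {
  all_genes <- unique(unlist(lapply(signatures, function(s) names(s$scores))))
  if (is.null(genes)) genes <- sort(all_genes)
  genes <- genes[genes %in% all_genes]
  sums <- stats::setNames(numeric(length(genes)), genes)
  cnts <- stats::setNames(integer(length(genes)), genes)
  for (s in signatures) {
    idx <- match(genes, names(s$scores))
    hit <- !is.na(idx)
    sums[hit] <- sums[hit] + s$scores[idx[hit]]
    cnts[hit] <- cnts[hit] + 1L
  }
  sums / cnts
}

#' Select genes by average DE score
#'
#' Keeps the genes whose cross-dataset average DE score is strictly greater
#' than the threshold.
#'
#' @param signatures list of [de_signature] objects.
#' @param genes candidate gene set.
#' @param threshold numeric cutoff (strict `>`).
#' @return sorted character vector of selected genes.
#' @export
select_by_average_de <- function(signatures, genes, threshold) {
  avg <- average_de_table(signatures, genes = genes)
  sort(names(avg)[avg > threshold])
}

#' Read a DE signature from a TSV file
#'
#' The file holds comment lines `# dataset_id=...` and `# platform=...`
#' followed by a header `gene<TAB>score` and one row per gene.
#'
#' @param path file path.
#' @return a [de_signature].
#' @export
read_de_signature <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  if (is.null(meta$dataset_id) || is.null(meta$platform)) {
    stop("signature file must carry '# dataset_id=' and '# platform=' lines")
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", quote = "",
                           colClasses = c("character", "numeric"),
                           stringsAsFactors = FALSE)
  if (!identical(names(tab), c("gene", "score"))) {
    stop("signature file must have columns gene, score")
  }
  de_signature(meta$dataset_id, meta$platform,
               stats::setNames(tab$score, tab$gene))
}

#' Write a DE signature to a TSV file
#' @param sig a [de_signature].
#' @param path output file path.
#' @export
write_de_signature <- function(sig, path) {
  stopifnot(inherits(sig, "de_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dataset_id=%s", sig$dataset_id),
               sprintf("# platform=%s", sig$platform)), con)
  utils::write.table(data.frame(gene = names(sig$scores),
                                score = unname(sig$scores),
                                stringsAsFactors = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
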