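#' Write a cohort to a directory of TSV files
#'
#' Emits `expression.tsv` (genes x samples), `annotations.tsv` (sample plus
#' all categorical and numerical feature columns), `mutations.tsv`
#' (`sample`, `gene`, `event`) and `survival.tsv` (`sample`, `os_time`,
#' `os_event`).
#'
#' @param cohort a [cohort_table].
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.frame(gene = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- merge(cohort$categorical, cohort$numerical, by = "sample",
               sort = TRUE)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  surv <- data.frame(sample = names(cohort$os_time),
                     os_time = unname(cohort$os_time),
                     os_event = unname(cohort$os_event[names(cohort$os_time)]),
                     stringsAsFactors = FALSE)
  utils::write.table(surv, file.path(dir, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Annotation columns are split into categorical (non-numeric) and numerical
#' (numeric) features by column type.
#'
#' @param dir directory path.
#' @return a [cohort_table].
#' @export
read_cohort <- function(dir) {
  expr_tab <- utils::read.table(file.path(dir, "expression.tsv"),
                                header = TRUE, sep = "\t", quote = "",
                                check.names = FALSE, stringsAsFactors = FALSE,
                                comment.char = "")
  genes <- expr_tab$gene
  expr <- as.matrix(expr_tab[, setdiff(names(expr_tab), "gene"),
                             drop = FALSE])
  rownames(expr) <- genes
  ann <- utils::read.table(file.path(dir, "annotations.tsv"), header = TRUE,
                           sep = "\t", quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  ann$sample <- as.character(ann$sample)
  is_num <- vapply(ann, is.numeric, logical(1))
  is_num["sample"] <- FALSE
  categorical <- ann[, c("sample", names(ann)[!is_num & names(ann) != "sample"]),
                     drop = FALSE]
  numerical <- ann[, c("sample", names(ann)[is_num]), drop = FALSE]
  mut <- utils::read.table(file.path(dir, "mutations.tsv"), header = TRUE,
                           sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  surv <- utils::read.table(file.path(dir, "survival.tsv"), header = TRUE,
                            sep = "\t", quote = "", stringsAsFactors = FALSE,
                            comment.char = "")
  cohort_table(expr, categorical = categorical, numerical = numerical,
               mutations = mut,
               os_time = stats::setNames(surv$os_time, surv$sample),
               os_event = stats::setNames(as.integer(surv$os_event),
                                          surv$sample))
}
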