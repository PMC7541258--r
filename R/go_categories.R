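# GO term ids used to bin master regulators into functional categories.
# Terms are matched literally (no ontology traversal).
.go_tf_activity   <- "GO:0003700"  # DNA-binding transcription factor activity
.go_dna_binding   <- "GO:0003677"  # DNA binding
.go_tx_regulator  <- "GO:0030528"  # transcription regulator activity
.go_tx_regulation <- "GO:0045449"  # regulation of transcription
.go_tf_cofactor   <- "GO:0003712"  # transcription cofactor activity
.go_signal_transd <- "GO:0007165"  # signal transduction
.go_intracellular <- "GO:0005622"  # intracellular
.go_plasma_membr  <- "GO:0005886"  # plasma membrane

#' Classify a master regulator by its GO annotation
#'
#' Bins a gene into one of four functional categories using literal GO term
#' membership, with precedence TF > TFcoFac > SigPathway:
#' * `TF`: transcription factor activity (GO:0003700), or DNA binding
#'   (GO:0003677) together with transcription regulator activity (GO:0030528)
#'   or regulation of transcription (GO:0045449);
#' * `TFcoFac`: not TF, and transcription cofactor activity (GO:0003712),
#'   GO:0030528 or GO:0045449;
#' * `SigPathway`: neither of the above, and signal transduction
#'   (GO:0007165), intracellular (GO:0005622) or plasma membrane
#'   (GO:0005886);
#' * `Unannotated`: none of the above.
#'
#' @param terms character vector of GO term ids (`"GO:NNNNNNN"`); may be
#'   empty.
#' @return one of `"TF"`, `"TFcoFac"`, `"SigPathway"`, `"Unannotated"`.
#' @export
classify_mr <- function(terms) {
  terms <- as.character(terms)
  if (length(terms) > 0L && !all(grepl("^GO:[0-9]{7}$", terms))) {
    stop("invalid GO term id: ",
         terms[!grepl("^GO:[0-9]{7}$", terms)][1L])
  }
  has <- function(t) t %in% terms
  if (has(.go_tf_activity) ||
      (has(.go_dna_binding) && (has(.go_tx_regulator) || has(.go_tx_regulation)))) {
    return("TF")
  }
  if (has(.go_tf_cofactor) || has(.go_tx_regulator) || has(.go_tx_regulation)) {
    return("TFcoFac")
  }
  if (has(.go_signal_transd) || has(.go_intracellular) || has(.go_plasma_membr)) {
    return("SigPathway")
  }
  "Unannotated"
}

#' Read a GO annotation table
#'
#' TSV with columns `gene` and `go_terms` (comma-separated GO ids; may be
#' empty).
#'
#' @param path file path.
#' @return named list mapping gene id -> character vector of GO term ids.
#' @export
read_go_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", comment.char = "",
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "go_terms") %in% names(tab))) {
    stop("GO annotation file must have columns gene, go_terms")
  }
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene in GO annotation: ",
         tab$gene[duplicated(tab$gene)][1L])
  }
  terms <- strsplit(tab$go_terms, ",", fixed = TRUE)
  terms <- lapply(terms, function(t) t[nzchar(t)])
  names(terms) <- tab$gene
  terms
}

#' Classify a set of genes into MR categories
#'
#' @param annotation named list gene -> GO term ids, as from
#'   [read_go_annotation()]. Genes absent from the list are `Unannotated`.
#' @param genes character vector of gene ids to classify.
#' @return named character vector of categories, one per gene.
#' @export
classify_mr_table <- function(annotation, genes) {
  out <- vapply(genes, function(g) {
    classify_mr(if (g %in% names(annotation)) annotation[[g]] else character(0))
  }, character(1))
  names(out) <- genes
  out
}
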