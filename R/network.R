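#' Regulon interactome data model
#'
#' A regulatory network is a table of directed edges regulator -> target, each
#' carrying a mode of regulation (MOR, signed strength in \[-1, +1\], positive
#' meaning activation) and a likelihood weight in (0, 1\] reflecting the
#' mutual-information support for the edge. The set of targets of one
#' regulator is its regulon.
#'
#' @param edges data.frame with columns `regulator`, `target` (character),
#'   `mor`, `likelihood` (numeric).
#' @return object of class `regulatory_network` (a validated data.frame).
#' @export
regulatory_network <- function(edges) {
  required <- c("regulator", "target", "mor", "likelihood")
  if (!is.data.frame(edges) || !all(required %in% names(edges))) {
    stop("edges must be a data.frame with columns ",
         paste(required, collapse = ", "))
  }
  edges <- edges[required]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  validate_network_edges(edges)
  rownames(edges) <- NULL
  attr(edges, "regulators") <- sort(unique(edges$regulator))
  class(edges) <- c("regulatory_network", "data.frame")
  edges
}

validate_network_edges <- function(edges) {
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) {
      stop(sprintf("invalid interactome: %s at row %d", what, i[1L]),
           call. = FALSE)
    }
  }
  bad_row(is.na(edges$regulator) | edges$regulator == "" | edges$regulator == ".",
          "missing regulator id")
  bad_row(is.na(edges$target) | edges$target == "" | edges$target == ".",
          "missing target id")
  bad_row(!is.finite(edges$mor), "malformed mor")
  bad_row(!is.finite(edges$likelihood), "malformed likelihood")
  bad_row(edges$mor < -1 | edges$mor > 1, "mor outside [-1, 1]")
  bad_row(edges$likelihood <= 0 | edges$likelihood > 1,
          "likelihood outside (0, 1]")
  bad_row(edges$regulator == edges$target, "self-edge")
  bad_row(duplicated(paste(edges$regulator, edges$target, sep = "\r")),
          "duplicate regulator-target edge")
  invisible(TRUE)
}

#' Read a regulon interactome from a tab-separated file
#'
#' Expects a UTF-8 TSV with header `regulator`, `target`, `mor`,
#' `likelihood`. Every edge must be complete; any malformed row (missing id,
#' non-numeric or out-of-range mor/likelihood, self-edge, duplicate edge) is
#' rejected with its row number.
#'
#' @param path file path.
#' @return a [regulatory_network].
#' @export
read_interactome <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  required <- c("regulator", "target", "mor", "likelihood")
  if (!identical(names(tab)[seq_along(required)], required)) {
    stop("interactome file must have header: ",
         paste(required, collapse = ", "))
  }
  mor <- suppressWarnings(as.numeric(tab$mor))
  lik <- suppressWarnings(as.numeric(tab$likelihood))
  bad <- which(is.na(mor) | is.na(lik))
  if (length(bad) > 0L) {
    stop(sprintf("invalid interactome: malformed numeric field at row %d",
                 bad[1L]))
  }
  regulatory_network(data.frame(regulator = tab$regulator,
                                target = tab$target,
                                mor = mor, likelihood = lik,
                                stringsAsFactors = FALSE))
}

#' Write a regulon interactome to a tab-separated file
#'
#' Inverse of [read_interactome()]; a write/read roundtrip reproduces the
#' edge table exactly.
#'
#' @param net a [regulatory_network].
#' @param path output file path.
#' @export
write_interactome <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract the regulon of a regulator
#'
#' @param net a [regulatory_network].
#' @param mr regulator gene id.
#' @return data.frame with columns `target`, `mor`, `likelihood`, one row per
#'   target of `mr`.
#' @export
regulon_of <- function(net, mr) {
  stopifnot(inherits(net, "regulatory_network"), length(mr) == 1L)
  idx <- net$regulator == mr
  if (!any(idx)) {
    stop(sprintf("unknown regulator '%s'", mr))
  }
  out <- data.frame(target = net$target[idx], mor = net$mor[idx],
                    likelihood = net$likelihood[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' All regulators of a network
#' @param net a [regulatory_network].
#' @return sorted character vector of regulator ids.
#' @export
regulators <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  regs <- attr(net, "regulators")
  if (is.null(regs)) regs <- sort(unique(net$regulator))
  regs
}

#' Partition the regulons of two regulators into common and unique targets
#'
#' Splits the union of the two regulons into three disjoint groups: targets
#' regulated by both MRs (common, carrying both MORs and both likelihood
#' weights) and targets unique to each MR. This partition is the substrate of
#' the synergy test.
#'
#' @param net a [regulatory_network].
#' @param mr1,mr2 regulator gene ids.
#' @return object of class `regulon_partition`: list with data.frames
#'   `common` (`target`, `mor1`, `mor2`, `w1`, `w2`), `unique1` and `unique2`
#'   (`target`, `mor`, `likelihood`), plus `mr1`, `mr2`, `size1`, `size2`
#'   (full regulon sizes).
#' @export
partition_regulons <- function(net, mr1, mr2) {
  r1 <- regulon_of(net, mr1)
  r2 <- regulon_of(net, mr2)
  partition_from_regulons(r1, r2, mr1, mr2)
}

# build a regulon_partition from two extracted regulon data.frames
partition_from_regulons <- function(r1, r2, mr1, mr2) {
  common_targets <- sort(intersect(r1$target, r2$target))
  i1 <- match(common_targets, r1$target)
  i2 <- match(common_targets, r2$target)
  common <- data.frame(target = common_targets,
                       mor1 = r1$mor[i1], mor2 = r2$mor[i2],
                       w1 = r1$likelihood[i1], w2 = r2$likelihood[i2],
                       stringsAsFactors = FALSE)
  u1 <- r1[!(r1$target %in% common_targets), , drop = FALSE]
  u2 <- r2[!(r2$target %in% common_targets), , drop = FALSE]
  u1 <- u1[order(u1$target), , drop = FALSE]
  u2 <- u2[order(u2$target), , drop = FALSE]
  rownames(u1) <- rownames(u2) <- NULL
  structure(list(common = common, unique1 = u1, unique2 = u2,
                 mr1 = mr1, mr2 = mr2,
                 size1 = nrow(r1), size2 = nrow(r2)),
            class = "regulon_partition")
}
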