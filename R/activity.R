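#' Rank-based signed normal scores of a DE signature
#'
#' Maps the G gene scores to standard-normal quantiles through their average
#' ranks: `z = qnorm((rank - 0.5) / G)` with ties given average ranks. The
#' transform is strictly monotone on untied inputs and centres the signature
#' so that regulon enrichment can be tested against an analytic N(0,1) null.
#'
#' @param sig a [de_signature], or a named numeric vector of scores.
#' @return named numeric vector of z-scores (one per gene).
#' @export
signed_normal_scores <- function(sig) {
  scores <- if (inherits(sig, "de_signature")) sig$scores else sig
  if (!is.numeric(scores) || is.null(names(scores))) {
    stop("signature scores must be a named numeric vector")
  }
  G <- length(scores)
  if (G < 2L) {
    stop("at least 2 genes are required for normal scores")
  }
  r <- rank(scores, ties.method = "average")
  stats::setNames(stats::qnorm((r - 0.5) / G), names(scores))
}

#' Normalized enrichment score of one regulator
#'
#' Likelihood-weighted, MOR-signed mean of the normal scores of a regulon:
#' with weights `w` (edge likelihood) and modes `mor` over the targets `t`
#' present in the signature (targets with `mor == 0` are excluded),
#' `NES = sum(w * mor * z_t) / sqrt(sum(w^2 * mor^2))`, which is N(0,1) when
#' the targets are an exchangeable draw from the signature. The two-sided
#' p-value is the normal tail `2 * pnorm(-|NES|)`. A positive NES reads as
#' activation of the regulator, negative as suppression.
#'
#' @param net a [regulatory_network].
#' @param z named numeric vector of normal scores (from
#'   [signed_normal_scores()]).
#' @param mr regulator id (must be in `net`).
#' @param min_targets minimum number of contributing targets; below it the
#'   NES is undefined (`NA`). Default 2 (the variance normalization
#'   degenerates on fewer).
#' @return list with `nes`, `p`, `n_used`.
#' @export
mr_nes <- function(net, z, mr, min_targets = 2L) {
  reg <- regulon_of(net, mr)
  idx <- match(reg$target, names(z))
  keep <- !is.na(idx) & reg$mor != 0
  n_used <- sum(keep)
  if (n_used < min_targets) {
    return(list(nes = NA_real_, p = NA_real_, n_used = n_used))
  }
  w <- reg$likelihood[keep]
  mor <- reg$mor[keep]
  zt <- unname(z[idx[keep]])
  nes <- sum(w * mor * zt) / sqrt(sum(w^2 * mor^2))
  list(nes = nes, p = 2 * stats::pnorm(-abs(nes)), n_used = n_used)
}

#' Differential-activity signature of all regulators
#'
#' Converts a gene-level DE signature into a regulator-level DA table by
#' computing the NES of every regulon in the network (see [mr_nes()]).
#' Regulators with fewer than `min_targets` scoreable targets get `NA` NES
#' and p.
#'
#' @param net a [regulatory_network].
#' @param sig a [de_signature].
#' @param min_targets minimum contributing targets per regulator (default 2).
#' @return object of class `da_table`: data.frame with columns `regulator`,
#'   `nes`, `p`, `n_targets_used`, rows sorted by regulator id, with the
#'   dataset id in `attr(, "dataset_id")`.
#' @export
da_signature <- function(net, sig, min_targets = 2L) {
  stopifnot(inherits(net, "regulatory_network"), inherits(sig, "de_signature"))
  z <- signed_normal_scores(sig)
  regs <- regulators(net)
  idx <- match(net$target, names(z))
  keep <- !is.na(idx) & net$mor != 0
  grp <- match(net$regulator, regs)[keep]
  w <- net$likelihood[keep]
  mor <- net$mor[keep]
  zt <- unname(z[idx[keep]])
  num <- den <- rep(0, length(regs))
  n_used <- rep(0L, length(regs))
  if (any(keep)) {
    wm <- w * mor
    agg <- rowsum(cbind(wm * zt, wm^2, 1), grp)
    gi <- as.integer(rownames(agg))
    num[gi] <- agg[, 1L]
    den[gi] <- agg[, 2L]
    n_used[gi] <- as.integer(agg[, 3L])
  }
  nes <- ifelse(n_used >= min_targets, num / sqrt(den), NA_real_)
  p <- 2 * stats::pnorm(-abs(nes))
  out <- data.frame(regulator = regs, nes = unname(nes), p = unname(p),
                    n_targets_used = unname(n_used),
                    stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- sig$dataset_id
  class(out) <- c("da_table", "data.frame")
  out
}

#' Dataset id of a DA table
#' @param da a `da_table`.
#' @return character scalar.
#' @export
da_dataset_id <- function(da) {
  stopifnot(inherits(da, "da_table"))
  attr(da, "dataset_id")
}

#' Write a DA table to TSV
#'
#' Columns: `regulator`, `nes`, `p`, `n_targets_used`, `dataset_id`;
#' undefined values are written as `NA`.
#'
#' @param da a `da_table`.
#' @param path output file path.
#' @export
write_da_table <- function(da, path) {
  stopifnot(inherits(da, "da_table"))
  out <- as.data.frame(da)
  out$dataset_id <- da_dataset_id(da)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
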