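#' Eligibility of an MR pair for synergy testing
#'
#' A pair is tested only when it shares strictly more than `min_common`
#' common regulons and the common regulons make up strictly more than
#' `min_frac` of each MR's regulon.
#'
#' @param size1,size2 regulon sizes of the two MRs.
#' @param common_size number of shared targets (must not exceed the smaller
#'   regulon).
#' @param min_common minimum shared-target count (strict `>`, default 10).
#' @param min_frac minimum shared fraction of each regulon (strict `>`,
#'   default 0.10).
#' @return logical.
#' @export
eligible_pair <- function(size1, size2, common_size,
                          min_common = 10L, min_frac = 0.10) {
  stopifnot(size1 >= 0, size2 >= 0, common_size >= 0)
  if (common_size > min(size1, size2)) {
    stop("inconsistent partition: common size exceeds a regulon size")
  }
  common_size > min_common &&
    common_size / size1 > min_frac &&
    common_size / size2 > min_frac
}

#' Expression contribution to activity
#'
#' `ECA = DE * MOR`: the contribution of one target to its regulator's
#' activity change, the product of the target's DE score and the edge's mode
#' of regulation. Vectorized.
#'
#' @param de DE score(s).
#' @param mor mode(s) of regulation in \[-1, 1\].
#' @return numeric ECA value(s).
#' @export
eca <- function(de, mor) {
  if (any(mor < -1 | mor > 1, na.rm = TRUE)) {
    stop("mor must lie in [-1, 1]")
  }
  de * mor
}

#' Synergy test of an MR pair on one DE signature
#'
#' For each MR of the pair, compares the ECA values of the common regulons
#' (computed with that MR's own MOR) against the ECA values of that MR's
#' unique regulons with a one-tailed Wilcoxon rank-sum test. The alternative
#' is "greater" when the MR's differential activity in that dataset is
#' positive (activated MRs should have their shared targets more up-weighted
#' than their unique ones) and "less" when negative. Targets without a DE
#' score are dropped; if either comparison group then becomes empty the
#' corresponding p is `NA`.
#'
#' @param partition a `regulon_partition` from [partition_regulons()].
#' @param sig a [de_signature].
#' @param da_sign1,da_sign2 sign (+1 or -1) of each MR's DA in this dataset.
#' @return named numeric vector `c(p1, p2)`.
#' @export
synergy_test <- function(partition, sig, da_sign1, da_sign2) {
  stopifnot(inherits(partition, "regulon_partition"),
            inherits(sig, "de_signature"))
  if (!(da_sign1 %in% c(-1, 1)) || !(da_sign2 %in% c(-1, 1))) {
    stop("da_sign must be +1 or -1")
  }
  scores <- sig$scores
  one_side <- function(common_mor, uniq, da_sign) {
    ci <- match(partition$common$target, names(scores))
    ui <- match(uniq$target, names(scores))
    ce <- eca(unname(scores[ci[!is.na(ci)]]), common_mor[!is.na(ci)])
    ue <- eca(unname(scores[ui[!is.na(ui)]]), uniq$mor[!is.na(ui)])
    if (length(ce) == 0L || length(ue) == 0L) {
      return(NA_real_)
    }
    alt <- if (da_sign > 0) "greater" else "less"
    rank_sum_test(ce, ue, alternative = alt)$p
  }
  c(p1 = one_side(partition$common$mor1, partition$unique1, da_sign1),
    p2 = one_side(partition$common$mor2, partition$unique2, da_sign2))
}

#' Screen all candidate MR pairs for synergy
#'
#' Considers every unordered pair of candidate MRs, keeps the pairs passing
#' [eligible_pair()], and runs [synergy_test()] per dataset, taking each MR's
#' DA sign per dataset from the matching DA table. Datasets are matched
#' between `sigs` and `das` by dataset id. Pairs are ordered with
#' `mr1 < mr2` lexicographically.
#'
#' @param net a [regulatory_network].
#' @param candidate_mrs character vector of MR ids (all present in `net` and
#'   in every DA table).
#' @param sigs list of [de_signature]s.
#' @param das list of `da_table`s covering the same dataset ids.
#' @param min_common,min_frac eligibility thresholds (see [eligible_pair()]).
#' @return data.frame of class `synergy_result` with one row per eligible
#'   pair per dataset: `mr1`, `mr2`, `size1`, `size2`, `common_size`,
#'   `dataset_id`, `da_sign1`, `da_sign2`, `p1`, `p2`. Zero rows when no
#'   pair is eligible.
#' @export
synergy_screen <- function(net, candidate_mrs, sigs, das,
                           min_common = 10L, min_frac = 0.10) {
  candidate_mrs <- sort(unique(as.character(candidate_mrs)))
  regs <- regulators(net)
  if (!all(candidate_mrs %in% regs)) {
    stop("candidate MR not in network: ",
         setdiff(candidate_mrs, regs)[1L])
  }
  da_ids <- vapply(das, da_dataset_id, character(1))
  sig_ids <- vapply(sigs, function(s) s$dataset_id, character(1))
  if (!all(sig_ids %in% da_ids)) {
    stop("every signature dataset needs a matching DA table")
  }
  for (da in das) {
    if (!all(candidate_mrs %in% da$regulator)) {
      stop("candidate MR missing from DA table '", da_dataset_id(da), "'")
    }
  }
  empty <- data.frame(mr1 = character(0), mr2 = character(0),
                      size1 = integer(0), size2 = integer(0),
                      common_size = integer(0), dataset_id = character(0),
                      da_sign1 = numeric(0), da_sign2 = numeric(0),
                      p1 = numeric(0), p2 = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(candidate_mrs) < 2L) {
    class(empty) <- c("synergy_result", "data.frame")
    return(empty)
  }
  cand_edges <- net[net$regulator %in% candidate_mrs, , drop = FALSE]
  regulon_list <- split(
    data.frame(target = cand_edges$target, mor = cand_edges$mor,
               likelihood = cand_edges$likelihood, stringsAsFactors = FALSE),
    cand_edges$regulator)
  pairs <- utils::combn(candidate_mrs, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    m1 <- pairs[1L, k]
    m2 <- pairs[2L, k]
    part <- partition_from_regulons(regulon_list[[m1]], regulon_list[[m2]],
                                    m1, m2)
    if (!eligible_pair(part$size1, part$size2, nrow(part$common),
                       min_common = min_common, min_frac = min_frac)) {
      next
    }
    for (j in seq_along(sigs)) {
      sig <- sigs[[j]]
      da <- das[[match(sig$dataset_id, da_ids)]]
      s1 <- sign(da$nes[match(m1, da$regulator)])
      s2 <- sign(da$nes[match(m2, da$regulator)])
      p1 <- p2 <- NA_real_
      if (!is.na(s1) && s1 != 0 && !is.na(s2) && s2 != 0) {
        ps <- synergy_test(part, sig, s1, s2)
        p1 <- ps[["p1"]]
        p2 <- ps[["p2"]]
      } else if (!is.na(s1) && s1 != 0) {
        p1 <- synergy_test(part, sig, s1, 1)[["p1"]]
        s2 <- NA_real_
      } else if (!is.na(s2) && s2 != 0) {
        p2 <- synergy_test(part, sig, 1, s2)[["p2"]]
        s1 <- NA_real_
      } else {
        s1 <- s2 <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mr1 = m1, mr2 = m2, size1 = part$size1, size2 = part$size2,
        common_size = nrow(part$common), dataset_id = sig$dataset_id,
        da_sign1 = s1, da_sign2 = s2, p1 = p1, p2 = p2,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("synergy_result", "data.frame")
  out
}

#' Top synergistic pair of a synergy screen
#'
#' Summarizes a [synergy_screen()] result by the pair minimizing the maximum
#' of its per-dataset p-values (both tests, all datasets; undefined p-values
#' count as 1). Ties break lexicographically on the pair.
#'
#' @param results a `synergy_result` data.frame.
#' @return character vector `c(mr1, mr2)`, or `NULL` when no pair was
#'   eligible.
#' @export
top_synergistic_pair <- function(results) {
  stopifnot(inherits(results, "synergy_result"))
  if (nrow(results) == 0L) {
    return(NULL)
  }
  key <- paste(results$mr1, results$mr2, sep = "\t")
  pmax_na1 <- pmax(ifelse(is.na(results$p1), 1, results$p1),
                   ifelse(is.na(results$p2), 1, results$p2))
  worst <- tapply(pmax_na1, key, max)
  best <- sort(names(worst)[worst == min(worst)])[1L]
  strsplit(best, "\t", fixed = TRUE)[[1L]]
}

#' Write a synergy report TSV
#'
#' One row per eligible pair, with its sizes and two p-value columns per
#' dataset (`p1_<dataset>` for the MR1 test, `p2_<dataset>` for MR2).
#'
#' @param results a `synergy_result` data.frame.
#' @param path output file path.
#' @export
write_synergy_report <- function(results, path) {
  stopifnot(inherits(results, "synergy_result"))
  if (nrow(results) == 0L) {
    utils::write.table(
      data.frame(mr1 = character(0), mr2 = character(0),
                 size1 = integer(0), size2 = integer(0),
                 common_size = integer(0)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ids <- unique(results$dataset_id)
  key <- paste(results$mr1, results$mr2, sep = "\t")
  ukey <- sort(unique(key))
  first <- match(ukey, key)
  wide <- data.frame(mr1 = results$mr1[first], mr2 = results$mr2[first],
                     size1 = results$size1[first],
                     size2 = results$size2[first],
                     common_size = results$common_size[first],
                     stringsAsFactors = FALSE)
  for (id in ids) {
    sub <- results[results$dataset_id == id, , drop = FALSE]
    subkey <- paste(sub$mr1, sub$mr2, sep = "\t")
    wide[[paste0("p1_", id)]] <- sub$p1[match(ukey, subkey)]
    wide[[paste0("p2_", id)]] <- sub$p2[match(ukey, subkey)]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
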