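#' Top-N regulators of a DA table by activation or suppression
#'
#' Returns the `n` regulators with the largest (activated) or smallest
#' (suppressed) NES among rows with a defined NES. Ties at the boundary are
#' broken lexicographically on regulator id so the set is deterministic.
#'
#' @param da a `da_table`.
#' @param n number of regulators to select.
#' @param direction `"activated"` or `"suppressed"`.
#' @return character vector of `n` regulator ids (in rank order).
#' @export
top_n <- function(da, n, direction = c("activated", "suppressed")) {
  direction <- match.arg(direction)
  stopifnot(inherits(da, "da_table"), n >= 1L)
  def <- da[!is.na(da$nes), , drop = FALSE]
  if (nrow(def) < n) {
    stop(sprintf("only %d regulators with defined NES; cannot take top %d",
                 nrow(def), n))
  }
  ord <- if (direction == "activated") {
    order(-def$nes, def$regulator)
  } else {
    order(def$nes, def$regulator)
  }
  def$regulator[ord][seq_len(n)]
}

#' Common top regulators across discovery DA tables
#'
#' Intersects the per-dataset top-N sets, separately for activated and
#' suppressed regulators.
#'
#' @param das list of `da_table`s (at least 2, the discovery datasets).
#' @param n top-N cutoff per dataset.
#' @return list with sorted character vectors `activated` and `suppressed`.
#' @export
common_top <- function(das, n) {
  if (length(das) < 2L) {
    stop("common_top needs at least 2 discovery DA tables")
  }
  act <- Reduce(intersect, lapply(das, top_n, n = n, direction = "activated"))
  sup <- Reduce(intersect, lapply(das, top_n, n = n, direction = "suppressed"))
  list(activated = sort(act), suppressed = sort(sup))
}

#' Validate a common-MR set in an independent DA table
#'
#' Two-sided Wilcoxon rank-sum test comparing the NES values of the selected
#' regulators against all other regulators with defined NES in the validation
#' dataset.
#'
#' @param da a `da_table` (validation dataset).
#' @param mrs nonempty character vector of regulator ids; must be a strict
#'   subset of the regulators with defined NES.
#' @return p-value.
#' @export
validate_common <- function(da, mrs) {
  stopifnot(inherits(da, "da_table"))
  def <- da[!is.na(da$nes), , drop = FALSE]
  mrs <- unique(as.character(mrs))
  if (length(mrs) == 0L) {
    stop("mrs must be nonempty")
  }
  if (!all(mrs %in% def$regulator) || length(mrs) >= nrow(def)) {
    stop("mrs must be a strict subset of regulators with defined NES")
  }
  sel <- def$regulator %in% mrs
  rank_sum_test(def$nes[sel], def$nes[!sel], alternative = "two.sided")$p
}

#' Filter regulators for activity-expression (DA-DE) consistency
#'
#' Keeps a regulator only if, in every discovery dataset, the sign of its own
#' gene's DE score matches the sign of its NES and the DE magnitude is
#' strictly above `de_threshold` (i.e. DE > 3 when activated, DE < -3 when
#' suppressed, at the default). Regulators missing a DA value or a DE score
#' in any discovery dataset are dropped with a warning.
#'
#' @param mrs candidate regulator ids.
#' @param das list of discovery `da_table`s.
#' @param sigs list of discovery [de_signature]s (same datasets).
#' @param de_threshold strict DE magnitude cutoff (default 3).
#' @return sorted character vector of consistent regulators.
#' @export
da_de_consistent <- function(mrs, das, sigs, de_threshold = 3) {
  mrs <- unique(as.character(mrs))
  kept <- character(0)
  for (mr in mrs) {
    nes <- vapply(das, function(da) {
      i <- match(mr, da$regulator)
      if (is.na(i)) NA_real_ else da$nes[i]
    }, numeric(1))
    de <- vapply(sigs, function(s) {
      if (mr %in% names(s$scores)) unname(s$scores[[mr]]) else NA_real_
    }, numeric(1))
    if (anyNA(nes) || anyNA(de)) {
      warning(sprintf(
        "dropping '%s': missing DA or DE value in a discovery dataset", mr))
      next
    }
    if (all(sign(de) == sign(nes) & abs(de) > de_threshold)) {
      kept <- c(kept, mr)
    }
  }
  sort(kept)
}

#' Write a selection report
#'
#' One row per selected regulator: direction, per-discovery-dataset NES rank
#' (within its direction), per-validation p-value of the common set, and the
#' DA-DE consistency verdict.
#'
#' @param path output TSV path.
#' @param selection list from [common_top()].
#' @param discovery_das,validation_das lists of `da_table`s.
#' @param consistent character vector from [da_de_consistent()].
#' @export
write_selection_report <- function(path, selection, discovery_das,
                                   validation_das, consistent) {
  rows <- list()
  for (direction in c("activated", "suppressed")) {
    mrs <- selection[[direction]]
    if (length(mrs) == 0L) next
    ranks <- sapply(discovery_das, function(da) {
      def <- da[!is.na(da$nes), , drop = FALSE]
      ord <- if (direction == "activated") {
        order(-def$nes, def$regulator)
      } else {
        order(def$nes, def$regulator)
      }
      match(mrs, def$regulator[ord])
    })
    ranks <- matrix(ranks, nrow = length(mrs))
    colnames(ranks) <- paste0("rank_", vapply(discovery_das, da_dataset_id,
                                              character(1)))
    vps <- vapply(validation_das, function(da) validate_common(da, mrs),
                  numeric(1))
    df <- data.frame(regulator = mrs, direction = direction,
                     ranks, stringsAsFactors = FALSE, check.names = FALSE)
    for (j in seq_along(validation_das)) {
      df[[paste0("validation_p_", da_dataset_id(validation_das[[j]]))]] <- vps[j]
    }
    df$da_de_consistent <- mrs %in% consistent
    rows[[direction]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(regulator = character(0), direction = character(0),
                      da_de_consistent = logical(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
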