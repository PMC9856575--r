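#' Interclass separation between two trial ensembles
#'
#' Scatter-normalized separation between the two class cluster means,
#' using a Fisher-type trace-normalized criterion:
#' \deqn{s = \|\mu_a - \mu_b\|^2 / (\mathrm{tr}(S_a) + \mathrm{tr}(S_b))}
#' where `mu` is the mean trial vector of an ensemble and `tr(S)` the sum
#' of its per-sample (unbiased) variances. Larger values indicate clusters
#' whose means are far apart relative to the within-class scatter, hence
#' channels on which the classes should be easier to separate. A 0/0 ratio
#' (identical, scatter-free ensembles) is defined as 0.
#'
#' The criterion is pluggable via `criterion` so an alternative separation
#' measure can be dropped in without touching the ranking machinery.
#'
#' @param ens_a,ens_b [trial_ensemble()] objects with equal trial length.
#' @param criterion optional function `(trials_a, trials_b) -> score`
#'   replacing the default.
#' @return single nonnegative separation score.
#' @export
interclass_separation <- function(ens_a, ens_b, criterion = NULL) {
  a <- if (inherits(ens_a, "trial_ensemble")) ens_a$trials else as.matrix(ens_a)
  b <- if (inherits(ens_b, "trial_ensemble")) ens_b$trials else as.matrix(ens_b)
  if (ncol(a) != ncol(b)) stop("trial lengths differ between ensembles")
  if (!is.null(criterion)) return(criterion(a, b))
  gap <- sum((colMeans(a) - colMeans(b))^2)
  scatter <- sum(apply(a, 2, stats::var)) + sum(apply(b, 2, stats::var))
  if (scatter == 0) {
    if (gap == 0) return(0)
    return(Inf)
  }
  gap / scatter
}

#' Rank channels by rank-of-rank-sum (RRS)
#'
#' Aggregates per-(subject, class-pair) interclass separation scores into a
#' single channel ordering:
#' 1. within each (subject, class pair), channels are ranked by descending
#'    separation (rank 1 = most separable; ties get average ranks);
#' 2. within each subject, the ranks are summed over the class pairs and
#'    the sums re-ranked (ascending, since small rank sums are good);
#' 3. across subjects, the per-subject rankings are summed and re-ranked to
#'    give the final ordering.
#'
#' With one subject and one class pair this reduces to ordering by the raw
#' separation scores.
#'
#' @param scores data frame with columns `subject`, `pair`, `channel`,
#'   `score`; every channel must be scored for every (subject, pair) cell.
#' @return object of class `"rank_table"`: list with `pair_ranks` (long
#'   data frame of stage-1 ranks), `subject_ranks` (per-subject rank sums
#'   and ranks), `final` (data frame `channel`, `rank_sum`, `final_rank`,
#'   ordered best first).
#' @export
rank_channels <- function(scores) {
  need <- c("subject", "pair", "channel", "score")
  if (!all(need %in% names(scores))) {
    stop("'scores' needs columns subject, pair, channel, score")
  }
  channels <- sort(unique(as.character(scores$channel)))
  cells <- unique(scores[c("subject", "pair")])
  if (nrow(scores) != nrow(cells) * length(channels) ||
      any(is.na(scores$score))) {
    stop("missing separation scores: every channel must be scored for ",
         "every (subject, class-pair) cell")
  }
  # stage 1: per (subject, pair), rank channels by descending separation
  scores$cell <- interaction(scores$subject, scores$pair, drop = TRUE)
  scores$rank <- stats::ave(-scores$score, scores$cell,
                            FUN = function(v) rank(v, ties.method = "average"))
  # stage 2: per subject, rank the rank sums (ascending)
  rs <- stats::aggregate(rank ~ subject + channel, scores, sum)
  names(rs)[names(rs) == "rank"] <- "rank_sum"
  rs$subject_rank <- stats::ave(rs$rank_sum, rs$subject,
                                FUN = function(v) rank(v, ties.method = "average"))
  # stage 3: across subjects, rank the summed per-subject rankings
  fin <- stats::aggregate(subject_rank ~ channel, rs, sum)
  names(fin)[names(fin) == "subject_rank"] <- "rank_sum"
  fin$final_rank <- rank(fin$rank_sum, ties.method = "average")
  fin <- fin[order(fin$final_rank, fin$channel), ]
  rownames(fin) <- NULL
  structure(list(pair_ranks = scores[setdiff(names(scores), "cell")],
                 subject_ranks = rs, final = fin),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("<rank_table> final channel ranking:\n")
  print(x$final)
  invisible(x)
}

#' Select the top-k channels of a ranking
#'
#' @param ranking a `"rank_table"` from [rank_channels()].
#' @param k number of channels, `<=` channel count.
#' @return character vector of `k` channel names, best first.
#' @export
select_top_k <- function(ranking, k) {
  fin <- ranking$final
  if (k > nrow(fin)) stop("'k' exceeds the number of ranked channels")
  as.character(fin$channel[seq_len(k)])
}

#' Interclass separations for a multi-subject, multi-channel dataset
#'
#' Convenience wrapper computing the [interclass_separation()] of every
#' class pair at every channel of every subject of a nested dataset (as
#' produced by [generate_dataset()]): `dataset[[subject]][[channel]]` is a
#' named list of per-class [trial_ensemble()]s.
#'
#' @param dataset nested list, see above.
#' @param criterion optional separation criterion override.
#' @return data frame with columns `subject`, `pair`, `channel`, `score`,
#'   ready for [rank_channels()].
#' @export
separation_table <- function(dataset, criterion = NULL) {
  rows <- list()
  for (subj in names(dataset)) {
    for (ch in names(dataset[[subj]])) {
      cls <- dataset[[subj]][[ch]]
      cn <- names(cls)
      if (length(cn) < 2L) stop("need at least two classes per channel")
      for (i in seq_len(length(cn) - 1L)) {
        for (j in seq((i + 1L), length(cn))) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj, pair = paste(cn[i], cn[j], sep = "|"),
            channel = ch,
            score = interclass_separation(cls[[i]], cls[[j]], criterion))
        }
      }
    }
  }
  do.call(rbind, rows)
}
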