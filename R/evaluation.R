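# Evaluation of infection-risk rankings against simulation ground truth.
#
# Truth label: node is in state I on the final day T (the inference target
# is the final-day infection probability). AUC uses mid-rank tie handling so
# heavily tied rankings (Degree, Contact) are neither penalized nor favoured
# by arbitrary ordering.

#' Tie-aware AUC of a score vector against binary labels
#'
#' Mid-rank (Mann-Whitney) formulation:
#' `AUC = (sum of positive ranks - n1 (n1 + 1) / 2) / (n1 * n0)`.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels logical or 0/1 truth labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: truth labels contain a single class")
  rk <- rank(scores)                     # ties get mid-ranks
  (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Tie-aware ROC curve: one point per distinct score threshold, tied scores
# stepped through jointly (the polygon whose area is the mid-rank AUC).
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
}

#' Evaluate a ranking against an outbreak
#'
#' @param scores per-node scores (higher = more likely infected at day T).
#' @param trajectory the true `sir_trajectory`.
#' @param obs optional `observation_set`, needed for
#'   `eval_policy = "unobserved"`.
#' @param eval_policy `"all"` evaluates every node (default);
#'   `"unobserved"` excludes nodes observed on the final day.
#' @param truth `"final_I"` labels nodes infectious on day T (default);
#'   `"ever_infected"` labels nodes that ever left S.
#' @return list of class `evaluation_result` with `auc`, `roc`
#'   (data.frame `fpr`, `tpr`), `eval_set` and `n_positive`.
#' @export
evaluate_ranking <- function(scores, trajectory, obs = NULL,
                             eval_policy = c("all", "unobserved"),
                             truth = c("final_I", "ever_infected")) {
  eval_policy <- match.arg(eval_policy)
  truth <- match.arg(truth)
  n <- nrow(trajectory$states)
  if (length(scores) != n) stop("scores length must equal node count")
  final <- trajectory$states[, trajectory$T + 1]
  labels <- if (truth == "final_I") final == 2L else final != 1L
  keep <- seq_len(n)
  if (eval_policy == "unobserved") {
    if (is.null(obs)) stop("eval_policy 'unobserved' needs the observation set")
    keep <- setdiff(keep, obs$node[obs$day == trajectory$T])
  }
  structure(list(auc = auc_score(scores[keep], labels[keep]),
                 roc = roc_points(scores[keep], labels[keep]),
                 eval_set = keep, n_positive = sum(labels[keep])),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: AUC = %.3f over %d nodes (%d positive)\n",
              x$auc, length(x$eval_set), x$n_positive))
  invisible(x)
}

#' Infections found among top-ranked nodes
#'
#' `hits(k)` = number of truly infectious (day T) nodes among the top k by
#' score; ties are broken by a fixed-seed shuffle so heavily tied rankings
#' are treated fairly.
#'
#' @param scores per-node scores.
#' @param trajectory the true `sir_trajectory`.
#' @param ks vector of k values.
#' @param seed integer seed for the tie-breaking shuffle.
#' @return data.frame with columns `k` and `hits`.
#' @export
topk_curve <- function(scores, trajectory, ks, seed = 1L) {
  n <- nrow(trajectory$states)
  if (any(ks > n)) stop("k must not exceed the node count")
  labels <- trajectory$states[, trajectory$T + 1] == 2L
  ord <- with_seed(seed, order(scores, sample.int(n), decreasing = TRUE))
  cum <- cumsum(labels[ord])
  data.frame(k = ks, hits = ifelse(ks == 0, 0L, cum[pmax(ks, 1)]))
}
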