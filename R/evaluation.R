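# Tie-grouped threshold sweep shared by the PR and ROC areas: strains with
# equal scores enter as one threshold group, which removes any dependence
# on input order.
.sweep_counts <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(l)[ends]
  fp <- ends - tp
  list(tp = tp, fp = fp, n_pos = sum(l), n_neg = sum(!l))
}

.drop_missing_pairs <- function(scores, defects) {
  keep <- !is.na(scores) & !is.na(defects)
  list(scores = scores[keep], defects = as.logical(defects[keep]))
}

#' Precision-recall curve and area
#'
#' Sweeps all score thresholds (ties grouped) with growth-defect strains
#' as positives and integrates by the step-wise rule
#' `sum(precision * delta recall)` — no trapezoidal interpolation between
#' PR points, which is known to be biased in PR space. The area of an
#' uninformative constant score equals the defect prevalence.
#'
#' @param scores Predicted sensitivity scores, higher = more sensitive.
#' @param defects Logical (or 0/1) observed growth defects; pairs with a
#'   missing score or phenotype are excluded.
#' @return List with `curve` (data frame threshold/recall/precision) and
#'   `auc`.
#' @export
pr_auc <- function(scores, defects) {
  d <- .drop_missing_pairs(scores, defects)
  if (!sum(d$defects) || all(d$defects))
    stop("PR curve undefined without both positives and negatives")
  sw <- .sweep_counts(d$scores, d$defects)
  precision <- sw$tp / (sw$tp + sw$fp)
  recall <- sw$tp / sw$n_pos
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = sort(unique(d$scores), decreasing = TRUE),
                          recall = recall, precision = precision),
       auc = auc)
}

#' ROC curve and area
#'
#' Trapezoidal area under the receiver operating characteristic; with
#' tied scores grouped this equals the Mann-Whitney U statistic divided
#' by `n_pos * n_neg`.
#'
#' @inheritParams pr_auc
#' @return List with `curve` (data frame threshold/fpr/tpr) and `auc`.
#' @export
roc_auc <- function(scores, defects) {
  d <- .drop_missing_pairs(scores, defects)
  if (!sum(d$defects) || all(d$defects))
    stop("ROC curve undefined without both positives and negatives")
  sw <- .sweep_counts(d$scores, d$defects)
  tpr <- c(0, sw$tp / sw$n_pos)
  fpr <- c(0, sw$fp / sw$n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(threshold = c(Inf, sort(unique(d$scores),
                                                  decreasing = TRUE)),
                          fpr = fpr, tpr = tpr),
       auc = auc)
}

# Fast PR area over many label permutations of a fixed score vector.
# Scores are pre-sorted once; each replicate only permutes labels.
.pr_auc_permuted <- function(scores, labels, R) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  n <- length(s); n_pos <- sum(labels)
  vapply(seq_len(R), function(r) {
    l <- labels[sample.int(n)][o]
    tp <- cumsum(l)[ends]
    precision <- tp / ends
    recall <- tp / n_pos
    sum(diff(c(0, recall)) * precision)
  }, numeric(1))
}

#' Randomized conditional scores
#'
#' Generates the replicate score vectors of one condition under one of
#' three null strategies:
#' \describe{
#'   \item{`shuffled_strains`}{permutes the strain-to-score assignment
#'     (equivalently the phenotype labels), keeping the score multiset.}
#'   \item{`shuffled_sets`}{recomputes the score using the essential-gene
#'     set (and weights) of another condition; donors are drawn without
#'     replacement until exhausted, then with replacement.}
#'   \item{`random_sets`}{recomputes the score using a uniformly drawn
#'     reference-gene set of the same size with uniform weights.}
#' }
#' Each replicate vector is min-max scaled to the range of the actual
#' score vector; areas under rank-based curves are invariant to this
#' monotone scaling.
#'
#' @param strategy One of `"shuffled_strains"`, `"shuffled_sets"`,
#'   `"random_sets"`.
#' @param condition Condition id to randomize.
#' @param dm The [disruption_matrix()].
#' @param cs The [conditional_score()] result.
#' @param R Number of replicates.
#' @param seed Integer seed; the replicate set is reproducible
#'   bit-for-bit.
#' @return An `R` x n-strains matrix of replicate score vectors.
#' @export
randomized_scores <- function(strategy = c("shuffled_strains", "shuffled_sets",
                                           "random_sets"),
                              condition, dm, cs, R = 10000L, seed = NULL) {
  strategy <- match.arg(strategy)
  if (R < 1) stop("'R' must be at least 1")
  if (!condition %in% colnames(cs$S)) stop("unknown condition: ", condition)
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(dm)
  actual <- cs$S[, condition]
  logm <- log1p(-m)
  inv_e <- ifelse(cs$E_s == 0, 0, 1 / cs$E_s)
  rep_scores <- switch(
    strategy,
    shuffled_strains = {
      t(vapply(seq_len(R), function(r) actual[sample.int(length(actual))],
               numeric(length(actual))))
    },
    shuffled_sets = {
      donors <- setdiff(colnames(cs$S), condition)
      if (!length(donors)) stop("'shuffled_sets' needs at least 2 conditions")
      draw <- .donor_sequence(donors, R)
      t(vapply(draw, function(d) {
        w <- cs$weights[[d]]
        inv_e * as.vector(logm[, names(w), drop = FALSE] %*% w)
      }, numeric(nrow(m))))
    },
    random_sets = {
      l_c <- length(cs$weights[[condition]])
      t(vapply(seq_len(R), function(r) {
        g <- sample(colnames(m), l_c)
        inv_e * rowSums(logm[, g, drop = FALSE])
      }, numeric(nrow(m))))
    })
  colnames(rep_scores) <- names(actual)
  .minmax_scale_rows(rep_scores, min(actual), max(actual))
}

# without replacement until the donor pool is exhausted, then with
# replacement; deterministic under the caller's seed
.donor_sequence <- function(donors, R) {
  full <- rep(list(donors), R %/% length(donors))
  seq <- unlist(lapply(full, sample))
  extra <- R - length(seq)
  if (extra > 0) seq <- c(seq, sample(donors, extra, replace = TRUE))
  seq[seq_len(R)]
}

.minmax_scale_rows <- function(x, lo, hi) {
  rng <- apply(x, 1, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  (x - rng[1, ]) / span * (hi - lo) + lo
}

#' Empirical significance of an observed area against replicates
#'
#' Add-one empirical p-value `p = (1 + #{replicate >= actual}) / (1 + R)`
#' per condition, with Benjamini-Hochberg correction across conditions
#' (within one randomization strategy).
#'
#' @param actual Named vector of observed areas, one per condition.
#' @param replicates List (parallel to `actual`) of replicate area
#'   vectors.
#' @return Data frame with condition, actual, p, q.
#' @export
empirical_significance <- function(actual, replicates) {
  stopifnot(length(actual) == length(replicates))
  p <- mapply(function(a, reps) (1 + sum(reps >= a)) / (1 + length(reps)),
              actual, replicates)
  data.frame(condition = names(actual), actual = unname(actual),
             p = unname(p), q = stats::p.adjust(p, method = "BH"),
             row.names = NULL)
}

#' Evaluate conditional-score predictions against observed phenotypes
#'
#' For every condition with both defect and no-defect strains, computes
#' the PR and ROC areas of the predicted sensitivity scores against the
#' binary growth-defect calls, and calibrates the PR area against the
#' requested randomization nulls ([randomized_scores()]), reporting
#' add-one empirical p-values and BH q-values per strategy.
#'
#' @param cs A [conditional_score()] result.
#' @param calls Strains x conditions 0/1 (or logical) defect-call matrix;
#'   NA cells are excluded pairwise.
#' @param dm The [disruption_matrix()] (needed by the set-based nulls).
#' @param strategies Randomization strategies to run.
#' @param R Replicates per strategy and condition.
#' @param seed Integer seed.
#' @return An object of class `evaluation_report`: data frame with one
#'   row per evaluable condition (columns condition, n_strains,
#'   n_defects, prevalence, pr_auc, roc_auc, and p_/q_ per strategy).
#'   Replicate areas are kept in the `"replicate_areas"` attribute.
#' @export
evaluate_conditions <- function(cs, calls, dm,
                                strategies = c("shuffled_strains",
                                               "shuffled_sets",
                                               "random_sets"),
                                R = 10000L, seed = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  conds <- intersect(colnames(cs$S), colnames(calls))
  rows <- list(); rep_areas <- list()
  for (cond in conds) {
    y <- calls[rownames(cs$S), cond]
    keep <- !is.na(y)
    y_ok <- as.logical(y[keep])
    if (!sum(y_ok) || all(y_ok)) next
    s <- cs$S[keep, cond]
    rows[[cond]] <- data.frame(
      condition = cond, n_strains = length(y_ok), n_defects = sum(y_ok),
      prevalence = mean(y_ok),
      pr_auc = pr_auc(s, y_ok)$auc, roc_auc = roc_auc(s, y_ok)$auc,
      stringsAsFactors = FALSE)
    for (strat in strategies) {
      areas <- if (strat == "shuffled_strains") {
        # fast path: permuting scores against fixed labels is the same
        # null as permuting labels against fixed scores
        .pr_auc_permuted(s, y_ok, R)
      } else {
        reps <- randomized_scores(strat, cond, dm, cs, R = R)
        apply(reps[, names(s), drop = FALSE], 1,
              function(r) pr_auc(r, y_ok)$auc)
      }
      rep_areas[[strat]][[cond]] <- areas
    }
  }
  if (!length(rows)) stop("no condition has both defect and no-defect strains")
  report <- do.call(rbind, rows)
  for (strat in strategies) {
    sig <- empirical_significance(
      stats::setNames(report$pr_auc, report$condition),
      rep_areas[[strat]][report$condition])
    report[[paste0("p_", strat)]] <- sig$p
    report[[paste0("q_", strat)]] <- sig$q
  }
  rownames(report) <- NULL
  structure(report, replicate_areas = rep_areas,
            class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("evaluation over %d conditions (median PR-AUC %.3f, baseline %.3f)\n",
              nrow(x), stats::median(x$pr_auc), stats::median(x$prevalence)))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
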