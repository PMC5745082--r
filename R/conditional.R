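#' Conditional-essentiality table
#'
#' Container for the conditionally essential gene sets derived from a
#' reference-strain chemical-genomics screen: one row per (condition,
#' gene) with the FDR-corrected p-value of the knockout's growth
#' phenotype. The per-gene promiscuity `C_g` (number of screen conditions
#' in which the gene has a significant phenotype) and the screen size
#' `N_c` are derived here and used by [gene_weight()].
#'
#' @param entries Data frame with columns `condition`, `gene`, `fdr_p`
#'   (values strictly inside (0, 1)).
#' @param n_screen_conditions Total number of conditions tested in the
#'   screen; defaults to the number of distinct conditions in `entries`
#'   (the screen can be larger than the overlap retained here).
#' @return An object of class `essentiality_table`: the entries plus
#'   `c_g` (named per-gene counts) and `n_screen` attributes.
#' @export
essentiality_table <- function(entries, n_screen_conditions = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("condition", "gene", "fdr_p") %in% names(entries)))
  if (any(entries$fdr_p <= 0 | entries$fdr_p >= 1))
    stop("'fdr_p' values must lie strictly inside (0, 1)")
  entries$condition <- as.character(entries$condition)
  entries$gene <- as.character(entries$gene)
  c_g <- vapply(split(entries$condition, entries$gene),
                function(x) length(unique(x)), integer(1))
  n_screen <- if (is.null(n_screen_conditions))
    length(unique(entries$condition)) else as.integer(n_screen_conditions)
  if (any(c_g > n_screen))
    stop("a gene is significant in more conditions than the screen size")
  structure(entries, c_g = c_g, n_screen = n_screen,
            class = c("essentiality_table", "data.frame"))
}

#' @export
print.essentiality_table <- function(x, ...) {
  cat(sprintf("conditional essentiality: %d entries, %d conditions, %d genes (screen size %d)\n",
              nrow(x), length(unique(x$condition)),
              length(attr(x, "c_g")), attr(x, "n_screen")))
  invisible(x)
}

#' Strain divergence E_s
#'
#' Mean log-survival of gene function across all reference genes:
#' `E_s = (1/n) * sum_g log(1 - P_{s,g}(AF))`. Always non-positive; zero
#' only for a strain with no disruption anywhere. Used to normalize the
#' conditional score so that overall genomic divergence from the
#' reference does not masquerade as condition-specific sensitivity.
#'
#' @param dm A [disruption_matrix()] or strains x genes matrix of P(AF).
#' @return Named vector of E_s values, one per strain.
#' @export
strain_divergence <- function(dm) {
  m <- unclass(dm)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (!ncol(m)) stop("empty gene set")
  if (any(m >= 1)) stop("P(AF) must be below 1 (cap at 0.99)")
  rowMeans(log1p(-m))
}

#' Weight of a conditionally essential gene
#'
#' `W_{g,c}` combines the strength of the knockout phenotype with the
#' gene's promiscuity across the screen. The published formula renders as
#' `-log10(F_{g,c}) * C_g / N_c` (`mode = "as_rendered"`), which
#' up-weights genes that respond in many conditions; the text's reading
#' of `C_g` as a specificity correction suggests the inverse,
#' `-log10(F_{g,c}) * N_c / C_g` (`mode = "inverted"`). Both are
#' first-class; `"uniform"` gives every gene weight 1 (the unweighted
#' model).
#'
#' @param f_gc FDR-corrected p-value(s) in (0, 1); zeros are clipped to
#'   the smallest positive double with a warning.
#' @param c_g Number of screen conditions where the gene is significant.
#' @param n_c Total screen conditions.
#' @param mode `"as_rendered"`, `"inverted"` or `"uniform"`.
#' @return Non-negative weight(s).
#' @examples
#' gene_weight(0.05, 1, 100)  # ~0.0130
#' @export
gene_weight <- function(f_gc, c_g, n_c,
                        mode = c("as_rendered", "inverted", "uniform")) {
  mode <- match.arg(mode)
  if (mode == "uniform") return(rep(1, length(f_gc)))
  if (any(c_g < 1) || any(c_g > n_c))
    stop("'c_g' must lie in [1, n_c]")
  if (any(f_gc == 0)) {
    warning("F_{g,c} of 0 clipped to the smallest positive double")
    f_gc[f_gc == 0] <- .Machine$double.xmin
  }
  if (any(f_gc < 0 | f_gc >= 1)) stop("'f_gc' must lie in (0, 1)")
  w <- -log10(f_gc)
  if (mode == "as_rendered") w * c_g / n_c else w * n_c / c_g
}

# weights for the genes of one condition, aligned with `genes`
.condition_weights <- function(ess, condition, genes, mode) {
  sub <- ess[ess$condition == condition & ess$gene %in% genes, , drop = FALSE]
  stats::setNames(
    gene_weight(sub$fdr_p, attr(ess, "c_g")[sub$gene], attr(ess, "n_screen"),
                mode),
    sub$gene)
}

#' Conditional sensitivity score S_{s,c}
#'
#' Combines the disruption matrix with the conditionally essential gene
#' sets: `S_{s,c} = sum_{g in set(c)} (1/E_s) * W_{g,c} *
#' log(1 - P_{s,g}(AF))`. Every summand is non-negative (a non-positive
#' log times the non-positive `1/E_s` times a non-negative weight), so
#' higher scores mark strains predicted to be more sensitive in the
#' condition. Strains with `E_s = 0` (no disruption anywhere, i.e.
#' reference-like) score 0. Also computes, per strain and condition, the
#' maximum attainable score `S_max` obtained by setting every set gene's
#' disruption to the panel-wide maximum `P_max(AF)` (see [max_score()]).
#'
#' @param dm A [disruption_matrix()].
#' @param ess An [essentiality_table()].
#' @param weight_mode Passed to [gene_weight()].
#' @return An object of class `conditional_scores`: list with `S`
#'   (strains x conditions matrix), `S_max` (same shape), `E_s`, `P_max`,
#'   `weights` (per-condition named weight vectors), `weight_mode`, and
#'   `skipped` (essential genes absent from the reference gene set).
#' @export
conditional_score <- function(dm, ess,
                              weight_mode = c("as_rendered", "inverted",
                                              "uniform")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(ess, "essentiality_table"))
  m <- unclass(dm)
  genes <- colnames(m)
  conditions <- unique(ess$condition)
  skipped <- setdiff(unique(ess$gene), genes)
  if (length(skipped))
    warning(length(skipped),
            " essential genes missing from the reference gene set; skipped")
  e_s <- strain_divergence(m)
  p_max <- max(m)
  inv_e <- ifelse(e_s == 0, 0, 1 / e_s)
  logm <- log1p(-m)
  S <- Smax <- matrix(0, nrow(m), length(conditions),
                      dimnames = list(rownames(m), conditions))
  weights <- vector("list", length(conditions))
  names(weights) <- conditions
  drop_cond <- logical(length(conditions))
  for (i in seq_along(conditions)) {
    w <- .condition_weights(ess, conditions[i], genes, weight_mode)
    weights[[i]] <- w
    if (!length(w)) {
      warning("condition '", conditions[i],
              "' has no usable essential genes; skipped")
      drop_cond[i] <- TRUE
      next
    }
    S[, i] <- inv_e * (logm[, names(w), drop = FALSE] %*% w) + 0  # +0: no -0
    Smax[, i] <- inv_e * sum(w) * log1p(-p_max) + 0
  }
  keep <- !drop_cond
  structure(
    list(S = S[, keep, drop = FALSE], S_max = Smax[, keep, drop = FALSE],
         E_s = e_s, P_max = p_max, weights = weights[keep],
         weight_mode = weight_mode, skipped = skipped),
    class = "conditional_scores")
}

#' @export
print.conditional_scores <- function(x, ...) {
  cat(sprintf("conditional scores: %d strains x %d conditions (weights: %s)\n",
              nrow(x$S), ncol(x$S), x$weight_mode))
  cat(sprintf("  P_max(AF) = %.4f; S range [%.3f, %.3f]\n",
              x$P_max, min(x$S), max(x$S)))
  invisible(x)
}

#' @export
summary.conditional_scores <- function(object, ...) {
  data.frame(condition = colnames(object$S),
             n_genes = lengths(object$weights),
             mean_S = colMeans(object$S),
             max_S = apply(object$S, 2, max),
             row.names = NULL)
}

#' Maximum attainable conditional score
#'
#' `S_max_{s,c} = sum_{g in set(c)} (1/E_s) * W_{g,c} * log(1 - P_max(AF))`,
#' where `P_max(AF)` is the largest disruption score observed across all
#' genes and strains. Strains with `E_s = 0` get `S_max = 0`.
#'
#' @param weights Named weight vector of the condition's essential genes.
#' @param e_s Strain divergence value(s).
#' @param p_max Panel-wide maximum disruption score, below 1.
#' @return `S_max` value(s), one per element of `e_s`.
#' @export
max_score <- function(weights, e_s, p_max) {
  if (p_max >= 1) stop("'p_max' must be below 1")
  ifelse(e_s == 0, 0, (1 / e_s) * sum(weights) * log1p(-p_max))
}

#' In-silico complementation of one essential gene
#'
#' Predicts whether introducing the reference allele of `gene` would
#' restore growth of `strain` in `condition`: the gene's disruption score
#' is set to zero (with the divergence term `E_s` held fixed) and the
#' drop in the conditional score `delta = S_{s,c} - S'_{s,c}` is
#' reported. Because the score is a sum, `delta` equals the gene's own
#' summand `(1/E_s) * W_{g,c} * log(1 - P_{s,g}(AF))` exactly. The pair
#' is called restorable when `delta > 0.01 * S_max_{s,c}`.
#'
#' @param cs A [conditional_score()] result.
#' @param dm The [disruption_matrix()] it was computed from.
#' @param strain,condition,gene Identifiers; `gene` must belong to the
#'   condition's essential set.
#' @return List with `delta`, `s_max` and `restorable`.
#' @export
complement_delta <- function(cs, dm, strain, condition, gene) {
  w <- cs$weights[[condition]]
  if (is.null(w)) stop("unknown condition: ", condition)
  if (!gene %in% names(w))
    stop("gene '", gene, "' is not in the essential set of '", condition, "'")
  e <- cs$E_s[[strain]]
  inv_e <- if (e == 0) 0 else 1 / e
  delta <- inv_e * w[[gene]] * log1p(-unclass(dm)[strain, gene])
  s_max <- cs$S_max[strain, condition]
  list(delta = unname(delta), s_max = unname(s_max),
       restorable = unname(delta > 0.01 * s_max))
}

#' All in-silico complementations of a panel
#'
#' Runs [complement_delta()] for every strain, condition and essential
#' gene of the panel.
#'
#' @inheritParams complement_delta
#' @return Data frame with columns strain, condition, gene, delta, s_max,
#'   restorable.
#' @export
complement_all <- function(cs, dm) {
  m <- unclass(dm)
  logm <- log1p(-m)
  inv_e <- ifelse(cs$E_s == 0, 0, 1 / cs$E_s)
  out <- vector("list", ncol(cs$S))
  for (i in seq_len(ncol(cs$S))) {
    cond <- colnames(cs$S)[i]
    w <- cs$weights[[cond]]
    delta <- logm[, names(w), drop = FALSE] *
      rep(w, each = nrow(m)) * inv_e + 0
    out[[i]] <- data.frame(
      strain = rep(rownames(m), times = length(w)),
      condition = cond,
      gene = rep(names(w), each = nrow(m)),
      delta = as.vector(delta),
      s_max = rep(cs$S_max[, i], times = length(w)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$restorable <- res$delta > 0.01 * res$s_max
  rownames(res) <- NULL
  res
}

#' Predicted restored phenotypes per gene
#'
#' Counts, for each gene, the (strain, condition) pairs whose growth
#' defect it is predicted to restore.
#'
#' @param deltas Output of [complement_all()].
#' @return Named integer vector sorted in decreasing order, one entry per
#'   gene appearing in `deltas`.
#' @export
restoration_counts <- function(deltas) {
  counts <- tapply(deltas$restorable, deltas$gene, sum)
  sort(stats::setNames(as.integer(counts), names(counts)), decreasing = TRUE)
}
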