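# Median colony-size windows (pixels) for time-point eligibility: plates
# of natural isolates vs plates of evolved clones, which grow less.
SIZE_WINDOWS <- list(natural = c(1900, 3600), evolved = c(1300, 3600))

#' Pick the best imaging time point of one condition-plate
#'
#' Eligible time points have a median colony size inside the plate-class
#' window (1900-3600 pixels for natural-isolate plates, 1300-3600 for
#' evolved-clone plates). Eligible time points are ranked
#' lexicographically by: proportion of colonies with circularity > 0.8
#' (higher first), proportion of colonies above the lower size bound
#' (higher first), colony-size IQR (lower first), and mean pairwise
#' correlation of per-strain replicate sizes (higher first). If no time
#' point is eligible, the one with median size closest to the window is
#' returned, flagged.
#'
#' @param records Colony records of one condition-plate across time
#'   points (columns timepoint, strain, replicate, size, circularity).
#' @param plate_class `"natural"` or `"evolved"`.
#' @return List with `timepoint` (the chosen id), `eligible` (logical
#'   flag, `FALSE` when the fallback fired) and `ranking` (data frame of
#'   the ranking keys per time point).
#' @export
select_timepoint <- function(records, plate_class = c("natural", "evolved")) {
  plate_class <- match.arg(plate_class)
  win <- SIZE_WINDOWS[[plate_class]]
  stopifnot(nrow(records) > 0)
  tps <- unique(records$timepoint)
  keys <- lapply(tps, function(tp) {
    r <- records[records$timepoint == tp, , drop = FALSE]
    med <- stats::median(r$size)
    # replicate correlation: per-strain size vectors across replicate slots
    rc <- NA_real_
    wide <- tapply(r$size, list(r$strain, r$replicate), mean)
    if (!is.null(dim(wide)) && ncol(wide) >= 2 && nrow(wide) >= 3) {
      cm <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
      rc <- mean(cm[upper.tri(cm)], na.rm = TRUE)
    }
    data.frame(timepoint = tp, median_size = med,
               eligible = med >= win[1] & med <= win[2],
               prop_round = mean(r$circularity > 0.8),
               prop_above_min = mean(r$size >= win[1]),
               iqr = stats::IQR(r$size),
               rep_cor = rc)
  })
  ranking <- do.call(rbind, keys)
  if (any(ranking$eligible)) {
    el <- ranking[ranking$eligible, , drop = FALSE]
    rc <- ifelse(is.na(el$rep_cor), -Inf, el$rep_cor)
    o <- order(-el$prop_round, -el$prop_above_min, el$iqr, -rc)
    list(timepoint = el$timepoint[o[1]], eligible = TRUE, ranking = ranking)
  } else {
    dist_to_win <- pmax(win[1] - ranking$median_size,
                        ranking$median_size - win[2], 0)
    list(timepoint = ranking$timepoint[which.min(dist_to_win)],
         eligible = FALSE, ranking = ranking)
  }
}

#' Remove mis-recognized and systematically missing colonies
#'
#' Three removal rules, each logged:
#' \describe{
#'   \item{`missing`}{a colony position (strain + replicate slot) with
#'     zero size in more than 66\% of the tested plates of the condition
#'     is a systematic pinning defect; its zero records are removed,
#'     *unless* all the strain's internal replicates on that plate are
#'     zero (then the absence is a genuine growth phenotype and is
#'     kept).}
#'   \item{`small_irregular`}{size < 1000 pixels and circularity < 0.5.}
#'   \item{`large_irregular`}{size >= 1000 pixels and circularity < 0.3.}
#' }
#'
#' @param records Colony records of one condition (all replicate plates;
#'   columns plate, strain, replicate, size, circularity).
#' @return List with `retained` (records), `removed` (records plus a
#'   `rule` column) and `log` (removal counts per rule). Counts satisfy
#'   `nrow(input) == nrow(retained) + nrow(removed)`.
#' @export
qc_filter <- function(records) {
  stopifnot(all(c("plate", "strain", "replicate", "size", "circularity") %in%
                  names(records)))
  rule <- rep(NA_character_, nrow(records))

  ## (a) systematic pinning defects across plates
  n_plates <- length(unique(records$plate))
  slot <- paste(records$strain, records$replicate, sep = "\r")
  zero_plates <- tapply(records$size == 0, slot, sum)
  frac_zero <- zero_plates[slot] / n_plates
  all_reps_zero <- stats::ave(records$size, records$plate, records$strain,
                              FUN = function(x) all(x == 0)) == 1
  sys_missing <- records$size == 0 & frac_zero > 2 / 3 & !all_reps_zero
  rule[sys_missing] <- "missing"

  ## (b) & (c) colony-recognition artifacts
  b <- is.na(rule) & records$size < 1000 & records$circularity < 0.5
  rule[b] <- "small_irregular"
  cc <- is.na(rule) & records$size >= 1000 & records$circularity < 0.3
  rule[cc] <- "large_irregular"

  removed <- records[!is.na(rule), , drop = FALSE]
  if (nrow(removed)) removed$rule <- rule[!is.na(rule)]
  else removed$rule <- character(0)
  list(retained = records[is.na(rule), , drop = FALSE],
       removed = removed,
       log = c(missing = sum(rule == "missing", na.rm = TRUE),
               small_irregular = sum(rule == "small_irregular", na.rm = TRUE),
               large_irregular = sum(rule == "large_irregular", na.rm = TRUE)))
}

#' Correct the edge effect of a colony plate
#'
#' Colonies in the two outermost rows and columns grow larger (more
#' nutrients); their sizes are scaled multiplicatively so that the edge
#' median matches the median of the rest of the plate. Interior colonies
#' are untouched. A zero edge median disables the correction (flagged).
#'
#' @param records Colony records of one plate (columns row, col, size).
#' @return The records with corrected sizes; attributes `"factor"` (the
#'   multiplier applied) and `"flagged"` (`TRUE` when the correction was
#'   skipped).
#' @export
edge_correction <- function(records) {
  nr <- max(records$row); nc <- max(records$col)
  if (nr < 5 || nc < 5) stop("edge correction needs at least a 5x5 grid")
  edge <- records$row <= 2 | records$row > nr - 2 |
    records$col <= 2 | records$col > nc - 2
  med_edge <- stats::median(records$size[edge])
  med_int <- stats::median(records$size[!edge])
  if (med_edge == 0) {
    attr(records, "factor") <- 1
    attr(records, "flagged") <- TRUE
    return(records)
  }
  f <- med_int / med_edge
  records$size[edge] <- records$size[edge] * f
  attr(records, "factor") <- f
  attr(records, "flagged") <- FALSE
  records
}

#' Flag a contaminated replicate by variance jackknife
#'
#' Each replicate's contribution to the replicate-set variance is
#' `1 - var(remaining) / var(all)` (sample variance). The replicate with
#' the largest contribution is flagged as a putative contamination when
#' its contribution exceeds 90\% (colony size) or 95\% (circularity). At
#' most one replicate is flagged per call; a zero-variance set flags
#' nothing.
#'
#' @param values Replicate measurements (>= 3 non-missing needed).
#' @param metric `"size"` (threshold 0.90) or `"circularity"` (0.95).
#' @return Integer index of the flagged replicate, or `integer(0)`.
#' @examples
#' jackknife_flags(c(100, 100, 100, 1000))  # 4
#' @export
jackknife_flags <- function(values, metric = c("size", "circularity")) {
  metric <- match.arg(metric)
  threshold <- if (metric == "size") 0.90 else 0.95
  ok <- which(!is.na(values))
  if (length(ok) < 3) stop("need at least 3 non-missing replicates")
  v_all <- stats::var(values[ok])
  if (v_all == 0) return(integer(0))
  contrib <- vapply(ok, function(i)
    1 - stats::var(values[setdiff(ok, i)]) / v_all, numeric(1))
  best <- which.max(contrib)
  if (contrib[best] > threshold) ok[best] else integer(0)
}

#' Simplified S-score from filtered colony sizes
#'
#' Deviation of each strain's growth in each condition from that strain's
#' expected growth, as a pooled modified t-score:
#' `S = (mean_cond - mean_ref) / sqrt(sigma^2 * (1/n_cond + 1/n_ref))`,
#' where the reference mean and variance pool the strain's replicate
#' sizes across all conditions, and `sigma` is floored at the plate-wide
#' median replicate standard deviation so that artificially quiet
#' replicate sets do not inflate scores. Negative S means the strain grew
#' less than expected. Cells with fewer than 2 replicates, and strains
#' measured in fewer than 5 conditions, are NA.
#'
#' @param sizes Data frame with columns strain, condition, size (one row
#'   per surviving replicate).
#' @return Strains x conditions numeric matrix of S-scores with an
#'   `"n_replicates"` attribute (surviving replicates per cell).
#' @export
sscore_matrix <- function(sizes) {
  stopifnot(all(c("strain", "condition", "size") %in% names(sizes)))
  strains <- sort(unique(sizes$strain))
  conds <- sort(unique(sizes$condition))
  cell_sd <- tapply(sizes$size, list(sizes$strain, sizes$condition),
                    stats::sd)
  sd_floor <- stats::median(cell_sd, na.rm = TRUE)
  S <- nrep <- matrix(NA_real_, length(strains), length(conds),
                      dimnames = list(strains, conds))
  for (st in strains) {
    r <- sizes[sizes$strain == st, , drop = FALSE]
    if (length(unique(r$condition)) < 5) next
    for (cd in unique(r$condition)) {
      x <- r$size[r$condition == cd]
      ref <- r$size[r$condition != cd]
      nrep[st, cd] <- length(x)
      if (length(x) < 2 || length(ref) < 2) next
      sigma2 <- max(stats::var(ref), sd_floor^2)
      S[st, cd] <- (mean(x) - mean(ref)) /
        sqrt(sigma2 * (1 / length(x) + 1 / length(ref)))
    }
  }
  attr(S, "n_replicates") <- nrep
  S
}

#' Quantile-normalize S-scores and call growth defects
#'
#' Each condition's S-score vector is quantile-normalized to the average
#' empirical distribution across conditions. A null normal is then
#' fitted robustly (median and MAD) to the normalized matrix; one-sided
#' lower-tail p-values are corrected by Benjamini-Hochberg, and cells
#' passing the FDR cut with a negative S-score are called growth
#' defects. Positive deviations are never called.
#'
#' @param S Strains x conditions S-score matrix (NA allowed).
#' @param fdr FDR level for the defect calls (default 0.05).
#' @return An object of class `phenotype_matrix`: list with `sscores`
#'   (normalized matrix), `calls` (0/1 matrix, NA where S is NA), `fdr`,
#'   and `null` (the fitted null's location/scale).
#' @export
normalize_and_call <- function(S, fdr = 0.05) {
  stopifnot(is.matrix(S), nrow(S) > 0, ncol(S) > 0)
  all_na <- colSums(!is.na(S)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-NA conditions dropped")
    S <- S[, !all_na, drop = FALSE]
  }
  N <- limma::normalizeQuantiles(S)
  dimnames(N) <- dimnames(S)
  mu <- stats::median(N, na.rm = TRUE)
  sigma <- stats::mad(N, na.rm = TRUE)
  if (sigma == 0) stop("degenerate S-score matrix: zero spread")
  p <- stats::pnorm(N, mean = mu, sd = sigma)
  q <- p
  q[] <- stats::p.adjust(p, method = "BH")
  calls <- (q <= fdr & N < mu) * 1
  calls[is.na(N)] <- NA
  structure(list(sscores = N, calls = calls, fdr = fdr,
                 null = c(location = mu, scale = sigma)),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotypes: %d strains x %d conditions; %d defect calls (FDR %g)\n",
              nrow(x$sscores), ncol(x$sscores),
              sum(x$calls == 1, na.rm = TRUE), x$fdr))
  cat(sprintf("  null fit: location %.3f, scale %.3f\n",
              x$null["location"], x$null["scale"]))
  invisible(x)
}

#' Full colony-plate QC chain
#'
#' Convenience wrapper for one condition's raw colony tables: selects a
#' time point per plate, removes artifacts ([qc_filter()]), corrects the
#' plate edge effect ([edge_correction()]) and drops jackknife-flagged
#' contaminations ([jackknife_flags()]).
#'
#' @param colonies Colony records (columns plate, timepoint, row, col,
#'   strain, replicate, size, circularity).
#' @param plate_class Passed to [select_timepoint()].
#' @return List with `sizes` (clean records), `removed`, `flagged`
#'   (records dropped by the jackknife) and `timepoints` (chosen per
#'   plate).
#' @export
process_plates <- function(colonies, plate_class = c("natural", "evolved")) {
  plate_class <- match.arg(plate_class)
  chosen <- lapply(split(colonies, colonies$plate),
                   select_timepoint, plate_class = plate_class)
  tp <- vapply(chosen, `[[`, FUN.VALUE = colonies$timepoint[1], "timepoint")
  keep <- colonies$timepoint == tp[as.character(colonies$plate)]
  recs <- colonies[keep, , drop = FALSE]
  flt <- qc_filter(recs)
  recs <- flt$retained
  recs <- do.call(rbind, lapply(split(recs, recs$plate), edge_correction))
  rownames(recs) <- NULL
  flag <- rep(FALSE, nrow(recs))
  key_vec <- paste(recs$plate, recs$strain, sep = "\r")
  for (idx in split(seq_len(nrow(recs)), key_vec)) {
    if (length(idx) < 3) next
    f <- jackknife_flags(recs$size[idx], "size")
    if (length(f)) flag[idx[f]] <- TRUE
    f2 <- jackknife_flags(recs$circularity[idx], "circularity")
    if (length(f2)) flag[idx[f2]] <- TRUE
  }
  list(sizes = recs[!flag, , drop = FALSE],
       removed = flt$removed,
       flagged = recs[flag, , drop = FALSE],
       timepoints = tp)
}
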