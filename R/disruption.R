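# Disruption-score cap: an absent gene gets P(neutral) 0.01, i.e. a
# disruption of 0.99, the largest single-event disruption defined; capping
# SNV-based scores at the same value keeps log(1 - P(AF)) finite downstream.
PAF_CAP <- 0.99

#' Cluster strains by phylogenetic distance
#'
#' Single-linkage clustering of the strain panel, cut at a fixed distance
#' threshold. Closely related strains (e.g. clones from an evolution
#' experiment) collapse into one cluster so that the allele-frequency
#' filter counts independent lineages rather than sequenced genomes.
#'
#' @param distances Square symmetric numeric matrix with zero diagonal and
#'   strain ids as dimnames, or a `dist` object.
#' @param threshold Height at which the single-linkage dendrogram is cut;
#'   0 keeps every (distinct) strain in its own cluster.
#' @return Named integer vector of cluster ids, one per strain.
#' @export
cluster_strains <- function(distances, threshold = 0.001) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  if (any(distances < 0)) stop("negative distances")
  if (any(abs(distances - t(distances)) > 1e-12))
    stop("distance matrix is not symmetric")
  if (any(diag(distances) != 0)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(distances)))
    rownames(distances) <- colnames(distances) <- paste0("S", seq_len(nrow(distances)))
  if (nrow(distances) == 1L)
    return(stats::setNames(1L, rownames(distances)))
  hc <- stats::hclust(stats::as.dist(distances), method = "single")
  stats::cutree(hc, h = threshold)
}

# one frequency "vote" per cluster: fraction of clusters with >= 1 carrier
.cluster_frequency <- function(carrier_strains, clusters) {
  length(unique(clusters[carrier_strains])) / length(unique(clusters))
}

# identity of a variant across strains, for frequency counting
.variant_key <- function(variants) {
  pos <- if ("position" %in% names(variants)) variants$position else NA
  paste(variants$gene, variants$class, ifelse(is.na(pos), "", pos), sep = "\r")
}

#' Allele-frequency and founder filtering of variants and gene absences
#'
#' Variants observed at high frequency across the panel are unlikely to be
#' deleterious and are removed: a variant's frequency is the fraction of
#' phylogenetic clusters containing at least one carrier, and variants at
#' or above `freq_threshold` (>= 10\% by default, inclusive) are dropped.
#' Reference genes absent in at least that fraction of clusters generate
#' no absence events for any strain. Variants and absences shared by
#' *every* member of a declared founder group (e.g. all clones descending
#' from one evolution-experiment ancestor) are removed for that group,
#' since they were present in the founder.
#'
#' Strain-level counting (one vote per strain instead of per cluster) is
#' available via `frequency_unit`.
#'
#' @param variants Variant table (see [read_variants()]).
#' @param presence Strains x genes logical/0-1 matrix; `FALSE`/0 marks a
#'   reference gene absent from a strain.
#' @param clusters Named cluster assignment from [cluster_strains()]; if
#'   `NULL` every strain is its own cluster.
#' @param founder_groups Optional named list of character vectors of
#'   strain ids.
#' @param freq_threshold Frequency at/above which events are removed.
#' @param frequency_unit `"cluster"` (default) or `"strain"`.
#' @return A list with `variants` (retained rows, plus a `frequency`
#'   column), `absences` (data frame strain/gene of retained absence
#'   events) and `log` (counts removed per rule).
#' @export
apply_frequency_filters <- function(variants, presence, clusters = NULL,
                                    founder_groups = NULL,
                                    freq_threshold = 0.10,
                                    frequency_unit = c("cluster", "strain")) {
  frequency_unit <- match.arg(frequency_unit)
  stopifnot(is.numeric(freq_threshold), freq_threshold > 0, freq_threshold <= 1)
  strains <- rownames(presence)
  if (is.null(strains)) stop("'presence' needs strain rownames")
  if (is.null(clusters)) clusters <- stats::setNames(seq_along(strains), strains)
  if (frequency_unit == "strain")
    clusters <- stats::setNames(seq_along(strains), strains)
  if (!all(variants$strain %in% names(clusters)))
    stop("variant table names strains missing from the cluster assignment")
  if (!is.null(founder_groups)) {
    unknown <- setdiff(unlist(founder_groups), strains)
    if (length(unknown))
      stop("founder group names unknown strains: ",
           paste(unknown, collapse = ", "))
  }
  n_clu <- length(unique(clusters))
  log_counts <- c(variant_frequency = 0L, variant_founder = 0L,
                  absence_frequency = 0L, absence_founder = 0L)

  ## --- variants: frequency filter (whole variant removed) ---
  key <- .variant_key(variants)
  freq_by_key <- vapply(split(variants$strain, key),
                        .cluster_frequency, numeric(1), clusters = clusters)
  freq <- freq_by_key[key]
  keep <- freq < freq_threshold
  log_counts["variant_frequency"] <- sum(!keep)
  variants <- variants[keep, , drop = FALSE]
  freq <- freq[keep]
  key <- key[keep]

  ## --- variants: founder exclusion (removed for group members only) ---
  if (!is.null(founder_groups) && nrow(variants)) {
    drop <- rep(FALSE, nrow(variants))
    for (grp in founder_groups) {
      carriers_by_key <- split(variants$strain, key)
      shared <- vapply(carriers_by_key, function(s) all(grp %in% s), logical(1))
      drop <- drop | (key %in% names(carriers_by_key)[shared] &
                        variants$strain %in% grp)
    }
    log_counts["variant_founder"] <- sum(drop)
    variants <- variants[!drop, , drop = FALSE]
    freq <- freq[!drop]
  }
  variants$frequency <- unname(freq)

  ## --- absences ---
  pres <- presence != 0
  absent_frac <- apply(!pres, 2, function(a) .cluster_frequency(strains[a], clusters))
  common_absent <- absent_frac >= freq_threshold
  idx <- which(!pres & !matrix(common_absent, nrow(pres), ncol(pres), byrow = TRUE),
               arr.ind = TRUE)
  log_counts["absence_frequency"] <-
    sum(!pres) - nrow(idx)
  absences <- data.frame(strain = strains[idx[, 1]],
                         gene = colnames(pres)[idx[, 2]],
                         stringsAsFactors = FALSE)
  if (!is.null(founder_groups) && nrow(absences)) {
    drop <- rep(FALSE, nrow(absences))
    for (grp in founder_groups) {
      by_gene <- split(absences$strain, absences$gene)
      shared <- vapply(by_gene, function(s) all(grp %in% s), logical(1))
      drop <- drop | (absences$gene %in% names(by_gene)[shared] &
                        absences$strain %in% grp)
    }
    log_counts["absence_founder"] <- sum(drop)
    absences <- absences[!drop, , drop = FALSE]
  }
  rownames(variants) <- rownames(absences) <- NULL
  list(variants = variants, absences = absences, log = log_counts)
}

#' Disruption score of one strain-gene from its retained variants
#'
#' The probability that the gene's function is affected:
#' `P(AF) = 1 - prod(P_i(neutral))` over the gene's retained variants,
#' capped at 0.99. An absent gene scores 0.99 outright; a present gene
#' with no retained variants scores 0.
#'
#' @param p_neutral Neutrality probabilities of the retained variants.
#' @param absent Is the gene absent from the strain?
#' @return A single disruption probability in \[0, 0.99\].
#' @examples
#' gene_disruption(c(0.5, 0.5))  # 0.75
#' @export
gene_disruption <- function(p_neutral = numeric(0), absent = FALSE) {
  if (absent) return(PAF_CAP)
  if (!length(p_neutral)) return(0)
  if (any(!is.finite(p_neutral)) || any(p_neutral <= 0 | p_neutral > 1))
    stop("P(neutral) values must lie in (0, 1]")
  min(1 - prod(p_neutral), PAF_CAP)
}

#' Strains x genes disruption matrix
#'
#' Runs the full per-gene aggregation: computes P(neutral) for every
#' variant, clusters strains, applies the frequency/founder filters, and
#' aggregates retained variants and absence events into the disruption
#' score P(AF) for every strain and reference gene.
#'
#' @param variants Variant table (columns strain, gene, class, position,
#'   length, sift_p, foldx_ddg).
#' @param presence Strains x genes 0/1 matrix (reference genes as columns).
#' @param distances Optional strain distance matrix for clustering; if
#'   `NULL`, every strain is its own cluster.
#' @param models Calibration models, see [default_calibrations()].
#' @param cluster_threshold Single-linkage cut height, see
#'   [cluster_strains()].
#' @param freq_threshold,founder_groups,frequency_unit Passed to
#'   [apply_frequency_filters()].
#' @return An object of class `disruption_matrix`: a strains x genes
#'   numeric matrix with attributes `provenance` (character matrix,
#'   `"variants"`, `"absence"` or `"none"` per cell), `clusters`, and
#'   `filter_log`.
#' @export
disruption_matrix <- function(variants, presence, distances = NULL,
                              models = default_calibrations(),
                              cluster_threshold = 0.001,
                              freq_threshold = 0.10,
                              founder_groups = NULL,
                              frequency_unit = c("cluster", "strain")) {
  stopifnot(is.matrix(presence))
  strains <- rownames(presence); genes <- colnames(presence)
  clusters <- if (is.null(distances)) NULL
              else cluster_strains(distances, cluster_threshold)[strains]
  flt <- apply_frequency_filters(variants, presence, clusters,
                                 founder_groups, freq_threshold,
                                 frequency_unit)
  v <- flt$variants
  m <- matrix(0, length(strains), length(genes),
              dimnames = list(strains, genes))
  prov <- matrix("none", length(strains), length(genes),
                 dimnames = list(strains, genes))
  if (nrow(v)) {
    v <- v[v$strain %in% strains & v$gene %in% genes, , drop = FALSE]
    pn <- p_neutral_variant(v, models)
    cell <- paste(v$strain, v$gene, sep = "\r")
    paf <- vapply(split(pn, cell), gene_disruption, numeric(1))
    parts <- do.call(rbind, strsplit(names(paf), "\r", fixed = TRUE))
    ij <- cbind(match(parts[, 1], strains), match(parts[, 2], genes))
    m[ij] <- paf
    prov[ij] <- "variants"
  }
  if (nrow(flt$absences)) {
    a <- flt$absences
    a <- a[a$strain %in% strains & a$gene %in% genes, , drop = FALSE]
    ij <- cbind(match(a$strain, strains), match(a$gene, genes))
    m[ij] <- PAF_CAP          # absence wins over any called variant
    prov[ij] <- "absence"
  }
  structure(m, provenance = prov, clusters = clusters,
            filter_log = flt$log,
            class = c("disruption_matrix", "matrix", "array"))
}

#' @export
print.disruption_matrix <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("disruption matrix: %d strains x %d genes\n", nrow(x), ncol(x)))
  cat(sprintf("  cells from variants: %d, from absence: %d, zero: %d\n",
              sum(prov == "variants"), sum(prov == "absence"),
              sum(prov == "none")))
  cat(sprintf("  mean P(AF) %.4f, max %.4f\n", mean(x), max(x)))
  invisible(x)
}

#' Gene-gene correlation of disruption profiles
#'
#' Pearson correlation of disruption scores across strains for every pair
#' of genes, used as a functional-association predictor: genes disrupted
#' in the same strains (e.g. members of one operon or complex) correlate.
#'
#' @param dm A [disruption_matrix()] (or plain strains x genes matrix).
#' @return Symmetric correlation matrix over the genes with nonzero
#'   variance; dropped genes are reported in the `"dropped"` attribute.
#' @export
disruption_correlation <- function(dm) {
  m <- unclass(dm)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (nrow(m) < 3L) stop("need at least 3 strains")
  v <- apply(m, 2, stats::var)
  dropped <- colnames(m)[v == 0]
  if (length(dropped))
    message(length(dropped), " zero-variance genes excluded from correlation")
  r <- stats::cor(m[, v > 0, drop = FALSE])
  attr(r, "dropped") <- dropped
  r
}
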