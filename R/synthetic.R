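#' Labeled mutation set for calibration fitting
#'
#' Draws predictor values log-uniformly on \[1e-5, 1\] and labels each as
#' tolerated with probability given by the logistic
#' `plogis(slope * log(value + pseudocount) + intercept)` — the same
#' family [fit_calibration()] estimates, so refitting a generated set
#' recovers the generating coefficients.
#'
#' @param n Number of mutations (>= 1).
#' @param slope,intercept,pseudocount Generating logistic; defaults are
#'   the shipped SIFT calibration.
#' @param seed Integer seed; the set is reproducible bit-for-bit.
#' @return Data frame with columns `value` and `tolerated`.
#' @export
gen_labeled_mutations <- function(n, slope = 0.625, intercept = 1.971,
                                  pseudocount = 1.527e-4, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("'pseudocount' must be positive")
  if (!is.null(seed)) set.seed(seed)
  value <- 10^stats::runif(n, -5, 0)
  p <- stats::plogis(slope * log(value + pseudocount) + intercept)
  data.frame(value = value,
             tolerated = stats::runif(n) < p)
}

#' Parameters of the synthetic strain panel
#'
#' Defaults describe a desk-scale panel with the statistical structure
#' the pipeline assumes: rare per-strain gene losses planted as
#' deleterious variants or gene absences, a background load of neutral
#' nonsynonymous variants, condition-specific essential-gene sets with
#' screen-style FDR p-values, and phylogenetic distances from a random
#' tree.
#'
#' @param variant_rate Mean number of background *neutral*
#'   nonsynonymous variants per gene and strain (Poisson over the
#'   panel, spread uniformly over genes), so the background load scales
#'   with the gene panel. This load is a noise source for the
#'   conditional score: the divergence correction amplifies whatever
#'   little disruption a near-reference strain carries, so set 0 for a
#'   noiseless panel.
#' @param p_lost Per strain-gene probability that a conditionally
#'   essential gene's function is lost (the planted causal events).
#' @param frac_noncausal Fraction of all planted loss events that hit
#'   genes essential in no condition (deleterious but phenotypically
#'   silent); 0 disables them.
#' @param frac_absent Fraction of loss events realized as a gene absence
#'   rather than a deleterious variant.
#' @param frac_essential Fraction of the gene panel that is essential in
#'   each condition.
#' @param fdr_range Range for the essentiality FDR p-values, sampled
#'   log-uniformly; must lie inside (0, 1).
#' @param flip_rate Default phenotype label-flip rate recorded in the
#'   ground truth (applied by [gen_phenotypes()]).
#' @return Named list of parameters.
#' @export
panel_params <- function(variant_rate = 0.1,
                         p_lost = 0.005,
                         frac_noncausal = 0.3,
                         frac_absent = 0.3,
                         frac_essential = 0.03,
                         fdr_range = c(1e-6, 0.05),
                         flip_rate = 0) {
  fracs <- c(frac_noncausal = frac_noncausal, frac_absent = frac_absent,
             frac_essential = frac_essential, flip_rate = flip_rate,
             p_lost = p_lost)
  if (any(fracs < 0 | fracs > 1))
    stop("fraction parameters must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (variant_rate < 0) stop("'variant_rate' must be non-negative")
  if (any(fdr_range <= 0) || any(fdr_range >= 1))
    stop("'fdr_range' must lie inside (0, 1)")
  list(variant_rate = variant_rate, p_lost = p_lost,
       frac_noncausal = frac_noncausal, frac_absent = frac_absent,
       frac_essential = frac_essential, fdr_range = fdr_range,
       flip_rate = flip_rate)
}

# deleterious variant classes planted in lost genes, and their mix
.DELETERIOUS_MIX <- c(missense_sift = 0.40, missense_foldx = 0.15,
                      nonsense = 0.30, start_loss = 0.075, stop_loss = 0.075)

.new_variant_row <- function(strain, gene, class, position, length,
                             sift_p, foldx_ddg) {
  data.frame(strain = strain, gene = gene, class = class,
             position = position, length = length,
             sift_p = sift_p, foldx_ddg = foldx_ddg,
             stringsAsFactors = FALSE)
}

.empty_variants <- function() {
  data.frame(strain = character(0), gene = character(0),
             class = character(0), position = numeric(0),
             length = numeric(0), sift_p = numeric(0),
             foldx_ddg = numeric(0), stringsAsFactors = FALSE)
}

#' Synthetic strain panel with planted ground truth
#'
#' Generates every input of the genotype-to-phenotype pipeline plus the
#' ground truth needed for parameter-recovery tests. Each planted "lost"
#' gene carries exactly one clearly deleterious event — a very low SIFT
#' probability, a strongly destabilizing FoldX value, a premature stop
#' outside the last 16 residues, a start/stop loss, or a gene absence —
#' while intact genes carry only neutral background variants (SIFT p in
#' \[0.2, 1\] or |ddG| <= 0.5 kcal/mol, plus the occasional harmless
#' late-stop nonsense). A strain has a true growth defect in a condition
#' iff at least one of the condition's essential genes is lost in it.
#'
#' @param n_strains,n_genes,n_conditions Panel dimensions (>= 2, >= 1,
#'   >= 1).
#' @param params See [panel_params()].
#' @param seed Integer seed; regeneration is bit-for-bit identical.
#' @return An object of class `strain_panel`: list with `variants`,
#'   `presence` (strains x genes 0/1 matrix), `essentiality`
#'   (an [essentiality_table()]), `distances` (symmetric, zero-diagonal)
#'   and `truth` (class `ground_truth`: `lost` strains x genes logical
#'   matrix, `essential_sets`, `defect` strains x conditions logical
#'   matrix, `gene_length`, `seed`, `noise`).
#' @export
gen_strain_panel <- function(n_strains, n_genes, n_conditions,
                             params = panel_params(), seed = 1L) {
  if (n_strains < 2) stop("'n_strains' must be at least 2")
  if (n_genes < 1 || n_conditions < 1)
    stop("'n_genes' and 'n_conditions' must be positive")
  set.seed(seed)
  strains <- sprintf("S%03d", seq_len(n_strains))
  genes <- sprintf("g%04d", seq_len(n_genes))
  conditions <- sprintf("cond%02d", seq_len(n_conditions))
  gene_length <- stats::setNames(sample(100:600, n_genes, replace = TRUE), genes)

  ## conditionally essential sets and their screen p-values
  l_c <- max(1L, ceiling(params$frac_essential * n_genes))
  essential_sets <- lapply(conditions, function(cd) sample(genes, l_c))
  names(essential_sets) <- conditions
  lr <- log10(params$fdr_range)
  ess <- data.frame(
    condition = rep(conditions, each = l_c),
    gene = unlist(essential_sets),
    fdr_p = 10^stats::runif(l_c * n_conditions, lr[1], lr[2]),
    stringsAsFactors = FALSE)
  essential_any <- unique(ess$gene)

  ## planted loss events
  lost <- matrix(FALSE, n_strains, n_genes, dimnames = list(strains, genes))
  ess_idx <- match(essential_any, genes)
  lost[, ess_idx] <- stats::runif(n_strains * length(ess_idx)) < params$p_lost
  non_idx <- setdiff(seq_len(n_genes), ess_idx)
  if (length(non_idx) && params$frac_noncausal > 0 &&
      params$frac_noncausal < 1) {
    # non-causal rate chosen so the expected share of silent losses among
    # all planted losses equals frac_noncausal
    rate_non <- params$p_lost * params$frac_noncausal /
      (1 - params$frac_noncausal) * length(ess_idx) / length(non_idx)
    lost[, non_idx] <- stats::runif(n_strains * length(non_idx)) <
      min(rate_non, 1)
  }

  ## realize losses as absences or deleterious variants
  presence <- matrix(1, n_strains, n_genes, dimnames = list(strains, genes))
  loss_at <- which(lost, arr.ind = TRUE)
  del_rows <- .empty_variants()
  if (nrow(loss_at)) {
    as_absence <- stats::runif(nrow(loss_at)) < params$frac_absent
    presence[loss_at[as_absence, , drop = FALSE]] <- 0
    vi <- loss_at[!as_absence, , drop = FALSE]
    if (nrow(vi)) {
      cls <- sample(names(.DELETERIOUS_MIX), nrow(vi), replace = TRUE,
                    prob = .DELETERIOUS_MIX)
      len <- gene_length[vi[, 2]]
      pos <- ifelse(cls %in% c("missense_sift", "missense_foldx"),
                    sample.int(600, nrow(vi), replace = TRUE) %% len + 1,
             ifelse(cls == "nonsense",
                    floor(stats::runif(nrow(vi)) * (len - 16)) + 1,
                    NA_real_))
      del_rows <- .new_variant_row(
        strain = strains[vi[, 1]], gene = genes[vi[, 2]],
        class = ifelse(cls %in% c("missense_sift", "missense_foldx"),
                       "missense", cls),
        position = pos, length = unname(len),
        sift_p = ifelse(cls == "missense_sift",
                        stats::runif(nrow(vi), 0, 1e-4), NA_real_),
        foldx_ddg = ifelse(cls == "missense_foldx",
                           stats::runif(nrow(vi), -5, -3), NA_real_))
    }
  }

  ## background neutral variants in intact, present genes
  n_bg <- stats::rpois(n_strains, params$variant_rate * n_genes)
  bg_rows <- .empty_variants()
  if (sum(n_bg)) {
    bs <- rep(seq_len(n_strains), n_bg)
    bg <- sample.int(n_genes, sum(n_bg), replace = TRUE)
    ok <- !lost[cbind(bs, bg)]          # never touch planted-lost genes
    bs <- bs[ok]; bg <- bg[ok]
    if (length(bs)) {
      kind <- sample(c("sift", "foldx", "late_stop"), length(bs),
                     replace = TRUE, prob = c(0.8, 0.1, 0.1))
      len <- gene_length[bg]
      pos <- ifelse(kind == "late_stop",
                    len - sample.int(15, length(bs), replace = TRUE) + 1,
                    sample.int(600, length(bs), replace = TRUE) %% len + 1)
      bg_rows <- .new_variant_row(
        strain = strains[bs], gene = genes[bg],
        class = ifelse(kind == "late_stop", "nonsense", "missense"),
        position = pos, length = unname(len),
        sift_p = ifelse(kind == "sift",
                        stats::runif(length(bs), 0.2, 1), NA_real_),
        foldx_ddg = ifelse(kind == "foldx",
                           stats::runif(length(bs), -0.5, 0.5), NA_real_))
    }
  }
  variants <- rbind(del_rows, bg_rows)
  rownames(variants) <- NULL

  ## phylogeny: random binary tree supplies realistic cluster structure
  tree <- ape::rtree(n_strains, tip.label = strains)
  distances <- stats::cophenetic(tree)[strains, strains]
  diag(distances) <- 0
  distances <- (distances + t(distances)) / 2

  ## ground truth defects: any essential gene of the condition lost
  defect <- vapply(conditions, function(cd)
    rowSums(lost[, essential_sets[[cd]], drop = FALSE]) > 0,
    logical(n_strains))
  dimnames(defect) <- list(strains, conditions)

  truth <- structure(
    list(strains = strains, genes = genes, conditions = conditions,
         lost = lost, essential_sets = essential_sets, defect = defect,
         gene_length = gene_length, seed = seed,
         noise = c(flip_rate = params$flip_rate,
                   frac_noncausal = params$frac_noncausal)),
    class = "ground_truth")
  structure(
    list(variants = variants, presence = presence,
         essentiality = essentiality_table(ess),
         distances = distances, truth = truth, params = params),
    class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("synthetic strain panel: %d strains, %d genes, %d conditions\n",
              length(x$truth$strains), length(x$truth$genes),
              length(x$truth$conditions)))
  cat(sprintf("  %d variants (%d deleterious planted), %d gene absences, %d true defects\n",
              nrow(x$variants), sum(x$truth$lost) - sum(x$presence == 0),
              sum(x$presence == 0), sum(x$truth$defect)))
  invisible(x)
}

#' Phenotypes from a planted ground truth
#'
#' Binary defect calls equal the true defect flags with each label
#' independently flipped with probability `flip_rate`; S-scores are drawn
#' consistently with the calls from a defect-shifted normal (defects
#' N(-4, 1), others N(0, 1)), mimicking an FDR-callable separation.
#'
#' @param truth A `ground_truth` (from [gen_strain_panel()]).
#' @param flip_rate Label-flip probability in \[0, 1\]; defaults to the
#'   rate recorded in the truth object.
#' @param seed Integer seed.
#' @return An object of class `phenotype_matrix` (see
#'   [normalize_and_call()]) with `sscores` and `calls`.
#' @export
gen_phenotypes <- function(truth, flip_rate = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(flip_rate)) flip_rate <- unname(truth$noise["flip_rate"])
  if (flip_rate < 0 || flip_rate > 1) stop("'flip_rate' must lie in [0, 1]")
  set.seed(seed)
  d <- truth$defect
  flip <- matrix(stats::runif(length(d)) < flip_rate, nrow(d), ncol(d))
  calls <- (d != flip) * 1  # XOR
  sc <- matrix(stats::rnorm(length(d), mean = ifelse(calls == 1, -4, 0), sd = 1),
               nrow(d), ncol(d), dimnames = dimnames(d))
  dimnames(calls) <- dimnames(d)
  structure(list(sscores = sc, calls = calls, fdr = NA_real_,
                 null = c(location = 0, scale = 1)),
            class = "phenotype_matrix")
}

#' Synthetic colony-array plates
#'
#' Emulates the per-colony output of plate-image analysis for the
#' replicate plates of one condition: each strain occupies four randomly
#' placed colonies per plate, colony size is the product of a strain
#' effect, a plate effect and a time-point growth factor, and
#' circularity is drawn high (well-formed colonies). Within a plate the
#' four replicates of a clean strain are identical by construction (see
#' the methods vignette: the leave-one-out variance flag would otherwise
#' fire on a fixed fraction of clean replicate sets regardless of the
#' noise scale). Planted artifacts on top of the clean signal:
#' contaminations (one replicate scaled by `contamination_ratio`),
#' systematically missing slots (zero size on every plate), and an
#' edge effect (outermost two rows/columns scaled by `edge_mult`).
#'
#' @param n_plates Number of replicate plates.
#' @param n_rows,n_cols Colony grid (total >= 16; total a multiple of 4).
#' @param n_contaminated Planted contaminations (one replicate each).
#' @param n_missing Planted systematically missing (strain, replicate)
#'   slots.
#' @param edge_mult Multiplier applied to the outermost two rows/columns.
#' @param contamination_ratio Size ratio of a contaminated replicate.
#' @param base_size Mean clean colony size, pixels.
#' @param strain_sd Between-strain size standard deviation. The default
#'   0 makes clean plates exactly uniform: any spread — even between
#'   strains — interacts with the unconditional edge correction (edge
#'   and interior medians of random strain subsets differ slightly, so
#'   the correction perturbs edge members of otherwise-constant
#'   replicate sets) and the scale-free variance flag then fires on
#'   clean colonies.
#' @param circ_base Circularity of clean colonies (constant, for the
#'   same reason as `strain_sd = 0`: the 95\% circularity variance flag
#'   is scale-free).
#' @param timepoint_scale Growth factor per imaging time point; the
#'   default brackets the eligible median-size window.
#' @param seed Integer seed.
#' @return Data frame of colony records (plate, timepoint, row, col,
#'   strain, replicate, size, circularity, opacity) with a `"truth"`
#'   attribute recording planted contaminations and missing slots.
#' @export
gen_colony_plates <- function(n_plates = 3L, n_rows = 32L, n_cols = 48L,
                              n_contaminated = 0L, n_missing = 0L,
                              edge_mult = 1, contamination_ratio = 10,
                              base_size = 2500, strain_sd = 0,
                              circ_base = 0.95,
                              timepoint_scale = c(0.5, 1, 1.5),
                              seed = 1L) {
  n_cells <- n_rows * n_cols
  if (n_cells < 16) stop("grid must hold at least 16 colonies")
  if (n_cells %% 4 != 0) stop("grid size must be a multiple of 4")
  set.seed(seed)
  n_strains <- n_cells %/% 4
  strains <- sprintf("c%03d", seq_len(n_strains))
  strain_eff <- stats::setNames(
    pmax(stats::rnorm(n_strains, base_size, strain_sd), base_size / 4),
    strains)
  plate_eff <- stats::runif(n_plates, 0.95, 1.05)
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    slot <- sample(rep(seq_len(n_strains), each = 4))  # random layout
    rep_idx <- stats::ave(slot, slot, FUN = seq_along)
    base <- strain_eff[slot] * plate_eff[p]
    df <- data.frame(plate = p, row = grid$row, col = grid$col,
                     strain = strains[slot], replicate = rep_idx,
                     size0 = unname(base),
                     circularity = circ_base,
                     opacity = stats::runif(n_cells, 0.5, 1))
    out[[p]] <- df
  }
  colonies <- do.call(rbind, out)

  ## planted contaminations: one grossly outlying replicate
  contam <- NULL
  if (n_contaminated > 0) {
    pick <- sample(nrow(colonies), n_contaminated)
    colonies$size0[pick] <- colonies$size0[pick] * contamination_ratio
    contam <- colonies[pick, c("plate", "strain", "replicate")]
  }
  ## planted systematically missing slots: zero on every plate
  missing <- NULL
  if (n_missing > 0) {
    slots <- unique(colonies[, c("strain", "replicate")])
    ms <- slots[sample(nrow(slots), n_missing), , drop = FALSE]
    hit <- paste(colonies$strain, colonies$replicate) %in%
      paste(ms$strain, ms$replicate)
    colonies$size0[hit] <- 0
    colonies$circularity[hit] <- 0
    missing <- ms
  }
  ## edge effect
  if (edge_mult != 1) {
    edge <- colonies$row <= 2 | colonies$row > n_rows - 2 |
      colonies$col <= 2 | colonies$col > n_cols - 2
    colonies$size0[edge] <- colonies$size0[edge] * edge_mult
  }
  ## unroll time points
  res <- do.call(rbind, lapply(seq_along(timepoint_scale), function(tp) {
    df <- colonies
    df$timepoint <- tp
    df$size <- df$size0 * timepoint_scale[tp]
    df
  }))
  res$size0 <- NULL
  res <- res[, c("plate", "timepoint", "row", "col", "strain",
                 "replicate", "size", "circularity", "opacity")]
  rownames(res) <- NULL
  attr(res, "truth") <- list(contaminated = contam, missing = missing,
                             edge_mult = edge_mult, seed = seed)
  res
}
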