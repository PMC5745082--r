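# Shared fixtures built in code.

# one variant record with sensible defaults
variant_row <- function(strain = "S1", gene = "g1", class = "missense",
                        position = NA_real_, length = NA_real_,
                        sift_p = NA_real_, foldx_ddg = NA_real_) {
  data.frame(strain = strain, gene = gene, class = class,
             position = position, length = length,
             sift_p = sift_p, foldx_ddg = foldx_ddg,
             stringsAsFactors = FALSE)
}

# tiny hand-built panel: 3 strains, 4 genes; strain S2 has g2 absent,
# strain S3 carries an early nonsense in g3
toy_presence <- function() {
  m <- matrix(1, 3, 4, dimnames = list(c("S1", "S2", "S3"),
                                       c("g1", "g2", "g3", "g4")))
  m["S2", "g2"] <- 0
  m
}

toy_variants <- function() {
  rbind(
    variant_row("S3", "g3", "nonsense", position = 50, length = 100),
    variant_row("S1", "g1", "missense", position = 10, length = 200,
                sift_p = 0.5))
}

# noiseless panel defaults shared by recovery tests
noiseless_params <- function(...) {
  panel_params(variant_rate = 0, frac_noncausal = 0, flip_rate = 0, ...)
}

# brute-force PR area: explicit sweep over every distinct threshold
pr_auc_bruteforce <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    called <- scores >= th[i]
    prec[i] <- sum(labels & called) / sum(called)
    rec[i] <- sum(labels & called) / sum(labels)
  }
  sum(diff(c(0, rec)) * prec)
}

# rank-sum ROC oracle (ties get average ranks)
roc_auc_ranksum <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
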