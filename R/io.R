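# Readers and writers for the plain TSV dialects the pipeline exchanges.
# All tables are tab-separated with a header; empty cells mark absent
# values (e.g. a missense variant scored by only one predictor).

#' Read / write a variant-effect table
#'
#' Columns: strain, gene, class (missense / nonsense / start_loss /
#' stop_loss), position (1-based residue, missense/nonsense only),
#' length (protein residues), sift_p, foldx_ddg. Empty cells are NA.
#'
#' @param path File path.
#' @return A data frame of variant records.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("strain", "gene", "class", "position", "length",
            "sift_p", "foldx_ddg")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "))
  v
}

#' @param variants A variant table.
#' @rdname read_variants
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a strain x gene presence/absence matrix
#'
#' Expects 0/1 values with strains as rows; Roary-style tables (genes as
#' rows) are accepted with `transpose = TRUE`.
#'
#' @param path File path.
#' @param transpose Is the file genes x strains?
#' @return Strains x genes 0/1 matrix.
#' @export
read_presence <- function(path, transpose = FALSE) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (transpose) m <- t(m)
  storage.mode(m) <- "numeric"
  if (!all(m %in% c(0, 1))) stop("presence matrix must be 0/1")
  m
}

#' Read a labeled square distance matrix
#'
#' @param path File path.
#' @return Symmetric numeric matrix with strain labels.
#' @export
read_distances <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "numeric"
  if (nrow(m) != ncol(m)) stop("distance matrix is not square")
  m
}

#' Read a conditional-essentiality table
#'
#' Columns: condition, gene, fdr_p.
#'
#' @param path File path.
#' @param n_screen_conditions See [essentiality_table()].
#' @return An [essentiality_table()].
#' @export
read_essentiality <- function(path, n_screen_conditions = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  essentiality_table(e, n_screen_conditions)
}

#' Write / read a labeled numeric matrix as TSV
#'
#' Generic strains x genes / strains x conditions matrix exchange
#' (disruption scores, conditional scores, S-scores, binary calls).
#'
#' @param m A matrix with dimnames.
#' @param path File path.
#' @return The path (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "numeric"
  m
}
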