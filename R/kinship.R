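#' Centered genomic relatedness (kinship) matrix
#'
#' Computes the centered relatedness matrix
#' `K = (1/p) * sum_s (g_s - mean(g_s)) (g_s - mean(g_s))'` over `p` SNPs
#' (the construction used by standard LMM association software for
#' genome-wide scans). Missing calls are mean-imputed per SNP. Every row of
#' `K` sums to zero by construction and the matrix is positive
#' semi-definite. The eigendecomposition is computed once and cached, since
#' both the association scan and the adaptive-differentiation test operate
#' on the kinship spectrum.
#'
#' @param G accession x SNP matrix of allele counts (0/1 inbred coding;
#'   `NA` allowed), with accession ids as rownames.
#' @return an object of class `kinship_matrix`: list with `K`, `ids`,
#'   `values` (eigenvalues, decreasing) and `vectors` (orthonormal columns).
#' @export
#' @examples
#' G <- matrix(c(0, 1, 1, 1, 0, 1), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' kinship_centered(G)$K
kinship_centered <- function(G) {
  stopifnot(is.matrix(G))
  if (is.null(rownames(G))) rownames(G) <- sprintf("acc%03d", seq_len(nrow(G)))
  if (any(colSums(!is.na(G)) == 0)) {
    rlang::abort("SNP(s) with no observed calls")
  }
  ## mean-impute missing calls per SNP
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  poly <- apply(G, 2, function(x) stats::var(x) > 0)
  if (!any(poly)) rlang::abort("all SNPs are monomorphic")
  Gc <- scale(G[, poly, drop = FALSE], center = TRUE, scale = FALSE)
  K <- tcrossprod(Gc) / ncol(Gc)
  e <- eigen(K, symmetric = TRUE)
  structure(list(K = K, ids = rownames(G),
                 values = e$values, vectors = e$vectors),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix: %d accessions>\n", length(x$ids)))
  cat(sprintf("  trace/n = %.4f, leading eigenvalues: %s\n",
              sum(diag(x$K)) / length(x$ids),
              paste(signif(utils::head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Write / read a kinship matrix as TSV
#'
#' Plain-text round-trip: ids header plus the dense matrix.
#' @param kinship a `kinship_matrix`.
#' @param path file path.
#' @return `read_kinship()` returns a `kinship_matrix`.
#' @export
write_kinship <- function(kinship, path) {
  stopifnot(inherits(kinship, "kinship_matrix"))
  df <- as.data.frame(kinship$K)
  names(df) <- kinship$ids
  df <- cbind(accession = kinship$ids, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  ids <- df$accession
  K <- as.matrix(df[, -1])
  rownames(K) <- ids
  e <- eigen(K, symmetric = TRUE)
  structure(list(K = K, ids = ids, values = e$values, vectors = e$vectors),
            class = "kinship_matrix")
}
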