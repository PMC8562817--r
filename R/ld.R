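#' LD matrices and their factorization
#'
#' An `ld_matrix` is a square symmetric SNP-correlation matrix with unit
#' diagonal, carrying the SNP identifiers in order. All downstream algebra
#' (whitening, sampling, simulation) goes through its eigen-factorization,
#' an `ld_factor`.
#'
#' @name ld
NULL

#' Construct and validate an LD matrix
#'
#' @param values square numeric matrix of SNP correlations.
#' @param snp_ids character vector of SNP identifiers, one per row/column.
#'   Defaults to the matrix dimnames or `snp1..snpM`.
#' @return an object of class `ld_matrix`: the matrix with a `snp_ids`
#'   attribute, validated for symmetry, unit diagonal and entries in [-1, 1].
#' @export
ld_matrix <- function(values, snp_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("LD matrix must be square, got ", nrow(values), "x", ncol(values))
  }
  if (is.null(snp_ids)) {
    snp_ids <- rownames(values)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(values)))
  }
  if (length(snp_ids) != nrow(values)) {
    stop("length(snp_ids) does not match LD dimension")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  obj <- structure(values, snp_ids = as.character(snp_ids),
                   class = c("ld_matrix", "matrix", "array"))
  validate_ld_matrix(obj)
  obj
}

#' @rdname ld_matrix
#' @param x an `ld_matrix`.
#' @export
validate_ld_matrix <- function(x) {
  v <- unclass(x)
  if (max(abs(v - t(v))) > 1e-8) stop("LD matrix is not symmetric (tol 1e-8)")
  if (max(abs(diag(v) - 1)) > 1e-6) {
    stop("LD matrix diagonal deviates from 1 beyond 1e-6 (genotypes not standardized?)")
  }
  if (max(abs(v)) > 1 + 1e-8) stop("LD entries outside [-1, 1] (tol 1e-8)")
  invisible(x)
}

#' SNP identifiers carried by an LD object
#'
#' @param x an [ld_matrix()] (or any object carrying a `snp_ids` attribute).
#' @return character vector of SNP ids in matrix order.
#' @export
snp_ids <- function(x) attr(x, "snp_ids")

#' Standardize a genotype/dosage matrix
#'
#' Columns are centered and scaled so each has mean 0 and second moment 1
#' (denominator N, not N-1), the convention under which `crossprod(X)/N`
#' has unit diagonal. For raw minor-allele counts g in {0,1,2} this matches
#' x = (g - 2f) / sqrt(2f(1-f)) up to the use of the realized in-sample
#' variance rather than the binomial formula.
#'
#' @param genotypes numeric matrix, rows = individuals, columns = SNPs.
#' @return matrix with standardized columns.
#' @export
standardize_genotypes <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  ctr <- sweep(genotypes, 2, colMeans(genotypes), "-")
  s <- sqrt(colMeans(ctr^2))
  if (any(s == 0)) {
    stop("monomorphic column(s): ", paste(which(s == 0), collapse = ", "))
  }
  sweep(ctr, 2, s, "/")
}

#' Compute an in-sample LD matrix from standardized genotypes
#'
#' V = X'X / N for a standardized genotype matrix X (N individuals x M SNPs).
#'
#' @param genotypes standardized genotype matrix (see
#'   [standardize_genotypes()]); columns must have mean 0 and variance 1
#'   within 1e-3.
#' @param snp_ids optional SNP identifiers (defaults to column names).
#' @return an [ld_matrix()].
#' @export
compute_ld <- function(genotypes, snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  mu <- colMeans(genotypes)
  v2 <- colMeans(genotypes^2) - mu^2
  bad <- which(abs(mu) > 1e-3 | abs(v2 - 1) > 1e-3)
  if (length(bad)) {
    stop("column(s) not standardized (mean 0, variance 1 within 1e-3): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  v <- crossprod(genotypes) / n
  v <- (v + t(v)) / 2
  diag(v) <- 1
  ld_matrix(v, snp_ids = snp_ids)
}

#' Eigen-factorize an LD matrix
#'
#' Computes V = U L U' and retains eigenvalues above `tol * max(L)`.
#' The factor stores A = L+^{1/2} U+' (so A'A reproduces V on the retained
#' subspace; column A[, m] plays the role of column m of V^{1/2}),
#' the whitening operator L+^{-1/2} U+', and the Gram matrix A'A that the
#' sampler consumes as its LD entries.
#'
#' @param ld an [ld_matrix()].
#' @param tol relative eigenvalue truncation threshold (default 1e-8).
#' @return an object of class `ld_factor` with elements `sqrt_rows` (A,
#'   rank x M), `inv_sqrt` (rank x M), `gram` (A'A, M x M), `eigenvalues`,
#'   `rank`, `tol`, `m` and `snp_ids`.
#' @export
ld_factorize <- function(ld, tol = 1e-8) {
  validate_ld_matrix(ld)
  v <- unclass(ld)
  eig <- eigen(v, symmetric = TRUE)
  lmax <- eig$values[1]
  if (!is.finite(lmax) || lmax <= 0) {
    stop("degenerate LD matrix: largest eigenvalue is not positive")
  }
  keep <- eig$values > tol * lmax
  lam <- eig$values[keep]
  u <- eig$vectors[, keep, drop = FALSE]
  a <- sqrt(lam) * t(u)           # rank x M
  inv_sqrt <- (1 / sqrt(lam)) * t(u)
  gram <- crossprod(a)            # A'A; equals V at full rank
  structure(
    list(sqrt_rows = a, inv_sqrt = inv_sqrt, gram = gram,
         eigenvalues = lam, rank = sum(keep), tol = tol,
         m = ncol(v), snp_ids = snp_ids(ld)),
    class = "ld_factor"
  )
}

#' @export
print.ld_factor <- function(x, ...) {
  cat("LD factor:", x$m, "SNPs, rank", x$rank,
      sprintf("(eigenvalue truncation %g)\n", x$tol))
  invisible(x)
}

#' Whiten GWAS marginal effects for a region
#'
#' Applies the one-time transform beta_tilde = V^{-1/2} beta_hat under which
#' the residual noise of the transformed effects is independent across
#' coordinates with variance sigma_e^2 = (1 - h2_r) / n. Also precomputes
#' b_m = beta_tilde' A[, m], the only per-SNP summary of beta_hat the
#' sampler needs.
#'
#' @param beta_hat numeric vector of marginal effects on the standardized
#'   scale (z / sqrt(n)).
#' @param ld_factor an [ld_factorize()] result.
#' @param n GWAS sample size.
#' @param h2_r regional SNP-heritability in (0, 1).
#' @return an object of class `transformed_region` with elements
#'   `beta_tilde` (rank-length), `b` (M-length), `ld` (the factor), `n`,
#'   `m_r`, `h2_r`, `snp_ids`.
#' @export
whiten <- function(beta_hat, ld_factor, n, h2_r) {
  stopifnot(inherits(ld_factor, "ld_factor"))
  beta_hat <- as.numeric(beta_hat)
  if (length(beta_hat) != ld_factor$m) {
    stop("length(beta_hat) = ", length(beta_hat),
         " does not match LD dimension ", ld_factor$m)
  }
  if (!is.finite(n) || n <= 0) stop("n must be positive")
  if (!is.finite(h2_r) || h2_r <= 0 || h2_r >= 1) {
    stop("h2_r must lie strictly in (0, 1), got ", h2_r)
  }
  beta_tilde <- drop(ld_factor$inv_sqrt %*% beta_hat)
  b <- drop(crossprod(ld_factor$sqrt_rows, beta_tilde))
  structure(
    list(beta_tilde = beta_tilde, b = b, beta_hat = beta_hat,
         ld = ld_factor, n = n, m_r = ld_factor$m, h2_r = h2_r,
         snp_ids = ld_factor$snp_ids),
    class = "transformed_region"
  )
}

#' Invert the whitening transform
#'
#' Maps whitened effects back to the marginal-effect scale:
#' beta_hat = A' beta_tilde, the projection of the original beta_hat onto
#' the retained eigen-subspace (exactly beta_hat when the LD matrix has
#' full rank).
#'
#' @param beta_tilde rank-length vector of whitened effects.
#' @param ld_factor the factor used for whitening.
#' @return M-length vector.
#' @export
unwhiten <- function(beta_tilde, ld_factor) {
  stopifnot(inherits(ld_factor, "ld_factor"))
  if (length(beta_tilde) != ld_factor$rank) {
    stop("length(beta_tilde) does not match factor rank")
  }
  drop(crossprod(ld_factor$sqrt_rows, beta_tilde))
}
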