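#' File formats and region windowing
#'
#' Tab-separated summary statistics, whitespace-delimited LD matrices with
#' optional SNP-id sidecar files, two-column regional-heritability tables,
#' per-region draw tables, and JSON run manifests. All writers use
#' full-precision numeric formatting so that write -> read round trips are
#' lossless and identical runs produce byte-identical outputs.
#'
#' @name io
NULL

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- .fmt_num(out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read GWAS summary statistics
#'
#' Tab-separated with header. Required columns: `snp_id` (or `snp`) and
#' `n`, plus either `z` or both `beta` and `se`. Optional: `chrom`,
#' `position` (1-based). The standardized-scale marginal effect is computed
#' as beta_std = z / sqrt(n); when both z and beta/se are present they must
#' agree (z = beta/se within 1e-6). Rows with missing required fields are
#' dropped with a message reporting the count.
#'
#' @param path file path.
#' @return data.frame of class `sumstats` with columns `snp_id`, `chrom`,
#'   `position`, `z`, `n`, `beta_std` (plus `beta`, `se` if supplied).
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("sumstats file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "snp"] <- "snp_id"
  names(df)[names(df) == "pos"] <- "position"
  if (!"snp_id" %in% names(df)) stop("missing required column: snp_id")
  if (!"n" %in% names(df)) stop("missing required column: n")
  has_z <- "z" %in% names(df)
  has_bse <- all(c("beta", "se") %in% names(df))
  if (!has_z && !has_bse) stop("need column z, or columns beta and se")
  for (col in intersect(c("z", "beta", "se", "n", "position"), names(df))) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      if (anyNA(v) && !anyNA(df[[col]])) stop("non-numeric values in column ", col)
      df[[col]] <- v
    }
  }
  need <- c("snp_id", "n", if (has_z) "z", if (!has_z) c("beta", "se"))
  ok <- stats::complete.cases(df[, need, drop = FALSE])
  if (any(!ok)) {
    message("dropping ", sum(!ok), " row(s) with missing required fields")
    df <- df[ok, , drop = FALSE]
  }
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id values")
  if (any(df$n <= 0)) stop("n must be positive")
  if (!has_z) df$z <- df$beta / df$se
  if (has_z && has_bse) {
    if (max(abs(df$z - df$beta / df$se), na.rm = TRUE) > 1e-6) {
      stop("z and beta/se disagree beyond 1e-6")
    }
  }
  if (!"chrom" %in% names(df)) df$chrom <- "1"
  if (!"position" %in% names(df)) df$position <- seq_len(nrow(df))
  df$beta_std <- df$z / sqrt(df$n)
  class(df) <- c("sumstats", "data.frame")
  df
}

#' @rdname read_sumstats
#' @param sumstats a `sumstats` data.frame.
#' @export
write_sumstats <- function(sumstats, path) {
  .write_tsv(as.data.frame(sumstats), path)
  invisible(path)
}

#' Divide sorted summary statistics into fixed-width regions
#'
#' Consecutive half-open windows of `window_bp` per chromosome, anchored at
#' the first SNP's position; empty windows are dropped and the trailing
#' partial window is retained. Coordinates in the output are 0-based
#' half-open.
#'
#' @param sumstats a `sumstats` data.frame (positions sorted within
#'   chromosome).
#' @param window_bp window width in base pairs (default 6e6).
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `m_r`; the per-SNP region assignment is attached as attribute
#'   `snp_region`.
#' @export
window_regions <- function(sumstats, window_bp = 6e6) {
  assign <- character(nrow(sumstats))
  regions <- list()
  for (ch in unique(sumstats$chrom)) {
    sel <- which(sumstats$chrom == ch)
    pos <- sumstats$position[sel]
    if (is.unsorted(pos)) stop("positions not sorted within chromosome ", ch)
    start0 <- pos[1] - 1            # 0-based anchor at the first SNP
    idx <- floor((pos - 1 - start0) / window_bp)
    for (w in sort(unique(idx))) {
      rid <- paste0(ch, "_", w + 1)
      in_w <- sel[idx == w]
      assign[in_w] <- rid
      regions[[rid]] <- data.frame(
        region_id = rid, chrom = ch,
        start = start0 + w * window_bp,
        end = start0 + (w + 1) * window_bp,
        m_r = length(in_w), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  attr(out, "snp_region") <- assign
  out
}

#' Read and write whitespace-delimited LD matrices
#'
#' A square numeric text matrix; if a sidecar file `<path>.snps` exists (one
#' SNP id per line) the ids are attached and later validated against the
#' summary statistics.
#'
#' @param path matrix file path.
#' @param snp_ids optional ids overriding the sidecar.
#' @return an [ld_matrix()].
#' @export
read_ld_file <- function(path, snp_ids = NULL) {
  if (!file.exists(path)) stop("LD file not found: ", path)
  v <- as.matrix(utils::read.table(path, header = FALSE))
  sidecar <- paste0(path, ".snps")
  if (is.null(snp_ids) && file.exists(sidecar)) {
    snp_ids <- readLines(sidecar)
  }
  ld_matrix(v, snp_ids = snp_ids)
}

#' @rdname read_ld_file
#' @param ld an [ld_matrix()].
#' @param with_snps write the `<path>.snps` sidecar too.
#' @export
write_ld_file <- function(ld, path, with_snps = TRUE) {
  v <- unclass(ld)
  lines <- apply(v, 1, function(r) paste(.fmt_num(r), collapse = "\t"))
  writeLines(lines, path)
  if (with_snps) writeLines(snp_ids(ld), paste0(path, ".snps"))
  invisible(path)
}

#' Read a regional heritability table
#'
#' Two tab-separated columns (`region_id`, `h2_r`). External estimators can
#' return non-positive values in null regions; those are floored at
#' `floor_eps` with a warning, since the model requires h2_r > 0.
#'
#' @param path file path.
#' @param floor_eps positive floor (default 1e-6).
#' @return data.frame with `region_id`, `h2_r`.
#' @export
read_h2_table <- function(path, floor_eps = 1e-6) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("region_id", "h2_r") %in% names(df))) {
    stop("h2 table needs columns region_id and h2_r")
  }
  low <- df$h2_r < floor_eps
  if (any(low)) {
    warning(sum(low), " region(s) with h2_r < ", floor_eps,
            " floored; external heritability estimates can go negative")
    df$h2_r[low] <- floor_eps
  }
  df
}

#' Persist and reload per-region MCMC draws
#'
#' A tab-separated table (`iteration`, `p`, `k`) per region, for
#' diagnostics and re-summarization.
#'
#' @param draws a `posterior_draws` object.
#' @param path output file.
#' @export
write_draws <- function(draws, path) {
  df <- data.frame(iteration = seq_along(draws$p_samples) + draws$burn_in,
                   p = draws$p_samples, k = draws$k_samples)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_draws
#' @param m_r,h2_r region metadata to reattach.
#' @export
read_draws <- function(path, m_r = NA_integer_, h2_r = NA_real_) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  structure(list(p_samples = as.numeric(df$p),
                 k_samples = as.numeric(df$k), pip = NULL,
                 accept_rate = NA_real_, n_iter = max(df$iteration),
                 burn_in = min(df$iteration) - 1L,
                 m_r = m_r, h2_r = h2_r, snp_ids = NULL),
            class = "posterior_draws")
}

#' Write a machine-readable run manifest
#'
#' Records the resolved configuration, seed, package version and md5
#' checksums of the input files; identical inputs and configuration yield a
#' byte-identical manifest, so re-running from a manifest reproduces
#' outputs exactly.
#'
#' @param dir output directory.
#' @param config named list of resolved settings.
#' @param seed integer seed.
#' @param inputs character vector of input file paths.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, inputs = character()) {
  sums <- if (length(inputs)) {
    s <- tools::md5sum(inputs)
    names(s) <- basename(names(s))
    as.list(s)
  } else {
    NULL
  }
  manifest <- list(
    tool = "regpoly",
    version = as.character(utils::packageVersion("regpoly")),
    seed = seed,
    config = config,
    input_md5 = sums)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
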