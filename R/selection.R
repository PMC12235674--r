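#' One-way ANOVA F statistic for a single gene
#'
#' Computes the classic between/within variance ratio
#' F = MSB / MSW with MSB = SSB/(k-1) and MSW = SSW/(N-k), and the upper-tail
#' p-value of the F(k-1, N-k) distribution. Degenerate cases follow fixed
#' rules: MSW = 0 with MSB > 0 gives (Inf, 0); a fully constant gene gives
#' (0, 1).
#'
#' @param values_by_group list of numeric vectors, one per class, each
#'   non-empty; the total number of observations must exceed the number of
#'   groups so MSW has positive degrees of freedom.
#' @return list with elements `F` and `p`.
#' @export
anova_f <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  n_i <- vapply(values_by_group, length, integer(1))
  if (any(n_i == 0L)) stop("empty group in ANOVA input", call. = FALSE)
  k <- length(n_i)
  N <- sum(n_i)
  if (N <= k) stop("need N > k observations for within-group degrees of freedom",
                   call. = FALSE)
  y <- unlist(values_by_group, use.names = FALSE)
  grand <- mean(y)
  gm <- vapply(values_by_group, mean, numeric(1))
  ssb <- sum(n_i * (gm - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i)
    sum((values_by_group[[i]] - gm[i])^2), numeric(1)))
  sst <- ssb + ssw
  tol <- 1e-12 * max(sst, 1)
  if (ssw <= tol) {
    if (ssb <= tol) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Per-gene ANOVA table for an expression matrix
#'
#' Vectorized row-wise one-way ANOVA of every gene against the sample class
#' labels. Constant genes are assigned (F = 0, p = 1) rather than dropped so
#' they remain available as reference-gene (NDEG) candidates. With
#' `fdr = TRUE` a Benjamini-Hochberg adjusted q-value column is added.
#'
#' @param x an [expr_matrix]; every column must be labelled.
#' @param labels named factor covering all samples of `x`.
#' @param fdr add BH-adjusted q-values?
#' @return data.frame of class `anova_table` with columns `gene_id`, `F`,
#'   `p` and optionally `q`, in the gene order of `x`.
#' @export
anova_table <- function(x, labels, fdr = FALSE) {
  sid <- colnames(x)
  if (!all(sid %in% names(labels)))
    stop("every sample of the matrix must have a label", call. = FALSE)
  g <- droplevels(factor(labels[sid]))
  k <- nlevels(g)
  N <- length(sid)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  if (N <= k) stop("need N > k observations", call. = FALSE)
  v <- unclass(x)
  ind <- stats::model.matrix(~ g - 1)           # N x k indicator
  n_i <- colSums(ind)
  gsum <- v %*% ind                              # G x k group sums
  gmean <- sweep(gsum, 2L, n_i, "/")
  grand <- rowSums(v) / N
  ssb <- (sweep(gmean, 1L, grand, "-")^2) %*% n_i
  sst <- rowSums(v^2) - N * grand^2
  ssw <- pmax(sst - ssb, 0)
  tol <- 1e-12 * pmax(sst, 1)
  f <- as.numeric((ssb / (k - 1)) / (ssw / (N - k)))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  zero_w <- as.numeric(ssw) <= tol
  zero_b <- as.numeric(ssb) <= tol
  f[zero_w & !zero_b] <- Inf; p[zero_w & !zero_b] <- 0
  f[zero_w & zero_b] <- 0;    p[zero_w & zero_b] <- 1
  out <- data.frame(gene_id = rownames(x), F = f, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (fdr) out$q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Write an ANOVA table as TSV
#' @param t an [anova_table()] result.
#' @param path output path.
#' @export
write_anova_table <- function(t, path) {
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select DEG and NDEG gene sets by p-value thresholds
#'
#' DEGs (classification features) are genes with p strictly below `tau_deg`;
#' NDEGs (normalization references, the housekeeping-gene analogue) are genes
#' with p strictly above `tau_ndeg`. Ties at a threshold are excluded. With
#' `mode = "q"` the BH-adjusted q-values are thresholded instead.
#'
#' @param t an [anova_table()] result.
#' @param tau_deg DEG threshold in (0, 1].
#' @param tau_ndeg NDEG threshold in [0, 1).
#' @param mode `"p"` (raw p-values) or `"q"` (FDR-adjusted; requires the `q`
#'   column).
#' @param require_ndeg if `TRUE` (a reference-based normalization will be
#'   requested) an empty NDEG set is a hard error; otherwise a warning.
#' @return list of class `gene_selection` with elements `deg`, `ndeg`,
#'   `tau_deg`, `tau_ndeg`, `mode`, preserving the table's gene order.
#' @export
select_genes <- function(t, tau_deg = 0.05, tau_ndeg = 0.95,
                         mode = c("p", "q"), require_ndeg = FALSE) {
  mode <- match.arg(mode)
  if (mode == "q" && is.null(t$q))
    stop("mode 'q' requires an ANOVA table computed with fdr = TRUE", call. = FALSE)
  stat <- if (mode == "q") t$q else t$p
  deg <- t$gene_id[stat < tau_deg]
  ndeg <- t$gene_id[stat > tau_ndeg]
  if (!length(ndeg)) {
    if (require_ndeg)
      stop("empty NDEG set at tau_ndeg = ", tau_ndeg,
           " but a reference-based normalization was requested", call. = FALSE)
    warning("empty NDEG set at tau_ndeg = ", tau_ndeg, call. = FALSE)
  }
  structure(list(deg = deg, ndeg = ndeg, tau_deg = tau_deg,
                 tau_ndeg = tau_ndeg, mode = mode),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection: %d DEG (%s < %g), %d NDEG (%s > %g)\n",
              length(x$deg), x$mode, x$tau_deg,
              length(x$ndeg), x$mode, x$tau_ndeg))
  invisible(x)
}
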