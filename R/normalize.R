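#' Log2 transformation with pseudo-count
#'
#' @param x an [expr_matrix] on linear scale with non-negative values.
#' @param pseudo_count positive constant added before taking log2 (default 1).
#' @return An [expr_matrix] flagged as log scale.
#' @export
log_transform <- function(x, pseudo_count = 1) {
  if (pseudo_count <= 0) stop("pseudo_count must be positive", call. = FALSE)
  if (any(unclass(x) < 0, na.rm = TRUE))
    stop("negative expression values: input looks already log-transformed", call. = FALSE)
  out <- log2(unclass(x) + pseudo_count)
  expr_matrix(out, platform = attr(x, "platform"), scale = "log")
}

#' Per-gene z-score transformation
#'
#' Each gene row is centred by its mean and scaled by its population standard
#' deviation (ddof = 0) across samples; constant rows map to all-zero.
#'
#' @param x an [expr_matrix] with at least 2 samples.
#' @return An [expr_matrix] (log/additive scale).
#' @export
zscore <- function(x) {
  v <- unclass(x)
  if (ncol(v) < 2L) stop("z-score needs at least 2 samples", call. = FALSE)
  m <- rowMeans(v)
  cv <- v - m
  s <- sqrt(rowMeans(cv^2))
  s[s == 0] <- Inf                     # constant rows -> 0/Inf = 0
  expr_matrix(cv / s, platform = attr(x, "platform"), scale = "log")
}

row_percentiles <- function(v) {
  # average ranks for ties; percentile = rank/(n+1), avoiding 0 and 1
  n <- ncol(v)
  t(apply(v, 1L, function(r) rank(r, ties.method = "average"))) / (n + 1)
}

#' Normal score transformation (rank-based inverse normal)
#'
#' Per gene row: average ranks for ties, percentile = rank/(n+1), then the
#' standard-normal quantile of the percentile.
#'
#' @param x an [expr_matrix] with at least 2 samples.
#' @return An [expr_matrix] (additive scale).
#' @export
normal_scores <- function(x) {
  v <- unclass(x)
  if (ncol(v) < 2L) stop("normal scores need at least 2 samples", call. = FALSE)
  out <- stats::qnorm(row_percentiles(v))
  dimnames(out) <- dimnames(v)
  expr_matrix(out, platform = attr(x, "platform"), scale = "log")
}

#' Non-parametric normalization (rank to percentile to target distribution)
#'
#' The same rank machinery as [normal_scores()]; with `target = "normal"` the
#' output is identical to the normal score transformation, with
#' `target = "uniform"` the rank/(n+1) percentiles are returned as-is.
#'
#' @param x an [expr_matrix] with at least 2 samples.
#' @param target `"normal"` or `"uniform"`.
#' @return An [expr_matrix] (additive scale).
#' @export
npn <- function(x, target = c("normal", "uniform")) {
  target <- match.arg(target)
  if (target == "normal") return(normal_scores(x))
  v <- unclass(x)
  if (ncol(v) < 2L) stop("NPN needs at least 2 samples", call. = FALSE)
  out <- row_percentiles(v)
  dimnames(out) <- dimnames(v)
  expr_matrix(out, platform = attr(x, "platform"), scale = "log")
}

qn_target <- function(v) {
  s <- apply(v, 2L, sort)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  rowMeans(s)
}

map_column_to_target <- function(col, target) {
  # value at within-column rank r takes target[r]; ties get the mean of the
  # tied target positions
  idx <- rank(col, ties.method = "first")
  base <- target[idx]
  stats::ave(base, match(col, col), FUN = mean)
}

#' Quantile normalization across samples
#'
#' Classic column-wise quantile normalization: the target at each rank
#' position is the cross-sample mean of the position-sorted values; each
#' sample's value at within-column rank r is replaced by the target at r,
#' with within-column ties receiving the mean of their tied targets.
#'
#' @param x an [expr_matrix].
#' @return An [expr_matrix] on the same scale flag as the input.
#' @export
quantile_normalize <- function(x) {
  v <- unclass(x)
  tgt <- qn_target(v)
  out <- apply(v, 2L, map_column_to_target, target = tgt)
  dimnames(out) <- dimnames(v)
  expr_matrix(out, platform = attr(x, "platform"), scale = attr(x, "scale"))
}

#' Fit a reference-gene quantile target
#'
#' Restricts the matrix to the reference (NDEG) rows, sorts each sample's m
#' reference values, and averages across samples at each sorted position,
#' yielding a non-decreasing target vector of length m. This target defines
#' the common distribution onto which [apply_rqn()] /
#' [apply_npn_reference()] percentile-map all genes.
#'
#' @param x an [expr_matrix].
#' @param reference_genes non-empty subset of `rownames(x)`.
#' @return list of class `fitted_normalizer` with elements `target` and
#'   `reference_genes`.
#' @export
fit_reference_target <- function(x, reference_genes) {
  if (!length(reference_genes)) stop("empty reference gene set", call. = FALSE)
  missing_ref <- setdiff(reference_genes, rownames(x))
  if (length(missing_ref))
    stop("reference gene not in matrix: ", missing_ref[1L], call. = FALSE)
  vr <- unclass(x)[reference_genes, , drop = FALSE]
  tgt <- if (ncol(vr) == 1L) sort(vr[, 1L]) else qn_target(vr)
  structure(list(target = as.numeric(tgt), reference_genes = reference_genes),
            class = "fitted_normalizer")
}

rqn_map <- function(v, target) {
  m <- length(target)
  if (m < 2L) stop("reference target needs at least 2 genes for interpolation",
                   call. = FALSE)
  g <- nrow(v)
  uj <- (seq_len(m) - 0.5) / m
  apply(v, 2L, function(col) {
    u <- (rank(col, ties.method = "average") - 0.5) / g
    stats::approx(uj, target, xout = u, rule = 2, ties = "ordered")$y
  })
}

#' Apply reference-based quantile normalization (RQN)
#'
#' Per sample column, each of the G gene values is assigned the fractional
#' percentile u = (rank - 0.5)/G (average ranks for ties) and mapped through
#' linear interpolation of the reference target's empirical quantile
#' function, where target position j of m sits at (j - 0.5)/m; percentiles
#' outside the target grid are clamped to the end values.
#'
#' @param x an [expr_matrix].
#' @param fitted a [fit_reference_target()] result with target length >= 2.
#' @return An [expr_matrix] on the same scale flag as the input.
#' @export
apply_rqn <- function(x, fitted) {
  v <- unclass(x)
  out <- rqn_map(v, fitted$target)
  dimnames(out) <- dimnames(v)
  expr_matrix(out, platform = attr(x, "platform"), scale = attr(x, "scale"))
}

#' Percentile-map all genes onto a reference distribution
#'
#' Mechanically identical to [apply_rqn()]; kept as a distinct named step
#' because it is composed differently (inside LOG_NPN_Z, where a z-score
#' follows).
#'
#' @inheritParams apply_rqn
#' @export
apply_npn_reference <- function(x, fitted) apply_rqn(x, fitted)

#' Internal-control-gene scaling (NICG)
#'
#' Per sample, subtracts the sample's mean over the reference (control) gene
#' rows from every value. On log-scale data this subtraction is equivalent to
#' dividing by the geometric-mean control signal on the linear scale; the
#' input must therefore be flagged as log scale.
#'
#' @param x_log a log-scale [expr_matrix].
#' @param reference_genes non-empty subset of `rownames(x_log)`.
#' @return An [expr_matrix] whose per-sample reference-gene means are zero.
#' @export
nicg_scale <- function(x_log, reference_genes) {
  if (!is_log_scale(x_log))
    stop("NICG scaling requires log-scale input", call. = FALSE)
  if (!length(reference_genes)) stop("empty reference gene set", call. = FALSE)
  missing_ref <- setdiff(reference_genes, rownames(x_log))
  if (length(missing_ref))
    stop("reference gene not in matrix: ", missing_ref[1L], call. = FALSE)
  v <- unclass(x_log)
  shift <- colMeans(v[reference_genes, , drop = FALSE])
  out <- sweep(v, 2L, shift, "-")
  expr_matrix(out, platform = attr(x_log, "platform"), scale = "log")
}

#' Normalization methods
#'
#' The nine supported schemes plus the identity baseline `RAW`:
#' `LOG`, `Z`, `NST`, `NPN`, `QN` operate without reference genes;
#' `LOG_RQN`, `LOG_RQN_Z`, `LOG_NPN_Z`, `LOG_NICG_Z` are the reference-based
#' composites that use the NDEG list as their reference set.
#' @export
NORMALIZATION_METHODS <- c("RAW", "LOG", "Z", "NST", "NPN", "QN",
                           "LOG_RQN", "LOG_RQN_Z", "LOG_NPN_Z", "LOG_NICG_Z")

#' Dispatch a (possibly composite) normalization scheme
#'
#' Composites chain the elementary transforms:
#' `LOG_RQN` = log2 then RQN against the NDEG-fitted target;
#' `LOG_RQN_Z` adds a final per-gene z-score; `LOG_NPN_Z` = log2, percentile
#' mapping onto the NDEG reference distribution, then z-score;
#' `LOG_NICG_Z` = log2, control-gene centering, then z-score. The fit (target
#' or control means) always comes from the matrix being normalized, so each
#' platform is normalized with its own samples while sharing the
#' training-derived reference gene list.
#'
#' @param x an [expr_matrix] (linear scale for methods starting with LOG).
#' @param method one of [NORMALIZATION_METHODS].
#' @param reference_genes NDEG reference list; required for the four
#'   reference-based composites.
#' @param pseudo_count passed to [log_transform()].
#' @param fitted optional [fit_reference_target()] result; when supplied, the
#'   quantile-mapping composites map onto this pre-fitted target instead of
#'   refitting on `x`. This is how a training-platform target is shared with
#'   the test platform so that both land on a common reference distribution.
#' @return The normalized [expr_matrix].
#' @export
normalize_expression <- function(x, method, reference_genes = NULL,
                                 pseudo_count = 1, fitted = NULL) {
  if (!method %in% NORMALIZATION_METHODS)
    stop("unknown normalization method: ", method, call. = FALSE)
  needs_ref <- method %in% c("LOG_RQN", "LOG_RQN_Z", "LOG_NPN_Z", "LOG_NICG_Z")
  if (needs_ref && is.null(fitted) && !length(reference_genes))
    stop("method ", method, " requires a non-empty reference (NDEG) gene list",
         call. = FALSE)
  if (method == "LOG_NICG_Z" && !length(reference_genes))
    stop("method LOG_NICG_Z requires a non-empty reference (NDEG) gene list",
         call. = FALSE)
  ref_fit <- function(xl)
    if (is.null(fitted)) fit_reference_target(xl, reference_genes) else fitted
  switch(method,
    RAW = x,
    LOG = log_transform(x, pseudo_count),
    Z = zscore(x),
    NST = normal_scores(x),
    NPN = npn(x, "normal"),
    QN = quantile_normalize(x),
    LOG_RQN = {
      xl <- log_transform(x, pseudo_count)
      apply_rqn(xl, ref_fit(xl))
    },
    LOG_RQN_Z = {
      xl <- log_transform(x, pseudo_count)
      zscore(apply_rqn(xl, ref_fit(xl)))
    },
    LOG_NPN_Z = {
      xl <- log_transform(x, pseudo_count)
      zscore(apply_npn_reference(xl, ref_fit(xl)))
    },
    LOG_NICG_Z = {
      xl <- log_transform(x, pseudo_count)
      zscore(nicg_scale(xl, reference_genes))
    })
}
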