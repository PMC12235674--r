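#' Design for a paired two-platform synthetic dataset
#'
#' Describes a toy transcriptomic study: a latent log2-scale expression
#' matrix shared by two platforms, a subset of genes carrying class-specific
#' mean shifts (planted DEGs), the remainder with no class effect (NDEG-like
#' nulls), a monotone platform distortion on platform B, severe class
#' imbalance mirroring a five-subtype cohort, and a few samples present on
#' platform B only.
#'
#' @param n_genes total genes (default 2000).
#' @param n_deg planted class-affected genes (default 200).
#' @param class_sizes named integer vector of per-class sample counts shared
#'   by both platforms; the default (96, 58, 231, 127, 8) reproduces a
#'   largest:smallest ratio that rounds to 29:1.
#' @param extra_b named integer vector of additional platform-B-only samples
#'   per class (default 2 extra Basal).
#' @param effect_size class-mean shift for planted DEGs, in units of the
#'   within-class (noise) SD; default 2.
#' @param min_shift_class_size shifts are planted only in classes with at
#'   least this many samples (default 20), so the planted signal is carried
#'   by classes large enough to detect it; if no class qualifies, all
#'   classes are eligible.
#' @param distortion list: `type` one of `"power"` (log-scale scaling by
#'   `gamma`, default 1.3), `"affine"` (log-scale `a*x + b`), `"none"`.
#' @param noise_sd per-measurement noise SD on the log2 scale (default 1).
#' @param dropout_rate probability an entry is set missing (default 0; note
#'   that cleaning drops any gene with a single missing value, so non-zero
#'   rates are meant for small matrices).
#' @param seed integer seed (default 20240225).
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 2000L, n_deg = 200L,
                             class_sizes = c(Basal = 96L, Her2 = 58L,
                                             LumA = 231L, LumB = 127L,
                                             Normal = 8L),
                             extra_b = c(Basal = 2L),
                             effect_size = 2,
                             distortion = list(type = "power", gamma = 1.3),
                             noise_sd = 1, dropout_rate = 0,
                             min_shift_class_size = 20L,
                             seed = 20240225L) {
  if (n_deg > n_genes) stop("n_deg cannot exceed n_genes", call. = FALSE)
  if (any(class_sizes < 1L)) stop("class sizes must be >= 1", call. = FALSE)
  structure(list(n_genes = n_genes, n_deg = n_deg, class_sizes = class_sizes,
                 extra_b = extra_b, effect_size = effect_size,
                 distortion = distortion, noise_sd = noise_sd,
                 dropout_rate = dropout_rate,
                 min_shift_class_size = min_shift_class_size, seed = seed),
            class = "synthetic_design")
}

distort_log <- function(vlog, distortion) {
  switch(distortion$type,
    none = vlog,
    power = vlog * (distortion$gamma %||% 1.3),
    affine = vlog * (distortion$a %||% 1) + (distortion$b %||% 0),
    stop("unknown distortion type: ", distortion$type, call. = FALSE))
}

#' Generate a paired two-platform expression dataset with known truth
#'
#' Latent log2 expression per gene: baseline ~ Normal(8, 2^2); planted DEGs
#' add a shift of `effect_size * noise_sd` (random sign) to one randomly
#' chosen class. Each platform observes latent + its own independent
#' Normal(0, noise_sd^2) measurement noise; platform A exponentiates to the
#' linear scale, platform B additionally applies the monotone distortion
#' before exponentiating. Dropout (if any) is applied independently per
#' platform. Everything is driven by the design's seed.
#'
#' @param design a [synthetic_design()].
#' @return list with `platform_a`, `platform_b` ([expr_matrix], linear
#'   scale), `labels` (named factor over all sample IDs) and `truth`
#'   (list: `deg_gene_ids`, `ndeg_gene_ids`, `shared_ids`, `b_only_ids`).
#' @export
generate_cross_platform <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  cs <- design$class_sizes
  classes <- names(cs)
  shared_lab <- rep(classes, times = cs)
  eb <- design$extra_b
  extra_lab <- if (length(eb)) rep(names(eb), times = eb) else character(0)
  n_shared <- length(shared_lab)
  n_all <- n_shared + length(extra_lab)
  sample_ids <- sprintf("S%04d", seq_len(n_all))
  shared_ids <- sample_ids[seq_len(n_shared)]
  b_only_ids <- if (n_all > n_shared) sample_ids[(n_shared + 1L):n_all] else character(0)
  lab_all <- c(shared_lab, extra_lab)
  labels <- subtype_labels(stats::setNames(lab_all, sample_ids),
                           class_order = classes)

  g <- design$n_genes
  gene_ids <- sprintf("G%05d", seq_len(g))
  deg_ids <- if (design$n_deg) gene_ids[seq_len(design$n_deg)] else character(0)
  ndeg_ids <- setdiff(gene_ids, deg_ids)

  baseline <- stats::rnorm(g, mean = 8, sd = 2)
  latent <- matrix(baseline, nrow = g, ncol = n_all)
  if (design$n_deg) {
    eligible <- classes[cs >= (design$min_shift_class_size %||% 1L)]
    if (!length(eligible)) eligible <- classes
    shift_class <- if (length(eligible) == 1L) rep(eligible, design$n_deg)
                   else sample(eligible, design$n_deg, replace = TRUE)
    shift_sign <- sample(c(-1, 1), design$n_deg, replace = TRUE)
    delta <- design$effect_size * design$noise_sd
    for (i in seq_len(design$n_deg)) {
      cols <- lab_all == shift_class[i]
      latent[i, cols] <- latent[i, cols] + shift_sign[i] * delta
    }
  }

  noise_a <- matrix(stats::rnorm(g * n_all, sd = design$noise_sd), g, n_all)
  noise_b <- matrix(stats::rnorm(g * n_all, sd = design$noise_sd), g, n_all)
  log_a <- latent + noise_a
  log_b <- distort_log(latent + noise_b, design$distortion)

  lin_a <- 2^log_a
  lin_b <- 2^log_b
  if (design$dropout_rate > 0) {
    lin_a[matrix(stats::runif(g * n_all) < design$dropout_rate, g, n_all)] <- NA_real_
    lin_b[matrix(stats::runif(g * n_all) < design$dropout_rate, g, n_all)] <- NA_real_
  }
  dimnames(lin_a) <- dimnames(lin_b) <- list(gene_ids, sample_ids)

  platform_a <- expr_matrix(lin_a[, shared_ids, drop = FALSE],
                            platform = "microarray")
  platform_b <- expr_matrix(lin_b, platform = "rnaseq")

  list(platform_a = platform_a, platform_b = platform_b, labels = labels,
       truth = list(deg_gene_ids = deg_ids, ndeg_gene_ids = ndeg_ids,
                    shared_ids = shared_ids, b_only_ids = b_only_ids))
}
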