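# fixtures are built in code; no data files

make_expr <- function(values, genes = NULL, samples = NULL,
                      platform = "test", scale = "linear") {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, platform = platform, scale = scale)
}

random_expr <- function(n_genes, n_samples, seed = 1, scale = "linear") {
  set.seed(seed)
  make_expr(matrix(abs(rnorm(n_genes * n_samples, 8, 2)), n_genes, n_samples),
            scale = scale)
}

write_expr_tsv <- function(x, path = tempfile(fileext = ".tsv")) {
  write_expression(x, path)
  path
}

# labels for paper-scale class counts on a given platform
paper_labels <- function(counts = c(Basal = 96, Her2 = 58, LumA = 231,
                                    LumB = 127, Normal = 8),
                         prefix = "M") {
  n <- sum(counts)
  subtype_labels(stats::setNames(rep(names(counts), counts),
                                 sprintf("%s%04d", prefix, seq_len(n))),
                 class_order = names(counts))
}

# small separable 3-class dataset for classifier/harness tests
separable_data <- function(n_per_class = 20, p = 6, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B", "C"), each = n_per_class))
  x <- matrix(rnorm(length(y) * p, sd = 0.3), length(y), p)
  x[y == "B", 1] <- x[y == "B", 1] + 5
  x[y == "C", 2] <- x[y == "C", 2] + 5
  rownames(x) <- sprintf("s%03d", seq_along(y))
  colnames(x) <- sprintf("f%d", seq_len(p))
  names(y) <- rownames(x)
  list(x = x, y = y)
}

small_sim <- function(n_genes = 300, n_deg = 30,
                      class_sizes = c(A = 40, B = 40, C = 40),
                      extra_b = c(A = 2), seed = 7, ...) {
  generate_cross_platform(synthetic_design(
    n_genes = n_genes, n_deg = n_deg, class_sizes = class_sizes,
    extra_b = extra_b, seed = seed, ...))
}

random_confusion <- function(k, seed) {
  set.seed(seed)
  matrix(rpois(k * k, lambda = sample(1:30, 1)) + diag(k) * sample(0:40, 1),
         k, k, dimnames = list(letters[1:k], letters[1:k]))
}
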