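#' Stratified cross-platform train/test split
#'
#' Draws `floor(frac * n_c)` training samples per class (uniformly, without
#' replacement, seeded) from the training platform's labelled samples; the
#' test set is the other platform's sample list minus the training IDs
#' (matched by name). Per-class flooring is the rounding convention that
#' reproduces training sizes of 390 from class counts (98, 58, 231, 127, 8)
#' and 389 from (96, 58, 231, 127, 8) at frac = 0.75.
#'
#' @param train_labels named factor: the training platform's labelled
#'   samples.
#' @param other_platform_ids sample IDs available on the test platform.
#' @param frac training fraction in (0, 1); default 0.75.
#' @param seed integer seed.
#' @param repeat_index bookkeeping index (>= 0) stored on the plan.
#' @return list of class `partition_plan` with elements `train_ids`,
#'   `test_ids`, `train_classes` (named factor over `train_ids`), `fold_of`
#'   (`NULL` until [assign_folds()]), `seed`, `repeat_index`.
#' @export
split_cross_platform <- function(train_labels, other_platform_ids,
                                 frac = 0.75, seed = 1L, repeat_index = 0L) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)", call. = FALSE)
  lab <- droplevels(factor(train_labels))
  set.seed(seed)
  train_ids <- character(0)
  for (cl in levels(lab)) {
    ids_c <- names(lab)[lab == cl]
    n_take <- floor(frac * length(ids_c))
    if (n_take == 0L) {
      warning("class '", cl, "' contributes no training samples at frac = ",
              frac, call. = FALSE)
      next
    }
    train_ids <- c(train_ids, sample(ids_c, n_take))
  }
  test_ids <- setdiff(other_platform_ids, train_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 train_classes = lab[train_ids], fold_of = NULL,
                 seed = seed, repeat_index = repeat_index),
            class = "partition_plan")
}

#' Stratified k-fold assignment on the training samples
#'
#' Within each class the training IDs are shuffled (seeded) and dealt
#' round-robin into k folds, so per-class fold sizes differ by at most one.
#'
#' @param plan a [split_cross_platform()] plan.
#' @param k number of folds (default 10).
#' @param seed integer seed; defaults to the plan's seed.
#' @return The plan with `fold_of` filled in: a named integer vector
#'   (fold 1..k) over the training IDs.
#' @export
assign_folds <- function(plan, k = 10L, seed = plan$seed) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- length(plan$train_ids)
  if (k > n) stop("k = ", k, " exceeds the training size ", n, call. = FALSE)
  lab <- plan$train_classes
  set.seed(seed)
  fold_of <- integer(0)
  for (cl in levels(droplevels(lab))) {
    ids_c <- names(lab)[lab == cl]
    ids_c <- sample(ids_c)
    f <- ((seq_along(ids_c) - 1L) %% k) + 1L
    fold_of <- c(fold_of, stats::setNames(f, ids_c))
  }
  plan$fold_of <- fold_of[plan$train_ids]
  plan$k <- k
  plan
}

#' Build the repeated-partition schedule
#'
#' One plan per repeat; repeat r uses seed `base_seed + r - 1` for the split
#' and a derived seed for fold assignment, so plans are reproducible and
#' mutually independent.
#'
#' @inheritParams split_cross_platform
#' @param k folds per repeat.
#' @param n_repeats number of repeats (default 5).
#' @param base_seed integer.
#' @return list of `partition_plan`s with folds assigned.
#' @export
make_repeats <- function(train_labels, other_platform_ids, frac = 0.75,
                         k = 10L, n_repeats = 5L, base_seed = 1L) {
  lapply(seq_len(n_repeats), function(r) {
    plan <- split_cross_platform(train_labels, other_platform_ids, frac,
                                 seed = base_seed + r - 1L,
                                 repeat_index = r - 1L)
    assign_folds(plan, k = k, seed = base_seed + r - 1L + 500000L)
  })
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("partition_plan[repeat %d, seed %d]: %d train / %d test%s\n",
              x$repeat_index, x$seed, length(x$train_ids), length(x$test_ids),
              if (is.null(x$fold_of)) "" else sprintf(", %d folds", x$k)))
  invisible(x)
}

#' Serialize a partition plan to JSON
#' @param plan a `partition_plan`.
#' @param path output path.
#' @export
write_partition_plan <- function(plan, path) {
  jsonlite::write_json(
    list(repeat_index = plan$repeat_index, seed = plan$seed,
         train_ids = plan$train_ids, test_ids = plan$test_ids,
         fold_of = as.list(plan$fold_of)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
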