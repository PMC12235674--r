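#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric matrix holding gene expression values,
#' genes in rows and samples in columns. Gene and sample identifiers live in
#' `rownames`/`colnames`; two attributes record provenance: `platform`
#' (free-text tag such as `"microarray"` or `"rnaseq"`) and `scale`
#' (`"linear"` for intensity/count-like values, `"log"` for additive-scale
#' values such as log2 intensities, z-scores or normal scores).
#'
#' @param values numeric matrix, rows = genes, columns = samples; `rownames`
#'   and `colnames` must be present and unique.
#' @param platform character tag for the measurement platform.
#' @param scale `"linear"` or `"log"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, platform = "unknown", scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix needs both rownames (genes) and colnames (samples)",
         call. = FALSE)
  dup_g <- gid[duplicated(gid)]
  if (length(dup_g))
    stop("duplicate gene ID: ", dup_g[1L], call. = FALSE)
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s))
    stop("duplicate sample ID: ", dup_s[1L], call. = FALSE)
  structure(values, platform = platform, scale = scale, class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [platform: %s, scale: %s]\n",
              nrow(x), ncol(x), attr(x, "platform"), attr(x, "scale")))
  if (anyNA(x)) cat(sprintf("  missing entries: %d\n", sum(is.na(x))))
  invisible(x)
}

# subsetting keeps the class and provenance attributes
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out, platform = attr(x, "platform"),
                     scale = attr(x, "scale"), class = "expr_matrix")
  out
}

is_log_scale <- function(x) identical(attr(x, "scale"), "log")

MISSING_TOKENS <- c("", "na", "nan", "null")

detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression matrix
#'
#' Expects one header row of sample IDs and a first column of gene IDs; the
#' delimiter is inferred from the file extension (`.csv` = comma, anything
#' else = tab). Empty fields and the tokens `NA`, `NaN`, `null`
#' (case-insensitive) are read as missing values and preserved as `NA`.
#'
#' @param path file path.
#' @param platform platform tag stored on the result.
#' @return An [expr_matrix] (scale `"linear"`), possibly containing `NA`s.
#' @export
read_expression <- function(path, platform = "unknown") {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  gid <- raw[[1L]]
  sid <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  miss <- matrix(tolower(trimws(body)) %in% MISSING_TOKENS, nrow = nrow(body))
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !miss, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene row %d ('%s'), sample column %d ('%s')",
                 body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], gid[bad[1L, 1L]],
                 bad[1L, 2L], sid[bad[1L, 2L]]), call. = FALSE)
  num[miss] <- NA_real_
  dimnames(num) <- list(gid, sid)
  expr_matrix(num, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' @param x an [expr_matrix].
#' @param path output path; first column `gene_id`, then one column per sample.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-label table
#'
#' Two delimited columns (sample ID, class label). A header row is optional:
#' the first line is skipped when its fields look like column headers
#' (case-insensitively `sample_id`/`sample`/`id` or `label`/`class`/`subtype`).
#'
#' @param path file path (`.csv` = comma-delimited, else tab).
#' @return A named factor: names are sample IDs, levels are the distinct
#'   class labels in order of first appearance.
#' @export
read_labels <- function(path) {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = FALSE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("label file needs two columns (sample_id, label)", call. = FALSE)
  header_like <- tolower(trimws(raw[1L, 2L])) %in% c("label", "class", "subtype") ||
    tolower(trimws(raw[1L, 1L])) %in% c("sample_id", "sample", "id")
  if (header_like) raw <- raw[-1L, , drop = FALSE]
  ids <- trimws(raw[[1L]]); labs <- trimws(raw[[2L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ID in label file: ", ids[duplicated(ids)][1L], call. = FALSE)
  subtype_labels(stats::setNames(labs, ids))
}

#' Construct a subtype-label object
#'
#' @param x a named character vector or named factor (names = sample IDs).
#' @param class_order optional explicit ordering of the class labels; default
#'   is order of first appearance.
#' @return A named factor whose levels are the fixed class order.
#' @export
subtype_labels <- function(x, class_order = NULL) {
  if (is.null(names(x)) || anyNA(names(x)))
    stop("labels must be named by sample ID", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate sample ID in labels: ",
         names(x)[duplicated(names(x))][1L], call. = FALSE)
  vals <- as.character(x)
  if (is.null(class_order)) class_order <- unique(vals)
  if (length(class_order) < 2L)
    stop("need at least 2 distinct class labels", call. = FALSE)
  factor(stats::setNames(vals, names(x)), levels = class_order)
}

#' Clean and match two platform matrices
#'
#' Restricts each matrix to its labelled samples, keeps only genes present on
#' both platforms, drops every gene carrying at least one missing value on
#' either platform, and reorders both matrices to a common lexicographic gene
#' order. Samples present on only one platform are retained (overlap between
#' platforms is handled at partition time, not here).
#'
#' @param raw_a,raw_b [expr_matrix] objects from the two platforms.
#' @param labels named factor from [subtype_labels()] / [read_labels()].
#' @return A list of class `cleaned_pair` with elements `matrix_a`,
#'   `matrix_b`, `labels`, and a `dropped` element recording counts of removed
#'   genes and samples.
#' @export
clean_and_match <- function(raw_a, raw_b, labels) {
  keep_a <- colnames(raw_a)[colnames(raw_a) %in% names(labels)]
  keep_b <- colnames(raw_b)[colnames(raw_b) %in% names(labels)]
  if (!length(keep_a) || !length(keep_b))
    stop("a matrix has no labelled samples after label filtering", call. = FALSE)
  a <- raw_a[, keep_a]
  b <- raw_b[, keep_b]
  shared <- intersect(rownames(a), rownames(b))
  if (!length(shared)) stop("no genes shared between the two matrices", call. = FALSE)
  a <- a[shared, ]; b <- b[shared, ]
  has_na <- rowSums(is.na(unclass(a))) > 0 | rowSums(is.na(unclass(b))) > 0
  kept <- sort(shared[!has_na])
  if (!length(kept)) stop("no genes shared between the two matrices survive missing-value removal", call. = FALSE)
  dropped <- list(
    samples_a = ncol(raw_a) - length(keep_a),
    samples_b = ncol(raw_b) - length(keep_b),
    genes_unshared = nrow(raw_a) + nrow(raw_b) - 2L * length(shared),
    genes_missing = sum(has_na)
  )
  message(sprintf(
    "clean_and_match: kept %d genes (%d dropped for missing values); dropped %d/%d unlabelled samples (a/b)",
    length(kept), dropped$genes_missing, dropped$samples_a, dropped$samples_b))
  used <- union(keep_a, keep_b)
  structure(list(matrix_a = a[kept, ], matrix_b = b[kept, ],
                 labels = labels[names(labels) %in% used],
                 dropped = dropped),
            class = "cleaned_pair")
}

#' @export
print.cleaned_pair <- function(x, ...) {
  cat(sprintf("cleaned_pair: %d matched genes; %d + %d labelled samples (%s / %s)\n",
              nrow(x$matrix_a), ncol(x$matrix_a), ncol(x$matrix_b),
              attr(x$matrix_a, "platform"), attr(x$matrix_b, "platform")))
  invisible(x)
}

#' Write a JSON run manifest
#'
#' @param path output path.
#' @param ... named entries (seeds, counts, file paths) to record.
#' @export
write_manifest <- function(path, ...) {
  entries <- list(...)
  entries$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
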