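#' Construct an expression set
#'
#' The central container of the package: a non-negative integer count matrix
#' (features in rows, samples in columns) together with a feature table
#' assigning every feature to one RNA class and a sample table assigning
#' every sample to one group.
#'
#' @param counts Integer matrix, features x samples, with row and column
#'   names. Counts must be finite, integer-valued and non-negative.
#' @param features Data frame with columns `feature_id` and `rna_class`
#'   (one of `"mRNA"`, `"lncRNA"`, `"miRNA"`, `"circRNA"`), one row per
#'   matrix row, in matrix order.
#' @param samples Data frame with columns `sample_id` and `group` (one of
#'   `"cold"`, `"control"`), one row per matrix column, in matrix order.
#'
#' @return An object of class `expr_set`: a list with elements `counts`,
#'   `features` (tibble) and `samples` (tibble).
#' @examples
#' counts <- matrix(c(5L, 0L, 3L, 8L), 2, 2,
#'                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' es <- expr_set(counts,
#'                features = data.frame(feature_id = c("g1", "g2"),
#'                                      rna_class = "mRNA"),
#'                samples = data.frame(sample_id = c("s1", "s2"),
#'                                     group = c("cold", "control")))
#' es
#' @export
expr_set <- function(counts, features, samples) {
  features <- as_tibble(features)
  samples <- as_tibble(samples)
  es <- structure(list(counts = counts, features = features,
                       samples = samples),
                  class = "expr_set")
  validate_expr_set(es)
}

#' Validate an expression set
#'
#' Checks every structural invariant of [expr_set()]: unique feature and
#' sample ids matching the matrix dimnames, finite non-negative integer
#' counts, known RNA classes and groups. Returns its input invisibly-valid
#' or raises a descriptive error; there is no silent coercion.
#'
#' @param es An `expr_set`.
#' @return `es`, invisibly validated.
#' @export
validate_expr_set <- function(es) {
  counts <- es$counts
  if (!is.matrix(counts)) stop_input("`counts` must be a matrix")
  fid <- es$features$feature_id
  sid <- es$samples$sample_id
  if (anyDuplicated(fid)) {
    stop_input(paste0("duplicate feature id(s): ",
                      paste(unique(fid[duplicated(fid)]), collapse = ", ")),
               class = "cernascreen_format_error")
  }
  if (anyDuplicated(sid)) {
    stop_input(paste0("duplicate sample id(s): ",
                      paste(unique(sid[duplicated(sid)]), collapse = ", ")),
               class = "cernascreen_format_error")
  }
  if (!identical(rownames(counts), as.character(fid)) ||
      !identical(colnames(counts), as.character(sid))) {
    stop_input("dimnames of `counts` must match feature/sample tables in order",
               class = "cernascreen_consistency_error")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop_input(sprintf(
      "invalid count at feature '%s', sample '%s': %s (counts must be finite non-negative integers)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])),
      class = "cernascreen_format_error")
  }
  if (!all(es$features$rna_class %in% RNA_CLASSES)) {
    stop_input(paste0("unknown rna_class: ",
                      paste(setdiff(es$features$rna_class, RNA_CLASSES),
                            collapse = ", ")))
  }
  if (!all(es$samples$group %in% GROUPS)) {
    stop_input(paste0("unknown group: ",
                      paste(setdiff(es$samples$group, GROUPS), collapse = ", ")))
  }
  invisible(es)
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cls <- table(factor(x$features$rna_class, levels = RNA_CLASSES))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  grp <- table(factor(x$samples$group, levels = GROUPS))
  cat("  groups: ", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy an expression set into a long tibble
#'
#' @param x An `expr_set`.
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) cell: `feature_id`,
#'   `rna_class`, `sample_id`, `group`, `count`.
#' @export
tidy.expr_set <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x$counts), times = ncol(x$counts)),
    rna_class = rep(x$features$rna_class, times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    group = rep(x$samples$group, each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Normalized counts of an expression set
#'
#' Divides each sample's counts by its size factor.
#'
#' @param es An `expr_set`.
#' @param size_factors Per-sample positive scale factors, as returned by
#'   [size_factors()]; defaults to computing them from `es`.
#' @return A numeric matrix of normalized counts, same dimnames as the input.
#' @export
normalized_counts <- function(es, size_factors = NULL) {
  sf <- size_factors %||% cernascreen::size_factors(es)
  sweep(es$counts, 2, sf, "/")
}
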