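#' Read a count table with its metadata
#'
#' The count file is a TSV whose header row holds sample ids and whose first
#' column holds feature ids. The metadata file is a TSV with columns `id`,
#' `role` and `label`: rows with `role = "sample"` map sample id to group
#' (`cold`/`control`), rows with `role = "feature"` map feature id to RNA
#' class. Row and column order of the count file is preserved.
#'
#' @param path Path to the count TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A validated [expr_set()].
#' @seealso [write_counts()] for the inverse.
#' @export
read_counts <- function(path, metadata_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(raw) < 2) stop_input("count file needs a feature column and at least one sample")
  fid <- raw[[1]]
  sid <- colnames(raw)[-1]
  mat <- matrix(NA_integer_, nrow(raw), length(sid),
                dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    v <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | !is.finite(num) | num < 0 | num != round(num))
    if (length(bad)) {
      stop_input(sprintf(
        "invalid count '%s' at feature '%s', sample '%s'",
        v[bad[1]], fid[bad[1]], sid[j]),
        class = "cernascreen_format_error")
    }
    mat[, j] <- as.integer(num)
  }

  meta <- read_metadata(metadata_path)
  missing_s <- setdiff(sid, meta$samples$sample_id)
  if (length(missing_s)) {
    stop_input(paste0("sample(s) in count header absent from metadata: ",
                      paste(missing_s, collapse = ", ")),
               class = "cernascreen_consistency_error")
  }
  missing_f <- setdiff(fid, meta$features$feature_id)
  if (length(missing_f)) {
    stop_input(paste0("feature(s) absent from metadata: ",
                      paste(head(missing_f, 5), collapse = ", ")),
               class = "cernascreen_consistency_error")
  }
  expr_set(mat,
           features = meta$features[match(fid, meta$features$feature_id), ],
           samples = meta$samples[match(sid, meta$samples$sample_id), ])
}

read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    role = readr::col_character(),
    label = readr::col_character()))
  if (!all(c("id", "role", "label") %in% colnames(meta))) {
    stop_input("metadata must have columns id, role, label",
               class = "cernascreen_format_error")
  }
  list(
    samples = meta |>
      filter(.data$role == "sample") |>
      select(sample_id = "id", group = "label"),
    features = meta |>
      filter(.data$role == "feature") |>
      select(feature_id = "id", rna_class = "label")
  )
}

#' Write a count table with its metadata
#'
#' Inverse of [read_counts()]; `read_counts(write_counts(es))` reproduces
#' `es` exactly.
#'
#' @param es An [expr_set()].
#' @param path Output path for the count TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return `es`, invisibly.
#' @export
write_counts <- function(es, path, metadata_path) {
  validate_expr_set(es)
  tab <- bind_cols(tibble(feature_id = rownames(es$counts)),
                   as_tibble(es$counts))
  readr::write_tsv(tab, path)
  meta <- bind_rows(
    tibble(id = es$samples$sample_id, role = "sample",
           label = es$samples$group),
    tibble(id = es$features$feature_id, role = "feature",
           label = es$features$rna_class))
  readr::write_tsv(meta, metadata_path)
  invisible(es)
}
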