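#' Venn-style overlap report of differential features and targeting
#'
#' Summarises, per RNA class, how many differential features exist and how
#' many of them participate in at least one targeting relation with a
#' differential feature of another class (miRNA seed interactions for
#' miRNA/mRNA/sponge classes; cis/trans pairs for lncRNA-mRNA), mirroring
#' the Venn screens that feed ceRNA assembly.
#'
#' @param de_records Classified records from [de_test()].
#' @param interactions From [build_interactions()].
#' @param lnc_pairs From [lnc_cis_targets()] / [lnc_trans_targets()]
#'   (rows may mix modes).
#' @return A tibble: `rna_class`, `n_de`, `n_de_linked` (differential
#'   features with >= 1 relation to another differential feature).
#' @export
venn_overlap <- function(de_records, interactions, lnc_pairs) {
  de <- de_records |> filter(.data$status != "ns")
  de_ids <- split(de$feature_id, de$rna_class)
  de_mirna <- de_ids[["miRNA"]] %||% character(0)
  de_mrna <- de_ids[["mRNA"]] %||% character(0)
  de_lnc <- de_ids[["lncRNA"]] %||% character(0)
  de_circ <- de_ids[["circRNA"]] %||% character(0)

  ia <- interactions |>
    filter(.data$mirna_id %in% de_mirna,
           .data$target_id %in% c(de_mrna, de_lnc, de_circ))
  lp <- lnc_pairs |>
    filter(.data$lnc_id %in% de_lnc, .data$mrna_id %in% de_mrna)

  linked <- list(
    miRNA = unique(ia$mirna_id),
    mRNA = unique(c(ia$target_id[ia$target_class == "mRNA"], lp$mrna_id)),
    lncRNA = unique(c(ia$target_id[ia$target_class == "lncRNA"], lp$lnc_id)),
    circRNA = unique(ia$target_id[ia$target_class == "circRNA"]))

  purrr::map_dfr(RNA_CLASSES, function(cl) {
    ids <- de_ids[[cl]] %||% character(0)
    tibble(rna_class = cl, n_de = length(ids),
           n_de_linked = length(intersect(ids, linked[[cl]])))
  })
}

#' Assemble direction-consistent ceRNA triads
#'
#' For every differential mRNA `m`, every differential miRNA with status
#' opposite to `m` and a seed interaction with `m`, and every differential
#' sponge with status equal to `m` and a seed interaction with the miRNA,
#' emits an (mRNA, miRNA, sponge) triad. circRNA sponges need only the
#' miRNA interaction; lncRNA sponges must additionally appear in
#' `lnc_pairs` with the core mRNA (cis or trans relation). Output is
#' de-duplicated and sorted by (`mrna_id`, `mirna_id`, `sponge_id`).
#'
#' @inheritParams venn_overlap
#' @return A tibble of triads: `mrna_id`, `mirna_id`, `sponge_id`,
#'   `sponge_class`, `mrna_status`, `mirna_status`, `sponge_status`,
#'   `mirna_targets_mrna`, `sponge_binds_mirna`, `lnc_mode`.
#' @export
assemble_triads <- function(de_records, interactions, lnc_pairs) {
  empty <- tibble(mrna_id = character(), mirna_id = character(),
                  sponge_id = character(), sponge_class = character(),
                  mrna_status = character(), mirna_status = character(),
                  sponge_status = character(),
                  mirna_targets_mrna = logical(),
                  sponge_binds_mirna = logical(), lnc_mode = character())
  de <- de_records |> filter(.data$status != "ns")
  status_of <- setNames(de$status, de$feature_id)
  de_by <- split(de$feature_id, de$rna_class)
  if (is.null(de_by[["mRNA"]]) || is.null(de_by[["miRNA"]])) return(empty)

  # miRNA -> mRNA edges with opposite directions
  mm <- interactions |>
    filter(.data$target_class == "mRNA",
           .data$mirna_id %in% de_by[["miRNA"]],
           .data$target_id %in% de_by[["mRNA"]]) |>
    mutate(mirna_status = unname(status_of[.data$mirna_id]),
           mrna_status = unname(status_of[.data$target_id])) |>
    filter(.data$mirna_status != .data$mrna_status) |>
    select(mrna_id = "target_id", "mirna_id", "mrna_status", "mirna_status")
  if (!nrow(mm)) return(empty)

  # miRNA -> sponge edges
  sponges <- interactions |>
    filter(.data$target_class %in% c("lncRNA", "circRNA"),
           .data$mirna_id %in% de_by[["miRNA"]],
           .data$target_id %in% c(de_by[["lncRNA"]], de_by[["circRNA"]])) |>
    mutate(sponge_status = unname(status_of[.data$target_id])) |>
    select(sponge_id = "target_id", sponge_class = "target_class",
           "mirna_id", "sponge_status")

  triads <- mm |>
    inner_join(sponges, by = "mirna_id", relationship = "many-to-many") |>
    filter(.data$sponge_status == .data$mrna_status,
           .data$sponge_id != .data$mrna_id)

  # lncRNA sponges must also be a cis/trans partner of the core mRNA
  lnc_key <- lnc_pairs |>
    mutate(key = paste(.data$lnc_id, .data$mrna_id))
  mode_of <- lnc_key |> distinct(.data$key, .keep_all = TRUE)
  triads <- triads |>
    mutate(key = paste(.data$sponge_id, .data$mrna_id)) |>
    filter(.data$sponge_class == "circRNA" | .data$key %in% lnc_key$key) |>
    left_join(mode_of |> select("key", "mode"), by = "key") |>
    mutate(lnc_mode = if_else(.data$sponge_class == "lncRNA", .data$mode,
                              "n/a"),
           mirna_targets_mrna = TRUE, sponge_binds_mirna = TRUE) |>
    select("mrna_id", "mirna_id", "sponge_id", "sponge_class",
           "mrna_status", "mirna_status", "sponge_status",
           "mirna_targets_mrna", "sponge_binds_mirna", "lnc_mode") |>
    distinct() |>
    arrange(.data$mrna_id, .data$mirna_id, .data$sponge_id)
  triads
}

#' Restrict triads to a functional term set
#'
#' Optional post-filter mirroring the comparison of enrichment results with
#' the candidate network: keep only triads whose core mRNA belongs to a
#' given term's member set (e.g. a lipid-storage annotation). Off by
#' default in the pipeline.
#'
#' @param triads Tibble from [assemble_triads()].
#' @param term_members Character vector of mRNA ids.
#' @return The filtered triad tibble.
#' @export
filter_triads_by_term <- function(triads, term_members) {
  triads |> filter(.data$mrna_id %in% term_members)
}

#' Validate ceRNA triad invariants
#'
#' Checks the direction rules on every row: mRNA and miRNA status opposite,
#' sponge status equal to the mRNA status, both interaction evidences true,
#' no `ns` member.
#'
#' @param triads Tibble from [assemble_triads()].
#' @return `triads`, invisibly; raises on any violation.
#' @export
validate_triads <- function(triads) {
  ok <- triads$mrna_status %in% c("up", "down") &
    triads$mirna_status %in% c("up", "down") &
    triads$sponge_status %in% c("up", "down") &
    triads$mrna_status != triads$mirna_status &
    triads$sponge_status == triads$mrna_status &
    triads$mirna_targets_mrna & triads$sponge_binds_mirna
  if (!all(ok)) {
    stop_input(sprintf("%d triad(s) violate the direction rules",
                       sum(!ok)))
  }
  invisible(triads)
}

#' Marker-gene normalization of an ambiguous gene
#'
#' Normalizes a gene whose bulk-tissue signal may track cell-type
#' composition rather than regulation, by dividing its normalized
#' expression by a marker-derived denominator per sample:
#' `value_j = x_target,j / sqrt(x_markA,j * x_markB,j)` (geometric form,
#' default) or `x_target,j / (x_markA,j * x_markB,j)` (plain product).
#' The geometric form is invariant to a common per-sample scaling of all
#' three features.
#'
#' @param es An [expr_set()].
#' @param target_id,marker_a_id,marker_b_id Feature ids; markers must have
#'   positive normalized expression in every sample.
#' @param size_factors Per-sample factors; computed from `es` if omitted.
#' @param form `"geometric"` (default) or `"product"`.
#' @return A tibble: `sample_id`, `group`, `value`.
#' @export
marker_normalize <- function(es, target_id, marker_a_id, marker_b_id,
                             size_factors = NULL,
                             form = c("geometric", "product")) {
  form <- match.arg(form)
  sf <- size_factors %||% cernascreen::size_factors(es)
  norm <- normalized_counts(es, sf)
  ids <- c(target_id, marker_a_id, marker_b_id)
  missing_ids <- setdiff(ids, rownames(norm))
  if (length(missing_ids)) {
    stop_input(paste0("feature(s) not found: ",
                      paste(missing_ids, collapse = ", ")))
  }
  a <- norm[marker_a_id, ]
  b <- norm[marker_b_id, ]
  zero <- a == 0 | b == 0
  if (any(zero)) {
    stop_input(paste0("zero marker expression in sample(s): ",
                      paste(colnames(norm)[zero], collapse = ", ")))
  }
  denom <- if (form == "geometric") sqrt(a * b) else a * b
  tibble(sample_id = es$samples$sample_id, group = es$samples$group,
         value = unname(norm[target_id, ] / denom))
}

#' Two-sample pooled-variance Student's t-test
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Group labels, two levels, >= 2 samples each.
#' @return A tibble with columns `t` and `p` (two-sided). With zero pooled
#'   variance: equal means give `t = 0, p = 1`; unequal means are an error.
#' @export
group_ttest <- function(values, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2 || any(table(groups) < 2)) {
    stop_input("need exactly two groups with >= 2 samples each")
  }
  x <- values[groups == lv[1]]
  y <- values[groups == lv[2]]
  if (var(x) + var(y) == 0) {
    if (mean(x) == mean(y)) return(tibble(t = 0, p = 1))
    stop_input("zero pooled variance with unequal means: t undefined")
  }
  ht <- t.test(x, y, var.equal = TRUE)
  tibble(t = unname(ht$statistic), p = ht$p.value)
}

#' Sign concordance between two fold-change sets
#'
#' Fraction of shared features whose fold changes agree in sign; a zero
#' fold change agrees only with another zero. Used to check agreement of
#' sequencing-based and qRT-PCR-based fold changes.
#'
#' @param lfc_seq,lfc_qpcr Named numeric vectors, feature -> fold change.
#' @return A fraction in `[0, 1]`.
#' @export
sign_concordance <- function(lfc_seq, lfc_qpcr) {
  shared <- intersect(names(lfc_seq), names(lfc_qpcr))
  if (!length(shared)) stop_input("no shared features")
  mean(sign(lfc_seq[shared]) == sign(lfc_qpcr[shared]))
}
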