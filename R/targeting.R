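SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")  # strongest first

check_rna <- function(x, what) {
  bad <- regexpr("[^ACGUN]", x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_input(sprintf("non-RNA character in %s at position %d", what, bad[i]))
  }
}

# Vectorized classification of 6mer-core matches. `seqs` is the target
# sequence per match (recycled), `starts` the 1-based core starts.
classify_site_starts <- function(mirna_seq, seqs, starts) {
  m8 <- chartr("ACGU", "UGCA", substr(mirna_seq, 8, 8))
  prev <- substring(seqs, starts - 1, starts - 1)
  nxt <- substring(seqs, starts + 6, starts + 6)   # "" past the end
  has_m8 <- starts > 1 & prev == m8
  has_a1 <- nxt == "A"
  rank <- ifelse(has_m8 & has_a1, 1L,
                 ifelse(has_m8, 2L, ifelse(has_a1, 3L, 4L)))
  tibble(position = as.integer(ifelse(has_m8, starts - 2L, starts - 1L)),
         site_type = SITE_TYPES[rank])
}

#' Find canonical miRNA seed sites on a target sequence
#'
#' Scans the target for occurrences of the seed core — the reverse
#' complement of miRNA positions 2-7 written 5'->3' — and classifies each
#' occurrence by the canonical site taxonomy: `6mer` (core only), `7mer-m8`
#' (core preceded on the target by the complement of miRNA position 8),
#' `7mer-A1` (core followed by an `A`), `8mer` (both). Overlapping
#' occurrences are reported independently; each occurrence is reported once
#' with its highest-ranking type. Positions are 0-based starts of the full
#' site on the target.
#'
#' @param mirna_seq miRNA sequence (RNA alphabet, 5'->3', length >= 8).
#' @param target_seq Target sequence (RNA alphabet).
#' @return A tibble with columns `position` and `site_type`, ordered by
#'   position; zero rows when the core never occurs.
#' @export
seed_sites <- function(mirna_seq, target_seq) {
  if (nchar(mirna_seq) < 8) stop_input("miRNA must be >= 8 nt")
  check_rna(mirna_seq, "miRNA")
  check_rna(target_seq, "target")
  core <- seed_core(mirna_seq)
  hits <- Biostrings::matchPattern(core, Biostrings::BString(target_seq))
  starts <- sort(BiocGenerics::start(hits))
  if (!length(starts)) {
    return(tibble(position = integer(), site_type = character()))
  }
  classify_site_starts(mirna_seq, rep(target_seq, length(starts)), starts)
}

#' Build the miRNA-target interaction table
#'
#' Aggregates [seed_sites()] over every (miRNA, target) pair using a
#' vectorized core scan; pairs without sites never materialize. circRNA
#' targets may optionally be scanned across the back-splice junction by
#' appending the first 7 nucleotides to the end of the sequence, since a
#' circular molecule has no 3' end.
#'
#' @param mirna_seqs Named character vector of miRNA sequences.
#' @param target_seqs Named character vector of target sequences.
#' @param target_classes Named character vector mapping every target id to
#'   its RNA class.
#' @param circular_junction If `TRUE`, extend circRNA targets across the
#'   back-splice junction (default `FALSE`: circRNAs scanned as linear
#'   strings).
#' @return A tibble with one row per interacting pair: `mirna_id`,
#'   `target_id`, `target_class`, `n_sites`, `best_site_type`; ordered by
#'   (`mirna_id`, `target_id`).
#' @export
build_interactions <- function(mirna_seqs, target_seqs, target_classes,
                               circular_junction = FALSE) {
  if (!length(mirna_seqs) || !length(target_seqs)) {
    stop_input("sequence maps must be non-empty")
  }
  missing_cls <- setdiff(names(target_seqs), names(target_classes))
  if (length(missing_cls)) {
    stop_input(paste0("target(s) lacking a class: ",
                      paste(head(missing_cls, 5), collapse = ", ")))
  }
  scan_seqs <- target_seqs
  if (circular_junction) {
    is_circ <- target_classes[names(target_seqs)] == "circRNA"
    scan_seqs[is_circ] <- paste0(target_seqs[is_circ],
                                 substr(target_seqs[is_circ], 1, 7))
  }
  rows <- purrr::map_dfr(names(mirna_seqs), function(mi) {
    core <- seed_core(mirna_seqs[[mi]])
    loc <- stringi::stri_locate_all_fixed(scan_seqs, core, overlap = TRUE)
    n_hit <- vapply(loc, function(m) sum(!is.na(m[, 1])), 0L)
    idx <- which(n_hit > 0)
    if (!length(idx)) return(NULL)
    t_idx <- rep(idx, n_hit[idx])
    starts <- unlist(lapply(loc[idx], function(m) m[, 1]), use.names = FALSE)
    sites <- classify_site_starts(mirna_seqs[[mi]], scan_seqs[t_idx], starts)
    tibble(target_i = t_idx,
           rank = match(sites$site_type, SITE_TYPES)) |>
      group_by(.data$target_i) |>
      summarise(n_sites = dplyr::n(), best = min(.data$rank)) |>
      mutate(mirna_id = mi, target_id = names(scan_seqs)[.data$target_i],
             best_site_type = SITE_TYPES[.data$best]) |>
      select("mirna_id", "target_id", "n_sites", "best_site_type")
  })
  if (!nrow(rows)) {
    return(tibble(mirna_id = character(), target_id = character(),
                  target_class = character(), n_sites = integer(),
                  best_site_type = character()))
  }
  rows |>
    mutate(target_class = unname(target_classes[.data$target_id])) |>
    select("mirna_id", "target_id", "target_class", "n_sites",
           "best_site_type") |>
    arrange(.data$mirna_id, .data$target_id)
}

#' Cis lncRNA-mRNA target pairs by genomic proximity
#'
#' A (lncRNA, mRNA) pair is a cis pair iff both lie on the same chromosome
#' with a gap distance (0 if overlapping or adjacent) at most `window` base
#' pairs. Coordinates are 0-based half-open; distances computed via
#' GenomicRanges.
#'
#' @param lnc_annotations,mrna_annotations Annotation tibbles with columns
#'   `feature_id`, `chrom`, `start`, `end`.
#' @param window Maximum gap in bp (default 100000).
#' @return A tibble: `lnc_id`, `mrna_id`, `mode = "cis"`, `evidence`
#'   (the distance in bp).
#' @export
lnc_cis_targets <- function(lnc_annotations, mrna_annotations,
                            window = 1e5) {
  check_coords <- function(ann, what) {
    need <- c("feature_id", "chrom", "start", "end")
    if (!all(need %in% colnames(ann)) || any(is.na(ann$start) | is.na(ann$end))) {
      stop_input(paste0("missing coordinates in ", what, " annotation"))
    }
  }
  check_coords(lnc_annotations, "lncRNA")
  check_coords(mrna_annotations, "mRNA")
  lev <- union(lnc_annotations$chrom, mrna_annotations$chrom)
  gr <- function(ann) {
    GenomicRanges::GRanges(factor(ann$chrom, levels = lev),
                           IRanges::IRanges(ann$start + 1, ann$end))
  }
  lg <- gr(lnc_annotations)
  mg <- gr(mrna_annotations)
  hits <- GenomicRanges::findOverlaps(lg, mg, maxgap = window,
                                      ignore.strand = TRUE)
  if (!length(hits)) {
    return(tibble(lnc_id = character(), mrna_id = character(),
                  mode = character(), evidence = numeric()))
  }
  d <- GenomicRanges::distance(lg[S4Vectors::queryHits(hits)],
                               mg[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  tibble(lnc_id = lnc_annotations$feature_id[S4Vectors::queryHits(hits)],
         mrna_id = mrna_annotations$feature_id[S4Vectors::subjectHits(hits)],
         mode = "cis", evidence = as.numeric(d)) |>
    filter(.data$evidence <= window) |>
    arrange(.data$lnc_id, .data$mrna_id)
}

#' Trans lncRNA-mRNA target pairs by expression correlation
#'
#' Pearson correlation of `log10(normalized count + 1)` across all samples;
#' a pair is a trans pair iff `|r| >= r_threshold`. With only six samples
#' this criterion is permissive; the threshold is deliberately high.
#'
#' @param es An [expr_set()] with >= 4 samples.
#' @param lnc_ids,mrna_ids Feature ids to correlate.
#' @param size_factors Per-sample factors; computed from `es` if omitted.
#' @param r_threshold Absolute correlation cutoff (default 0.9).
#' @return A tibble: `lnc_id`, `mrna_id`, `mode = "trans"`, `evidence`
#'   (the correlation r). Zero-variance features are excluded with a
#'   warning.
#' @export
lnc_trans_targets <- function(es, lnc_ids, mrna_ids, size_factors = NULL,
                              r_threshold = 0.9) {
  if (ncol(es$counts) < 4) stop_input("trans correlation needs >= 4 samples")
  sf <- size_factors %||% cernascreen::size_factors(es)
  x <- log10(normalized_counts(es, sf) + 1)
  keep_var <- function(ids, what) {
    v <- apply(x[ids, , drop = FALSE], 1, sd)
    if (any(v == 0)) {
      warning(sprintf("excluding %d zero-variance %s feature(s)",
                      sum(v == 0), what))
    }
    ids[v > 0]
  }
  lnc_ids <- keep_var(lnc_ids, "lncRNA")
  mrna_ids <- keep_var(mrna_ids, "mRNA")
  if (!length(lnc_ids) || !length(mrna_ids)) {
    return(tibble(lnc_id = character(), mrna_id = character(),
                  mode = character(), evidence = numeric()))
  }
  r <- cor(t(x[lnc_ids, , drop = FALSE]), t(x[mrna_ids, , drop = FALSE]))
  idx <- which(abs(r) >= r_threshold, arr.ind = TRUE)
  tibble(lnc_id = lnc_ids[idx[, 1]], mrna_id = mrna_ids[idx[, 2]],
         mode = "trans", evidence = r[idx]) |>
    arrange(.data$lnc_id, .data$mrna_id)
}
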