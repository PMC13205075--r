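#' Configure a pipeline run
#'
#' Collects every knob of the screen in one validated, serializable object:
#' either a simulation block (the synthetic experiment is generated first)
#' or paths to existing inputs, plus thresholds, targeting parameters,
#' marker-normalization settings and the master seed.
#'
#' @param outdir Output directory (created if missing).
#' @param simulate If `TRUE` (default) the inputs are generated by
#'   [simulate_experiment()] from `sim`; otherwise `inputs` paths are read.
#' @param sim Named list of [sim_config()] arguments (without `seed`).
#' @param inputs Named list of paths: `counts`, `metadata`, `fasta`,
#'   `gmt`, `annotation` (annotation TSV with `feature_id`, `rna_class`,
#'   `chrom`, `start`, `end`, `strand`). Required when `simulate = FALSE`.
#' @param lfc_cut,p_cut Classification thresholds (see [de_thresholds()]).
#' @param pseudocount Pseudocount for the Wald test.
#' @param cis_window Cis-targeting window in bp.
#' @param trans_r_threshold Trans-targeting |r| cutoff.
#' @param norm_form Marker normalization form, `"geometric"` or
#'   `"product"`.
#' @param norm_target,marker_a,marker_b Feature ids for marker
#'   normalization; `NULL` (default) uses the simulation truth's markers,
#'   or skips the stage for real inputs.
#' @param seed Master integer seed; mandatory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, simulate = TRUE, sim = list(),
                            inputs = NULL,
                            lfc_cut = 0.6,
                            p_cut = c(mRNA = 0.05, lncRNA = 0.05,
                                      miRNA = 0.01, circRNA = 0.01),
                            pseudocount = 0.5,
                            cis_window = 1e5, trans_r_threshold = 0.9,
                            norm_form = "geometric",
                            norm_target = NULL, marker_a = NULL,
                            marker_b = NULL, seed) {
  if (missing(seed)) stop_input("`seed` is mandatory")
  if (missing(outdir)) stop_input("`outdir` is mandatory")
  cfg <- list(outdir = outdir, simulate = isTRUE(simulate), sim = sim,
              inputs = inputs, lfc_cut = lfc_cut, p_cut = as.list(p_cut),
              pseudocount = pseudocount, cis_window = cis_window,
              trans_r_threshold = trans_r_threshold, norm_form = norm_form,
              norm_target = norm_target, marker_a = marker_a,
              marker_b = marker_b, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$lfc_cut <= 0) stop_input("lfc_cut must be positive")
  pc <- unlist(cfg$p_cut)
  if (!all(RNA_CLASSES %in% names(pc)) || any(pc <= 0 | pc > 1)) {
    stop_input("p_cut must name all four classes with values in (0, 1]")
  }
  if (!cfg$simulate) {
    need <- c("counts", "metadata", "fasta", "gmt", "annotation")
    have <- names(cfg$inputs %||% list())
    missing_in <- setdiff(need, have)
    if (length(missing_in)) {
      stop_input(paste0("simulate = FALSE but input path(s) missing: ",
                        paste(missing_in, collapse = ", ")))
    }
    paths <- unlist(cfg$inputs[need])
    if (anyDuplicated(paths)) stop_input("input paths must be distinct")
  }
  if (!cfg$norm_form %in% c("geometric", "product")) {
    stop_input("norm_form must be 'geometric' or 'product'")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' `write_pipeline_config()` then `read_pipeline_config()` round-trips the
#' configuration exactly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return The configuration.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  # yaml drops names of atomic vectors; store them as maps
  if (!is.null(raw$sim$n_de_per_class)) {
    raw$sim$n_de_per_class <- as.list(raw$sim$n_de_per_class)
  }
  yaml::write_yaml(raw, path)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$p_cut <- unlist(raw$p_cut)
  if (!is.null(raw$sim$n_de_per_class)) {
    raw$sim$n_de_per_class <- unlist(raw$sim$n_de_per_class)
  }
  do.call(pipeline_config, raw)
}

stage_log <- function(log, stage, ...) {
  c(log, sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the complete screen
#'
#' Executes the stages in order — simulate (or load), differential
#' expression + PCA, targeting, ceRNA assembly, enrichment, marker
#' normalization — writing every result as TSV (plus GraphML for the
#' network) under `config$outdir`, together with a plain-text run log and a
#' JSON manifest recording an MD5 content hash for every produced file.
#' Identical configuration and seed reproduce identical hashes.
#'
#' @param config A [pipeline_config()].
#' @return A list: `manifest` (named MD5 hashes), `log` (character),
#'   `results` (the in-memory stage outputs), `paths` (output files).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$outdir, name)
  paths <- character(0)
  log <- character(0)

  # --- inputs ---------------------------------------------------------
  if (config$simulate) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim <- simulate_experiment(scfg)
    es <- sim$expr
    annotation <- sim$annotation
    seqs <- sim$sequences
    terms <- sim$terms
    truth <- sim$truth
    write_counts(es, out("counts.tsv"), out("metadata.tsv"))
    write_fasta(seqs, out("sequences.fasta"))
    write_gmt(terms, out("terms.gmt"))
    readr::write_tsv(annotation, out("annotation.tsv"))
    readr::write_tsv(truth$planted_triads, out("truth_triads.tsv"))
    paths <- c(paths, out("counts.tsv"), out("metadata.tsv"),
               out("sequences.fasta"), out("terms.gmt"),
               out("annotation.tsv"), out("truth_triads.tsv"))
    log <- stage_log(log, "simulate", "%d features x %d samples, %d planted triads",
                     nrow(es$counts), ncol(es$counts),
                     nrow(truth$planted_triads))
  } else {
    es <- read_counts(config$inputs$counts, config$inputs$metadata)
    seqs <- read_fasta(config$inputs$fasta)
    terms <- read_gmt(config$inputs$gmt)
    annotation <- readr::read_tsv(config$inputs$annotation,
                                  col_types = readr::cols())
    truth <- NULL
    log <- stage_log(log, "load", "%d features x %d samples",
                     nrow(es$counts), ncol(es$counts))
  }

  thresholds <- list(lfc_cut = config$lfc_cut, p_cut = unlist(config$p_cut))

  # --- differential expression ---------------------------------------
  sf <- size_factors(es)
  de <- de_test(es, thresholds, config$pseudocount)
  readr::write_tsv(de, out("de_records.tsv"))
  paths <- c(paths, out("de_records.tsv"))
  de_counts <- de |> filter(.data$status != "ns") |>
    dplyr::count(.data$rna_class)
  log <- stage_log(log, "de", "differential features: %s",
                   paste(sprintf("%s=%d", de_counts$rna_class, de_counts$n),
                         collapse = ", "))
  pca <- pca_samples(es, sf)
  readr::write_tsv(tidy(pca), out("pca_scores.tsv"))
  paths <- c(paths, out("pca_scores.tsv"))

  # --- targeting ------------------------------------------------------
  cls <- setNames(es$features$rna_class, es$features$feature_id)
  mirna_seqs <- seqs[names(cls)[cls == "miRNA"]]
  target_seqs <- seqs[names(cls)[cls != "miRNA"]]
  interactions <- build_interactions(mirna_seqs, target_seqs, cls)
  readr::write_tsv(interactions, out("interactions.tsv"))
  de_ids <- split(de$feature_id[de$status != "ns"],
                  de$rna_class[de$status != "ns"])
  cis <- lnc_cis_targets(
    annotation |> filter(.data$rna_class == "lncRNA"),
    annotation |> filter(.data$rna_class == "mRNA"),
    window = config$cis_window)
  lnc_de <- de_ids[["lncRNA"]] %||% character(0)
  mrna_de <- de_ids[["mRNA"]] %||% character(0)
  trans <- if (length(lnc_de) && length(mrna_de)) {
    lnc_trans_targets(es, lnc_de, mrna_de, sf,
                      r_threshold = config$trans_r_threshold)
  } else {
    tibble(lnc_id = character(), mrna_id = character(),
           mode = character(), evidence = numeric())
  }
  lnc_pairs <- bind_rows(cis, trans)
  readr::write_tsv(lnc_pairs, out("lnc_pairs.tsv"))
  paths <- c(paths, out("interactions.tsv"), out("lnc_pairs.tsv"))
  log <- stage_log(log, "targets",
                   "%d seed interactions, %d cis pairs, %d trans pairs",
                   nrow(interactions), nrow(cis), nrow(trans))

  # --- ceRNA assembly -------------------------------------------------
  venn <- venn_overlap(de, interactions, lnc_pairs)
  readr::write_tsv(venn, out("venn_report.tsv"))
  triads <- assemble_triads(de, interactions, lnc_pairs)
  validate_triads(triads)
  readr::write_tsv(triads, out("triads.tsv"))
  write_network(triads, out("network_edges.tsv"), "edge-tsv")
  write_network(triads, out("network.graphml"), "graphml")
  paths <- c(paths, out("venn_report.tsv"), out("triads.tsv"),
             out("network_edges.tsv"), out("network.graphml"))
  log <- stage_log(log, "cerna", "%d triads", nrow(triads))

  # --- enrichment -----------------------------------------------------
  tested_mrna <- de$feature_id[de$rna_class == "mRNA" & !is.na(de$p)]
  enr <- bind_rows(
    enrich_terms(de$feature_id[de$rna_class == "mRNA" & de$status == "up"],
                 terms, tested_mrna, "up"),
    enrich_terms(de$feature_id[de$rna_class == "mRNA" & de$status == "down"],
                 terms, tested_mrna, "down"))
  readr::write_tsv(enr, out("enrichment.tsv"))
  top <- bind_rows(
    top_terms(enr |> filter(.data$direction == "up")),
    top_terms(enr |> filter(.data$direction == "down")))
  readr::write_tsv(top, out("enrichment_top.tsv"))
  paths <- c(paths, out("enrichment.tsv"), out("enrichment_top.tsv"))
  log <- stage_log(log, "enrich", "%d term records", nrow(enr))

  # --- marker normalization ------------------------------------------
  norm_target <- config$norm_target %||% truth$norm_target_id
  marker_a <- config$marker_a %||% truth$marker_ids[1]
  marker_b <- config$marker_b %||% truth$marker_ids[2]
  marker_tab <- NULL
  marker_test <- NULL
  if (!is.null(norm_target) && !is.na(norm_target)) {
    marker_tab <- marker_normalize(es, norm_target, marker_a, marker_b, sf,
                                   form = config$norm_form)
    marker_test <- group_ttest(marker_tab$value, marker_tab$group)
    readr::write_tsv(marker_tab, out("marker_normalized.tsv"))
    readr::write_tsv(marker_test, out("marker_ttest.tsv"))
    paths <- c(paths, out("marker_normalized.tsv"), out("marker_ttest.tsv"))
    log <- stage_log(log, "normalize", "target %s: t = %.3f, p = %.4g",
                     norm_target, marker_test$t, marker_test$p)
  }

  readr::write_lines(log, out("run_log.txt"))
  manifest <- setNames(as.vector(tools::md5sum(paths)), basename(paths))
  jsonlite::write_json(as.list(manifest), out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(manifest = manifest, log = log,
       results = list(expr = es, de = de, pca = pca,
                      interactions = interactions, lnc_pairs = lnc_pairs,
                      venn = venn, triads = triads, enrichment = enr,
                      enrichment_top = top, marker = marker_tab,
                      marker_test = marker_test, truth = truth),
       paths = paths)
}

#' Plain-text report of a pipeline run
#'
#' Renders a compact summary — per-class differential counts, the triad
#' network listing, top enriched terms and the marker-normalization test —
#' from the in-memory result of [run_pipeline()].
#'
#' @param run Result of [run_pipeline()].
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly if `path` is given.
#' @export
pipeline_report <- function(run, path = NULL) {
  r <- run$results
  lines <- c("ceRNA screen report", "===================", "", run$log, "",
             "Triads:",
             if (nrow(r$triads)) {
               sprintf("  %s(%s) -| %s(%s) -| %s(%s) [%s]",
                       r$triads$mirna_id, r$triads$mirna_status,
                       r$triads$mrna_id, r$triads$mrna_status,
                       r$triads$sponge_id, r$triads$sponge_status,
                       r$triads$sponge_class)
             } else "  (none)",
             "", "Top enriched terms (by gene ratio):",
             if (nrow(r$enrichment_top)) {
               with(head(r$enrichment_top, 10),
                    sprintf("  [%s/%s] %s: gene_ratio=%.3f p=%.3g",
                            namespace, direction, term_name, gene_ratio, p))
             } else "  (none)")
  if (!is.null(path)) {
    readr::write_lines(lines, path)
    return(invisible(lines))
  }
  lines
}
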