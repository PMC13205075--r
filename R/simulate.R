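BASES <- c("A", "C", "G", "U")

#' Configure a synthetic ceRNA experiment
#'
#' Defines the study conditions the generator emulates: a two-group design
#' (cold exposure vs control, `n_per_group` biological replicates each) over
#' four RNA classes, negative-binomial counts with a single global
#' dispersion (variance = mu + dispersion * mu^2), a set of planted
#' differential features per class at `+-planted_log10fc` (base-10 log of
#' the cold/control mean ratio), and `n_triads` planted direction-consistent
#' ceRNA triads whose miRNA seed sites are written into the target
#' sequences.
#'
#' Planted effects are split symmetrically about the baseline mean (control
#' = baseline * 10^(-fc/2), cold = baseline * 10^(+fc/2)), so the
#' between-group ratio is exactly `10^(+-fc)` while both groups of a
#' differential feature stay inside the expressed range. Baseline means are
#' log-uniform on `baseline_mean_log10_range`, spanning low to high
#' expressors of a filtered bulk RNA-seq experiment.
#'
#' @param n_mrna,n_lncrna,n_mirna,n_circrna Features per RNA class.
#' @param n_per_group Biological replicates per group (default 3).
#' @param baseline_mean_log10_range Range (log10) for baseline means.
#' @param dispersion Global NB dispersion alpha (default 0.1).
#' @param n_de_per_class Named integer vector (`mRNA`, `lncRNA`, `miRNA`,
#'   `circRNA`): how many features per class carry a planted effect. Must
#'   cover the features consumed by triads, markers and the normalization
#'   target.
#' @param planted_log10fc Magnitude of the planted log10 fold change.
#' @param n_triads Number of planted ceRNA triads; odd-indexed triads are
#'   mRNA-up / miRNA-down / circRNA-up, even-indexed ones are mRNA-down /
#'   miRNA-up / lncRNA-down.
#' @param target_length Sequence length (nt) for mRNA/lncRNA/circRNA.
#' @param mirna_length miRNA sequence length (nt, default 22).
#' @param seed Master integer seed; mandatory. Component streams (counts,
#'   sequences, terms, annotation) are derived via [derive_seed()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mrna = 2000, n_lncrna = 300, n_mirna = 150,
                       n_circrna = 500, n_per_group = 3,
                       baseline_mean_log10_range = c(1.0, 3.5),
                       dispersion = 0.1,
                       n_de_per_class = c(mRNA = 60, lncRNA = 15,
                                          miRNA = 25, circRNA = 20),
                       planted_log10fc = 1.0, n_triads = 20,
                       target_length = 500, mirna_length = 22,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop_input("`seed` is mandatory: the generator has no hidden entropy")
  }
  cfg <- list(n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_circrna = n_circrna, n_per_group = n_per_group,
              baseline_mean_log10_range = unlist(baseline_mean_log10_range),
              dispersion = dispersion,
              n_de_per_class = unlist(n_de_per_class),
              planted_log10fc = planted_log10fc, n_triads = n_triads,
              target_length = target_length, mirna_length = mirna_length,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  sizes <- c(mRNA = cfg$n_mrna, lncRNA = cfg$n_lncrna, miRNA = cfg$n_mirna,
             circRNA = cfg$n_circrna)
  if (any(sizes < 1)) stop_input("class sizes must be positive")
  if (cfg$n_per_group < 1) stop_input("n_per_group must be positive")
  if (cfg$dispersion <= 0) stop_input("dispersion must be positive")
  if (cfg$planted_log10fc < 0) stop_input("planted_log10fc must be >= 0")
  nde <- cfg$n_de_per_class
  if (!all(RNA_CLASSES %in% names(nde))) {
    stop_input("n_de_per_class must name all four RNA classes")
  }
  if (any(nde[RNA_CLASSES] > sizes[RNA_CLASSES])) {
    stop_input("n_de_per_class cannot exceed the class sizes")
  }
  n_a <- ceiling(cfg$n_triads / 2)  # circRNA-sponge pattern
  n_b <- floor(cfg$n_triads / 2)    # lncRNA-sponge pattern
  need <- c(mRNA = cfg$n_triads + 3, lncRNA = n_b, miRNA = cfg$n_triads,
            circRNA = n_a)
  if (cfg$n_triads > 0 && any(nde[names(need)] < need)) {
    stop_input(paste0(
      "n_de_per_class too small for the planted network; need at least ",
      paste(sprintf("%s=%d", names(need), need), collapse = ", "),
      " (triads + two markers + one normalization target)"))
  }
  if (cfg$mirna_length < 8) stop_input("mirna_length must be >= 8")
  if (cfg$target_length < 30) stop_input("target_length must be >= 30")
  invisible(cfg)
}

feature_ids <- function(cfg) {
  list(mRNA = sprintf("mRNA_%04d", seq_len(cfg$n_mrna)),
       lncRNA = sprintf("lnc_%04d", seq_len(cfg$n_lncrna)),
       miRNA = sprintf("mir_%04d", seq_len(cfg$n_mirna)),
       circRNA = sprintf("circ_%04d", seq_len(cfg$n_circrna)))
}

# Deterministic allocation of planted roles to feature ids. The first
# features of each class are planted (features are exchangeable in the
# generative model, so this loses no generality and keeps truth auditable).
plan_truth <- function(cfg) {
  ids <- feature_ids(cfg)
  nde <- cfg$n_de_per_class
  status <- purrr::map(RNA_CLASSES, function(cl) {
    rep("ns", length(ids[[cl]]))
  })
  names(status) <- RNA_CLASSES
  role <- purrr::map(status, function(s) rep("none", length(s)))
  triad_of <- purrr::map(status, function(s) rep(NA_integer_, length(s)))

  n_t <- cfg$n_triads
  pattern_a <- which(seq_len(n_t) %% 2 == 1)  # circRNA sponge, mRNA up
  pattern_b <- which(seq_len(n_t) %% 2 == 0)  # lncRNA sponge, mRNA down

  triads <- NULL
  if (n_t > 0) {
    mrna_idx <- seq_len(n_t)
    mirna_idx <- seq_len(n_t)
    circ_idx <- seq_along(pattern_a)
    lnc_idx <- seq_along(pattern_b)
    sponge_id <- character(n_t)
    sponge_class <- character(n_t)
    sponge_id[pattern_a] <- ids$circRNA[circ_idx]
    sponge_class[pattern_a] <- "circRNA"
    sponge_id[pattern_b] <- ids$lncRNA[lnc_idx]
    sponge_class[pattern_b] <- "lncRNA"
    up_a <- seq_len(n_t) %in% pattern_a
    triads <- tibble(
      triad = seq_len(n_t),
      mrna_id = ids$mRNA[mrna_idx],
      mirna_id = ids$miRNA[mirna_idx],
      sponge_id = sponge_id,
      sponge_class = sponge_class,
      mrna_status = if_else(up_a, "up", "down"),
      mirna_status = if_else(up_a, "down", "up"),
      sponge_status = if_else(up_a, "up", "down"))
    status$mRNA[mrna_idx] <- triads$mrna_status
    role$mRNA[mrna_idx] <- "triad_mrna"
    triad_of$mRNA[mrna_idx] <- triads$triad
    status$miRNA[mirna_idx] <- triads$mirna_status
    role$miRNA[mirna_idx] <- "triad_mirna"
    triad_of$miRNA[mirna_idx] <- triads$triad
    status$circRNA[circ_idx] <- "up"
    role$circRNA[circ_idx] <- "triad_sponge"
    triad_of$circRNA[circ_idx] <- pattern_a
    status$lncRNA[lnc_idx] <- "down"
    role$lncRNA[lnc_idx] <- "triad_sponge"
    triad_of$lncRNA[lnc_idx] <- pattern_b
  }

  # Two adipocyte-marker genes (planted up: markers track the fat gain in
  # the cold group) and one normalization target (planted down). Only
  # planted when the mRNA quota leaves room, so an all-null configuration
  # stays truly null.
  marker_ids <- character(0)
  norm_target_id <- NA_character_
  if (nde[["mRNA"]] >= n_t + 3) {
    marker_pos <- n_t + 1:2
    norm_pos <- n_t + 3
    status$mRNA[marker_pos] <- "up"
    role$mRNA[marker_pos] <- "marker"
    status$mRNA[norm_pos] <- "down"
    role$mRNA[norm_pos] <- "norm_target"
    marker_ids <- ids$mRNA[marker_pos]
    norm_target_id <- ids$mRNA[norm_pos]
  }

  # Fill the remaining planted quota per class, alternating up/down.
  for (cl in RNA_CLASSES) {
    used <- sum(status[[cl]] != "ns")
    extra <- nde[[cl]] - used
    if (extra < 0) stop_input("internal: planted roles exceed n_de_per_class")
    if (extra > 0) {
      pos <- which(status[[cl]] == "ns")[seq_len(extra)]
      status[[cl]][pos] <- rep(c("up", "down"), length.out = extra)
      role[[cl]][pos] <- "extra"
    }
  }

  de_status <- bind_rows(purrr::map(RNA_CLASSES, function(cl) {
    tibble(feature_id = ids[[cl]], rna_class = cl, status = status[[cl]],
           role = role[[cl]], triad = triad_of[[cl]])
  })) |>
    mutate(log10_fc = dplyr::case_when(
      .data$status == "up" ~ cfg$planted_log10fc,
      .data$status == "down" ~ -cfg$planted_log10fc,
      TRUE ~ 0))

  list(de_status = de_status, triads = triads,
       marker_ids = marker_ids, norm_target_id = norm_target_id)
}

random_seq_matrix <- function(n, len) {
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

reverse_complement_rna <- function(x) {
  chartr("ACGU", "UGCA",
         vapply(strsplit(x, "", fixed = TRUE),
                function(s) paste0(rev(s), collapse = ""), character(1)))
}

# The 8mer site string for a miRNA: reverse complement of positions 2-8
# written 5'->3' on the target, followed by an A opposite position 1.
site_string_8mer <- function(mirna_seq) {
  paste0(reverse_complement_rna(substr(mirna_seq, 2, 8)), "A")
}

seed_core <- function(mirna_seq) {
  reverse_complement_rna(substr(mirna_seq, 2, 7))
}

# Generate sequences with planted 8mer sites and no accidental seed cores of
# any planted-differential miRNA anywhere else (rejection sampling).
simulate_sequences <- function(cfg, truth) {
  ids <- feature_ids(cfg)
  de <- truth$de_status
  de_mirnas <- de$feature_id[de$rna_class == "miRNA" & de$status != "ns"]

  # miRNA sequences: resample until all planted-DE miRNAs have distinct seed
  # cores and no miRNA's 8mer site string contains another's core (so that
  # replanting one site can never recreate a scrubbed match).
  mirna_seqs <- setNames(random_seq_matrix(length(ids$miRNA),
                                           cfg$mirna_length), ids$miRNA)
  for (attempt in seq_len(200)) {
    cores <- vapply(mirna_seqs[de_mirnas], seed_core, character(1))
    sites <- vapply(mirna_seqs[de_mirnas], site_string_8mer, character(1))
    bad <- anyDuplicated(cores) > 0
    if (!bad) {
      for (i in seq_along(sites)) {
        if (any(vapply(cores[-i], function(co) grepl(co, sites[i], fixed = TRUE),
                       logical(1)))) {
          bad <- TRUE
          break
        }
      }
    }
    if (!bad) break
    resample <- sample(seq_along(de_mirnas), 1)
    mirna_seqs[de_mirnas[resample]] <- random_seq_matrix(1, cfg$mirna_length)
    if (attempt == 200) stop_input("could not draw miRNAs with compatible seed cores")
  }

  target_ids <- c(ids$mRNA, ids$lncRNA, ids$circRNA)
  targets <- setNames(random_seq_matrix(length(target_ids),
                                        cfg$target_length), target_ids)

  # Plant one 8mer site per (triad miRNA, mRNA) and (triad miRNA, sponge).
  planted <- NULL
  if (!is.null(truth$triads) && nrow(truth$triads)) {
    planted <- truth$triads |>
      tidyr::pivot_longer(cols = c("mrna_id", "sponge_id"),
                          values_to = "target_id") |>
      select("mirna_id", "target_id") |>
      mutate(position = sample.int(cfg$target_length - 8L, n(),
                                   replace = TRUE) - 1L,
             site_type = "8mer")
  }
  plant_sites <- function(seqs) {
    if (is.null(planted)) return(seqs)
    for (i in seq_len(nrow(planted))) {
      s <- seqs[[planted$target_id[i]]]
      p <- planted$position[i]
      substr(s, p + 1, p + 8) <- site_string_8mer(
        mirna_seqs[[planted$mirna_id[i]]])
      seqs[[planted$target_id[i]]] <- s
    }
    seqs
  }
  targets <- plant_sites(targets)

  # Scrub accidental cores: any occurrence of a planted-DE miRNA's seed core
  # outside that miRNA's own planted sites is rewritten with random bases,
  # then planted sites are re-stamped; iterate to convergence.
  allowed <- if (is.null(planted)) {
    tibble(mirna_id = character(), target_id = character(),
           core_start = integer())
  } else {
    # core occupies 1-based positions p+2 .. p+7 of the site
    planted |> mutate(core_start = .data$position + 2L) |>
      select("mirna_id", "target_id", "core_start")
  }
  for (iter in seq_len(60)) {
    dirty <- FALSE
    for (mi in de_mirnas) {
      core <- seed_core(mirna_seqs[[mi]])
      hits <- stringr::str_locate_all(targets, stringr::fixed(core))
      ok <- allowed |> filter(.data$mirna_id == mi)
      for (t in which(vapply(hits, nrow, 0L) > 0)) {
        starts <- hits[[t]][, 1]
        ok_starts <- ok$core_start[ok$target_id == target_ids[t]]
        for (s0 in setdiff(starts, ok_starts)) {
          dirty <- TRUE
          substr(targets[t], s0, s0 + 5) <- paste0(
            sample(BASES, 6, replace = TRUE), collapse = "")
        }
      }
    }
    if (!dirty) break
    targets <- plant_sites(targets)
    if (iter == 60) {
      stop_input("site scrubbing did not converge; use longer target sequences")
    }
  }

  list(sequences = c(mirna_seqs, targets), planted_sites = planted)
}

simulate_annotation <- function(cfg, truth) {
  de <- truth$de_status
  n <- nrow(de)
  chrom <- paste0("chr", sample.int(18, n, replace = TRUE))
  start <- sample.int(1e8, n, replace = TRUE)
  len <- ifelse(de$rna_class == "miRNA", cfg$mirna_length, cfg$target_length)
  ann <- tibble(feature_id = de$feature_id, rna_class = de$rna_class,
                chrom = chrom, start = start, end = start + len,
                strand = sample(c("+", "-"), n, replace = TRUE))
  # lncRNA sponges of planted triads sit in cis of their mRNA (10 kb gap).
  if (!is.null(truth$triads)) {
    lnc_triads <- truth$triads |> filter(.data$sponge_class == "lncRNA")
    for (i in seq_len(nrow(lnc_triads))) {
      m <- match(lnc_triads$mrna_id[i], ann$feature_id)
      l <- match(lnc_triads$sponge_id[i], ann$feature_id)
      ann$chrom[l] <- ann$chrom[m]
      ann$start[l] <- ann$end[m] + 10000L
      ann$end[l] <- ann$start[l] + cfg$target_length
    }
  }
  ann
}

simulate_terms <- function(cfg, truth) {
  ids <- feature_ids(cfg)
  de <- truth$de_status
  up_mrna <- de$feature_id[de$rna_class == "mRNA" & de$status == "up"]
  random_term <- function(term_id, nm, ns) {
    size <- sample(20:50, 1)
    tibble(term_id = term_id, term_name = nm, namespace = ns,
           members = list(sample(ids$mRNA, size)))
  }
  planted <- tibble(
    term_id = "BP:0001", term_name = "lipid storage", namespace = "BP",
    members = list(unique(c(up_mrna, sample(ids$mRNA, 10)))))
  rest <- bind_rows(
    purrr::map(2:10, function(i) random_term(sprintf("BP:%04d", i),
                                             sprintf("process %d", i), "BP")),
    purrr::map(1:5, function(i) random_term(sprintf("MF:%04d", i),
                                            sprintf("function %d", i), "MF")),
    purrr::map(1:5, function(i) random_term(sprintf("CC:%04d", i),
                                            sprintf("component %d", i), "CC")),
    purrr::map(1:10, function(i) random_term(sprintf("path:%04d", i),
                                             sprintf("pathway %d", i),
                                             "pathway")))
  bind_rows(planted, rest)
}

#' Simulate counts only
#'
#' The counts component of [simulate_experiment()]: negative-binomial counts
#' with the planted group effects, without sequences, annotation or term
#' sets. Useful for large null simulations and power studies where only the
#' testing stages are exercised.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expr` (an [expr_set()]) and `truth` (the
#'   planted differential-status tibble plus triad table, marker ids and
#'   normalization-target id).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  truth <- plan_truth(config)
  de <- truth$de_status
  n <- nrow(de)
  npg <- config$n_per_group
  set.seed(derive_seed(config$seed, "counts"))
  rng <- config$baseline_mean_log10_range
  base <- 10^runif(n, rng[1], rng[2])
  # symmetric split keeps cold/control = 10^(signed fc)
  mu_cold <- base * 10^(de$log10_fc / 2)
  mu_ctrl <- base * 10^(-de$log10_fc / 2)
  size <- 1 / config$dispersion
  draw <- function(mu) {
    matrix(rnbinom(n * npg, mu = rep(mu, npg), size = size), nrow = n)
  }
  counts <- cbind(draw(mu_cold), draw(mu_ctrl))
  storage.mode(counts) <- "integer"
  sample_ids <- c(sprintf("cold_%d", seq_len(npg)),
                  sprintf("control_%d", seq_len(npg)))
  dimnames(counts) <- list(de$feature_id, sample_ids)
  es <- expr_set(counts,
                 features = de |> select("feature_id", "rna_class"),
                 samples = tibble(sample_id = sample_ids,
                                  group = rep(GROUPS, each = npg)))
  list(expr = es, truth = truth)
}

#' Simulate a complete synthetic ceRNA experiment
#'
#' Generates counts, genomic annotation, sequences and a synthetic term
#' collection with a fully known planted truth: differential features in
#' all four RNA classes, 8mer seed sites supporting each planted triad,
#' cis-located lncRNA sponges, one term enriched for planted-up mRNAs
#' (emulating a lipid-storage annotation), and two adipocyte-marker genes
#' plus a normalization target exercising marker normalization. Fully
#' reproducible from `config$seed`; each component draws from its own
#' derived stream (see [derive_seed()]).
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#' \describe{
#'   \item{expr}{[expr_set()] of counts.}
#'   \item{annotation}{Feature annotation tibble (`feature_id`, `rna_class`,
#'     `chrom`, `start`, `end`, `strand`; 0-based half-open).}
#'   \item{sequences}{Named character vector of RNA sequences.}
#'   \item{terms}{Term annotation tibble as from [read_gmt()].}
#'   \item{truth}{`synthetic_truth` list: `de_status`, `planted_sites`,
#'     `planted_triads`, `marker_ids`, `norm_target_id`.}
#' }
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  cnt <- simulate_counts(config)
  truth <- cnt$truth

  set.seed(derive_seed(config$seed, "sequences"))
  seqs <- simulate_sequences(config, truth)

  set.seed(derive_seed(config$seed, "annotation"))
  annotation <- simulate_annotation(config, truth)

  set.seed(derive_seed(config$seed, "terms"))
  terms <- simulate_terms(config, truth)

  planted_triads <- if (is.null(truth$triads)) {
    tibble()
  } else {
    truth$triads |>
      mutate(mirna_targets_mrna = TRUE, sponge_binds_mirna = TRUE,
             lnc_mode = if_else(.data$sponge_class == "lncRNA", "cis", "n/a")) |>
      select(-"triad")
  }
  truth_obj <- structure(
    list(de_status = truth$de_status,
         planted_sites = seqs$planted_sites %||%
           tibble(mirna_id = character(), target_id = character(),
                  position = integer(), site_type = character()),
         planted_triads = planted_triads,
         marker_ids = truth$marker_ids,
         norm_target_id = truth$norm_target_id),
    class = "synthetic_truth")

  list(expr = cnt$expr, annotation = annotation, sequences = seqs$sequences,
       terms = terms, truth = truth_obj)
}

#' Simulation-based power of the differential-expression screen
#'
#' For each effect size in `effect_grid`, simulates `reps` experiments
#' (counts only), runs the differential-expression stage with its default
#' class-specific thresholds, and records the fraction of planted features
#' called with their true direction.
#'
#' @param config A [sim_config()]; its `planted_log10fc` is overridden by
#'   the grid values.
#' @param effect_grid Numeric vector of log10 fold-change magnitudes.
#' @param reps Replicates per effect size (>= 1).
#' @return A tibble with columns `effect` and `detection_fraction`,
#'   monotone non-decreasing in `effect` up to Monte-Carlo error.
#' @export
power_simulation <- function(config, effect_grid, reps = 10) {
  if (!length(effect_grid)) stop_input("effect_grid must be non-empty")
  if (reps < 1) stop_input("reps must be >= 1")
  k <- 0
  res <- purrr::map_dfr(effect_grid, function(eff) {
    hits <- vapply(seq_len(reps), function(r) {
      k <<- k + 1
      cfg <- config
      cfg$planted_log10fc <- eff
      cfg$seed <- as.integer((as.numeric(config$seed) + 7919 * k) %% (2^31 - 1))
      sim <- simulate_counts(cfg)
      de <- de_test(sim$expr)
      truth <- sim$truth$de_status |> filter(.data$status != "ns")
      called <- de |> select("feature_id", called = "status")
      joined <- truth |> left_join(called, by = "feature_id")
      mean(joined$called == joined$status)
    }, numeric(1))
    tibble(effect = eff, detection_fraction = mean(hits))
  })
  res
}
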