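# Independent oracles and tiny fixture builders. These deliberately avoid
# the package's own code paths (naive loops, literal definitions) so the
# implementation and its check never share logic.

rand_rna <- function(len) {
  paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

naive_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Literal sliding-window seed-site scanner applying the four canonical
# definitions position by position.
naive_seed_scan <- function(mirna, target) {
  core <- naive_revcomp(substr(mirna, 2, 7))
  m8 <- c(A = "U", C = "G", G = "C", U = "A")[substr(mirna, 8, 8)]
  L <- nchar(target)
  out <- NULL
  for (i in seq_len(L - 5)) {
    if (substr(target, i, i + 5) != core) next
    has_m8 <- i > 1 && substr(target, i - 1, i - 1) == m8
    has_a1 <- i + 6 <= L && substr(target, i + 6, i + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    pos <- if (has_m8) i - 2L else i - 1L
    out <- rbind(out, data.frame(position = pos, site_type = type))
  }
  if (is.null(out)) {
    data.frame(position = integer(), site_type = character())
  } else {
    out
  }
}

# Exhaustive (m, mu, s) triple enumeration applying the direction and
# evidence rules literally.
brute_force_triads <- function(de_records, interactions, lnc_pairs) {
  de <- de_records[de_records$status != "ns", ]
  st <- setNames(de$status, de$feature_id)
  mrnas <- de$feature_id[de$rna_class == "mRNA"]
  mirnas <- de$feature_id[de$rna_class == "miRNA"]
  sponges <- de[de$rna_class %in% c("lncRNA", "circRNA"), ]
  ia_key <- paste(interactions$mirna_id, interactions$target_id)
  lnc_key <- paste(lnc_pairs$lnc_id, lnc_pairs$mrna_id)
  rows <- NULL
  for (m in mrnas) for (mu in mirnas) for (si in seq_len(nrow(sponges))) {
    s <- sponges$feature_id[si]
    s_cl <- sponges$rna_class[si]
    if (s == m) next
    if (st[mu] == st[m]) next
    if (st[s] != st[m]) next
    if (!(paste(mu, m) %in% ia_key)) next
    if (!(paste(mu, s) %in% ia_key)) next
    if (s_cl == "lncRNA" && !(paste(s, m) %in% lnc_key)) next
    rows <- rbind(rows, data.frame(mrna_id = m, mirna_id = mu,
                                   sponge_id = s))
  }
  if (is.null(rows)) data.frame(mrna_id = character(), mirna_id = character(),
                                sponge_id = character())
  else unique(rows[order(rows$mrna_id, rows$mirna_id, rows$sponge_id), ])
}

triad_key <- function(x) paste(x$mrna_id, x$mirna_id, x$sponge_id)

# Random small problem instance for triad brute-forcing.
random_triad_instance <- function(n_per_class = 8) {
  classes <- c("mRNA", "lncRNA", "miRNA", "circRNA")
  de <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(feature_id = paste0(cl, "_", seq_len(n_per_class)),
               rna_class = cl,
               status = sample(c("up", "down", "ns"), n_per_class,
                               replace = TRUE))
  }))
  mirnas <- de$feature_id[de$rna_class == "miRNA"]
  targets <- de$feature_id[de$rna_class != "miRNA"]
  cls <- setNames(de$rna_class, de$feature_id)
  all_pairs <- expand.grid(mirna_id = mirnas, target_id = targets,
                           stringsAsFactors = FALSE)
  keep <- runif(nrow(all_pairs)) < 0.25
  interactions <- all_pairs[keep, ]
  interactions$target_class <- unname(cls[interactions$target_id])
  interactions$n_sites <- 1L
  interactions$best_site_type <- "6mer"
  lnc <- de$feature_id[de$rna_class == "lncRNA"]
  mr <- de$feature_id[de$rna_class == "mRNA"]
  lp <- expand.grid(lnc_id = lnc, mrna_id = mr, stringsAsFactors = FALSE)
  lp <- lp[runif(nrow(lp)) < 0.3, ]
  lp$mode <- sample(c("cis", "trans"), nrow(lp), replace = TRUE)
  lp$evidence <- 1
  list(de = tibble::as_tibble(de),
       interactions = tibble::as_tibble(interactions),
       lnc_pairs = tibble::as_tibble(lp))
}

# Hypergeometric upper tail by exhaustive subset enumeration.
enum_hypergeom_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  in_term <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% in_term))
  mean(hits >= k)
}

# Small deterministic expression set.
tiny_es <- function(counts, classes = NULL, groups = NULL) {
  nf <- nrow(counts)
  ns <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("f", seq_len(nf))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ns))
  classes <- classes %||% rep("mRNA", nf)
  groups <- groups %||% c(rep("cold", ceiling(ns / 2)),
                          rep("control", floor(ns / 2)))
  expr_set(counts,
           features = data.frame(feature_id = rownames(counts),
                                 rna_class = classes),
           samples = data.frame(sample_id = colnames(counts),
                                group = groups))
}

small_sim_config <- function(seed, ...) {
  args <- list(n_mrna = 200, n_lncrna = 40, n_mirna = 30, n_circrna = 60,
               n_de_per_class = c(mRNA = 20, lncRNA = 6, miRNA = 12,
                                  circRNA = 8),
               n_triads = 10, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
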