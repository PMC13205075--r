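#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, `term_id TAB description TAB member...`.
#' The description field carries the namespace as `"namespace|term name"`
#' with namespace one of `BP`, `MF`, `CC`, `pathway`; a description without
#' `|` is taken as a pathway name. Duplicate members within a line are
#' collapsed (set semantics).
#'
#' @param path Path to a GMT file.
#' @return A tibble of term annotations with columns `term_id`, `term_name`,
#'   `namespace` and a list-column `members` of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_input(sprintf("GMT line %d has %d field(s); need term, description and >=1 member",
                         i, length(parts)),
                 class = "cernascreen_format_error")
    }
    desc <- parts[2]
    if (grepl("|", desc, fixed = TRUE)) {
      ns <- sub("\\|.*$", "", desc)
      nm <- sub("^[^|]*\\|", "", desc)
    } else {
      ns <- "pathway"
      nm <- desc
    }
    if (!ns %in% c("BP", "MF", "CC", "pathway")) {
      stop_input(sprintf("GMT line %d: unknown namespace '%s'", i, ns),
                 class = "cernascreen_format_error")
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop_input(sprintf("GMT line %d: term '%s' has no members", i, parts[1]),
                 class = "cernascreen_format_error")
    }
    tibble(term_id = parts[1], term_name = nm, namespace = ns,
           members = list(members))
  })
  terms <- bind_rows(rows)
  dup <- terms |>
    dplyr::count(.data$namespace, .data$term_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    stop_input(paste0("duplicate term id(s) within a namespace: ",
                      paste(dup$term_id, collapse = ", ")),
               class = "cernascreen_format_error")
  }
  terms
}

#' Write a GMT gene-set file
#'
#' Inverse of [read_gmt()]: the namespace is encoded into the description
#' field as `"namespace|term name"`.
#'
#' @param terms Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `terms`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- purrr::pmap_chr(
    list(terms$term_id, terms$term_name, terms$namespace, terms$members),
    function(id, nm, ns, members) {
      paste(c(id, paste0(ns, "|", nm), members), collapse = "\t")
    })
  readr::write_lines(lines, path)
  invisible(terms)
}
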