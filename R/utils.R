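#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join semi_join anti_join distinct bind_rows bind_cols
#'   across n pull rename relocate slice_head if_else
#' @importFrom stats median rnbinom rpois runif setNames prcomp pnorm phyper
#'   p.adjust cor sd t.test pt var
#' @importFrom utils head
NULL

# RNA classes recognised throughout the package, in display order.
RNA_CLASSES <- c("mRNA", "lncRNA", "miRNA", "circRNA")

# Sample groups: treatment first so fold changes read cold over control.
GROUPS <- c("cold", "control")

stop_input <- function(msg, class = "cernascreen_error") {
  abort(msg, class = c(class, "cernascreen_error"))
}

#' Derive a component seed from a master seed
#'
#' Each stochastic component of the simulator (counts, sequences, terms,
#' annotation) consumes its own RNG stream, seeded deterministically from the
#' master seed by `seed + 10007 * index` modulo `2^31 - 1`. Adding a new
#' component therefore never perturbs the draws of an existing one.
#'
#' @param seed Master integer seed.
#' @param component One of `"counts"`, `"sequences"`, `"terms"`,
#'   `"annotation"`.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, component = c("counts", "sequences", "terms",
                                            "annotation")) {
  component <- match.arg(component)
  idx <- match(component, c("counts", "sequences", "terms", "annotation"))
  as.integer((as.numeric(seed) + 10007 * idx) %% (2^31 - 1))
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- rlang::`%||%`
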