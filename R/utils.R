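## Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats median rnorm rlnorm rnbinom rbinom runif sd var quantile
#'   pnorm t.test wilcox.test p.adjust cmdscale dist cor setNames
#' @importFrom utils read.delim write.table head
NULL

## identifier must carry a lowercase namespace prefix, e.g. "ko:K24443"
.is_namespaced <- function(x) {
  grepl("^[a-z][a-z0-9]*:.+", x)
}

.check_namespaced <- function(x, what = "identifier") {
  bad <- which(!.is_namespaced(x))
  if (length(bad)) {
    stop(sprintf("malformed %s (missing namespace prefix): '%s' (record %d)",
                 what, x[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(x)
}

.namespace_of <- function(x) sub(":.*$", "", x)

#' Deterministic per-stage child seeds
#'
#' Fans a single global seed out to per-stage child seeds keyed by stage
#' name, so adding a stage to a workflow never perturbs the randomness of
#' earlier stages. Values stay below 2^31.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return An integer child seed.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 97561) %% 2147483629)
}

#' Empirical p-value with the add-one convention
#'
#' `(1 + #replicates at least as extreme) / (n + 1)`: with 99 replicates p
#' lies on the grid 1/100 ... 100/100 and is never 0.
#'
#' @param null_values numeric vector of null replicate values.
#' @param observed the observed value.
#' @param larger_is_extreme direction of extremeness.
#' @return The empirical p-value.
#' @export
empiricalP <- function(null_values, observed, larger_is_extreme = TRUE) {
  stopifnot(is.numeric(null_values), length(observed) == 1L)
  if (larger_is_extreme) {
    (1 + sum(null_values >= observed)) / (length(null_values) + 1)
  } else {
    (1 + sum(null_values <= observed)) / (length(null_values) + 1)
  }
}

.dedup_union <- function(lst) {
  out <- unlist(lst, use.names = FALSE)
  sort(unique(out))
}
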