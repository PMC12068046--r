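#' @keywords internal
"_PACKAGE"

#' @import EBImage
#' @importFrom stats coef lm median prcomp predict pnorm qnorm quantile rnorm
#'   rpois runif sd setNames var wilcox.test rmultinom rlnorm p.adjust
#'   runmed
#' @importFrom utils combn head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-component seed from a global seed
#'
#' All stochastic components take an explicit integer seed. When a single
#' run-level seed must be fanned out to several independent components, the
#' per-component seed is derived deterministically from the run seed and a
#' short text tag, keeping streams distinct and reproducible.
#'
#' @param seed integer run-level seed.
#' @param tag character tag naming the component.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 69069 + h * 9973) %% (2^31 - 2)) + 1L
}

# Evaluate expr with a local RNG state under the given seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

relu <- function(x) pmax(x, 0)

# Per-label sums over a label matrix; returns vector indexed 1..max label.
label_sums <- function(values, labels, nlab = max(labels)) {
  if (nlab < 1L) return(numeric(0))
  idx <- labels > 0L
  v <- rowsum(as.numeric(values[idx]), group = labels[idx])
  out <- numeric(nlab)
  out[as.integer(rownames(v))] <- v[, 1L]
  out
}

label_areas <- function(labels, nlab = max(labels)) {
  if (nlab < 1L) return(integer(0))
  tab <- tabulate(labels[labels > 0L], nbins = nlab)
  tab
}

# Full-precision CSV writers: numeric columns serialized with %.17g so that
# write -> read round-trips reproduce doubles exactly.
#' Write a table to CSV preserving full double precision
#' @param df data.frame to write.
#' @param path output file path.
#' @export
write_table_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a CSV written by \code{write_table_full}
#' @param path file path.
#' @export
read_table_full <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
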