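#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim rbinom rnorm runif setNames t.test pt sd var
#' @importFrom utils combn head read.table write.table
NULL

# Deterministic substream seeding: a single user-facing seed governs all
# randomness; each stage draws from seed + offset (kept below 2^31).
substream_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000007L + offset * 9973L) %% 2147483647L
}

with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, offset))
  expr
}

#' Normalize chromosome names to a single style
#'
#' @param x character vector of chromosome names.
#' @param style `"chr"` (default) prefixes bare names with `"chr"`;
#'   `"plain"` strips the prefix.
#' @return character vector in the requested style.
#' @export
normalize_chrom <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", as.character(x))
  if (style == "chr") paste0("chr", bare) else bare
}

ps_info <- function(...) {
  if (isTRUE(getOption("pedscreen.quiet", TRUE))) return(invisible(NULL))
  message("INFO [pedscreen] ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
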