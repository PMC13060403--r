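#' @keywords internal
"_PACKAGE"

## NULL-default operator, used throughout for optional config fields
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' One master seed drives every stochastic stage of the pipeline; per-stage
#' seeds are derived by fixed offsets so partial reruns of a stage reproduce
#' exactly without consuming the RNG stream of other stages. The result is
#' always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param offset non-negative integer stage offset.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  # splitmix-style scramble keeps derived seeds well separated even for
  # consecutive masters and offsets, while staying inside 32-bit range
  x <- (as.double(master) %% 2147483647) + 1
  y <- (x * 48271 + as.double(offset) * 9973 + 17) %% 2147483647
  as.integer((y * 16807 + 3) %% 2147483646)
}

## Run code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write a table as TSV
#'
#' Plain TSV with a header row, no quoting and no row names; missing values are
#' written as empty fields, matching the cohort-table interchange convention.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param comment optional character vector of `#`-prefixed header lines
#'   (provenance: config hash, seed) written before the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame; `#` comment lines are skipped, empty fields become `NA`.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    na.strings = c("", "NA"), stringsAsFactors = FALSE,
                    check.names = FALSE)
}

## stop() with the calling function's name stripped, for clean messages
fail <- function(...) stop(..., call. = FALSE)

## Check a proportion-valued scalar, naming the offending field.
check_prop <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    fail(sprintf("field '%s' must be a proportion in %s%g, %g%s (got %s)",
                 name, if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]", format(x)[1]))
  }
  invisible(x)
}
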