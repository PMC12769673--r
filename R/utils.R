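#' Derive a deterministic child seed from a master seed and a stage tag
#'
#' Pipeline stages (library construction, fitness assignment, passaging,
#' sequencing, FASTQ emission) each consume their own stream so that changing
#' one stage's sampling never perturbs another. The child seed is a
#' deterministic 31-bit hash of the master seed and the tag.
#'
#' @param master integer master seed.
#' @param tag character stage label.
#' @return integer in [1, 2^31 - 2].
#' @export
child_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- as.double(master) %% 2147483647
  for (v in utf8ToInt(tag)) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate expr with a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, expr) {
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_ <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
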