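#' Build a synthetic genome-wide knockout guide library
#'
#' Constructs a guide universe in the style of a genome-scale CRISPR knockout
#' library: \code{n_genes * guides_per_gene} gene-targeting guides plus
#' \code{n_controls} non-targeting control guides, each carrying a distinct
#' random 20-nt protospacer. The defaults of downstream helpers emulate a
#' Brunello-scale design (about 19,000 genes, 4 guides per gene, 1000
#' controls); small libraries are equally valid for testing.
#'
#' @param n_genes number of targeted genes (>= 1).
#' @param guides_per_gene guides designed per gene (>= 1).
#' @param n_controls number of non-targeting control guides (>= 0).
#' @param seed integer seed; the library is deterministic given the seed.
#' @return A data.frame of class \code{guide_library} with columns
#'   \code{guide_id}, \code{gene} (symbol or \code{"CONTROL"}),
#'   \code{protospacer} (20-mer over ACGT) and \code{is_control}.
#' @examples
#' lib <- build_library(10, 4, 2, seed = 1)
#' nrow(lib)  # 42
#' @export
build_library <- function(n_genes, guides_per_gene, n_controls = 0L, seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_controls >= 0)
  n_target <- n_genes * guides_per_gene
  n_total <- n_target + n_controls
  if (n_total > 4^18) {
    stop_("cannot draw %d distinct 20-mers: request exceeds feasible diversity",
          n_total)
  }
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  spacers <- with_seed(seed, random_kmers(n_total, k = 20L))
  guide_id <- c(
    sprintf("%s_g%d", rep(genes, each = guides_per_gene),
            rep(seq_len(guides_per_gene), times = n_genes)),
    if (n_controls > 0) sprintf("CTRL%05d_g1", seq_len(n_controls))
  )
  lib <- data.frame(
    guide_id = guide_id,
    gene = c(rep(genes, each = guides_per_gene), rep("CONTROL", n_controls)),
    protospacer = spacers,
    is_control = c(rep(FALSE, n_target), rep(TRUE, n_controls)),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("guide_library", "data.frame")
  validate_library(lib)
}

# Distinct random k-mers; re-draws collisions (vanishingly rare at 4^20).
random_kmers <- function(n, k = 20L, max_tries = 50L) {
  draw <- function(m) {
    apply(matrix(sample(c("A", "C", "G", "T"), m * k, replace = TRUE),
                 nrow = m), 1, paste, collapse = "")
  }
  out <- unique(draw(n))
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop_("failed to generate %d distinct %d-mers", n, k)
    out <- unique(c(out, draw(n - length(out))))
  }
  out[seq_len(n)]
}

#' Validate a guide library
#'
#' Checks the invariants every pipeline stage relies on: unique guide ids,
#' unique protospacers, 20-mers over ACGT, controls labelled
#' \code{gene == "CONTROL"}.
#'
#' @param lib a \code{guide_library} data.frame.
#' @return the library, invisibly classed, or an error.
#' @export
validate_library <- function(lib) {
  need <- c("guide_id", "gene", "protospacer", "is_control")
  if (!all(need %in% names(lib))) {
    stop_("guide library lacks columns: %s",
          paste(setdiff(need, names(lib)), collapse = ", "))
  }
  if (anyDuplicated(lib$guide_id)) stop_("duplicate guide_id in library")
  if (anyDuplicated(lib$protospacer)) stop_("duplicate protospacer in library")
  if (!all(grepl("^[ACGT]{20}$", lib$protospacer))) {
    stop_("protospacers must be 20-mers over {A,C,G,T}")
  }
  if (any(lib$is_control & lib$gene != "CONTROL")) {
    stop_("control guides must carry gene = \"CONTROL\"")
  }
  if (any(!lib$is_control & lib$gene == "CONTROL")) {
    stop_("gene \"CONTROL\" reserved for control guides")
  }
  if (!inherits(lib, "guide_library")) class(lib) <- c("guide_library", "data.frame")
  invisible(lib)
}

#' Read / write a guide library as TSV or FASTA
#'
#' The TSV carries the four library columns; the FASTA uses guide ids as
#' record names and protospacers as sequences.
#'
#' @param lib a \code{guide_library}.
#' @param path file path.
#' @rdname library_io
#' @export
write_library_tsv <- function(lib, path) {
  validate_library(lib)
  write_tsv_(as.data.frame(lib), path)
}

#' @rdname library_io
#' @export
read_library_tsv <- function(path) {
  lib <- read_tsv_(path, colClasses = c(
    guide_id = "character", gene = "character",
    protospacer = "character", is_control = "logical"))
  validate_library(lib)
  lib
}

#' @rdname library_io
#' @export
write_library_fasta <- function(lib, path) {
  validate_library(lib)
  writeLines(paste0(">", lib$guide_id, "\n", lib$protospacer), path)
  invisible(path)
}
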