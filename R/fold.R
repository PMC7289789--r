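#' Fold sequences into dot-bracket strings
#'
#' Production pipelines typically supply structures computed externally
#' (thermodynamic folding) as a structure file; the internal backend is a
#' deterministic base-pair-maximizing dynamic program (Nussinov-style) kept so
#' the package has no external executable dependency. Internal backend
#' constraints: minimum hairpin loop of 3 unpaired bases, allowed pairs
#' AU/UA, GC/CG, GU/UG (T is treated as U), N pairs with nothing. Ties during
#' traceback are broken deterministically: prefer pairing the smallest i, then
#' its largest admissible partner.
#'
#' @param seqs character vector of nucleotide sequences over
#'   \code{A,C,G,T,U,N} (case-insensitive).
#' @param backend \code{"nussinov"} (internal) or \code{"file"} (precomputed
#'   dot-bracket strings supplied via \code{structures}).
#' @param structures for \code{backend = "file"}: either a named character
#'   vector of dot-bracket strings (names = window ids) or a path to a
#'   two-column tab-separated file \code{<window_id>\\t<dotbracket>}.
#' @param ids window ids used to look structures up when
#'   \code{backend = "file"}.
#' @param min_loop minimum hairpin loop length (internal backend).
#' @return Character vector of dot-bracket strings, same lengths as
#'   \code{seqs}.
#' @examples
#' fold_sequence("GGGAAACCC")  # "(((...)))"
#' @export
fold_sequence <- function(seqs, backend = c("nussinov", "file"),
                          structures = NULL, ids = NULL, min_loop = 3L) {
  backend <- match.arg(backend)
  if (backend == "nussinov") {
    if (any(!nzchar(seqs))) stop("fold_sequence: empty sequence", call. = FALSE)
    return(.nussinov_fold(as.character(seqs), as.integer(min_loop)))
  }
  if (is.null(structures)) {
    stop("fold_sequence: backend 'file' requires `structures`", call. = FALSE)
  }
  if (length(structures) == 1L && is.character(structures) &&
      is.null(names(structures)) && file.exists(structures)) {
    structures <- read_structure_file(structures)
  }
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) {
    stop("fold_sequence: backend 'file' requires window `ids`", call. = FALSE)
  }
  out <- unname(structures[ids])
  missing <- is.na(out)
  if (any(missing)) {
    stop("fold_sequence: no structure for window id ", ids[which(missing)[1]],
         call. = FALSE)
  }
  bad <- which(nchar(out) != nchar(seqs))
  if (length(bad)) {
    stop(sprintf("fold_sequence: structure length %d != sequence length %d for id %s",
                 nchar(out[bad[1]]), nchar(seqs[bad[1]]), ids[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Read a dot-bracket structure file
#'
#' One \code{<window_id>\\t<dotbracket>} line per window.
#' @param path file path.
#' @return named character vector of dot-bracket strings.
#' @export
read_structure_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("id", "structure"))
  stats::setNames(df$structure, df$id)
}

#' Count paired bases in dot-bracket strings
#' @param db character vector of dot-bracket strings.
#' @return integer vector: number of \code{"("} per string.
#' @export
pair_count <- function(db) {
  vapply(strsplit(db, ""), function(ch) sum(ch == "("), integer(1))
}
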