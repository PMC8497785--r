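#' Define a protein construct in full-length numbering
#'
#' A construct is a contiguous stretch of a full-length protein, identified by
#' its first and last residue numbers in the numbering of the complete chain
#' (1-based). Truncated constructs keep full-length numbering so that every
#' per-residue track produced downstream aligns with the intact protein.
#'
#' @param name Construct label, e.g. `"189-400"`.
#' @param first_residue First residue number (full-length numbering, >= 1).
#' @param last_residue Last residue number (>= `first_residue`).
#' @param sequence Optional one-letter amino-acid sequence. When supplied its
#'   length must equal `last_residue - first_residue + 1`.
#'
#' @return An object of class `"construct"`: a list with fields `name`,
#'   `first_residue`, `last_residue`, `sequence` and `n_residues`.
#'
#' @examples
#' construct("189-400", 189, 400)
#' n_residues(construct("149-400", 149, 400)) # 252
#' @export
construct <- function(name, first_residue, last_residue, sequence = NULL) {
  check_number(first_residue, "first_residue", integerish = TRUE)
  check_number(last_residue, "last_residue", integerish = TRUE)
  first_residue <- as.integer(round(first_residue))
  last_residue <- as.integer(round(last_residue))
  if (first_residue < 1L) {
    stop_idpnmr("`first_residue` must be >= 1")
  }
  if (last_residue < first_residue) {
    stop_idpnmr("`last_residue` must be >= `first_residue`")
  }
  n <- last_residue - first_residue + 1L
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) != 1L || nchar(sequence) != n) {
      stop_idpnmr(
        "`sequence` length (", nchar(sequence),
        ") must equal the construct span (", n, ")"
      )
    }
    bad <- setdiff(strsplit(sequence, "")[[1]], names(residue_masses()))
    if (length(bad) > 0) {
      stop_idpnmr("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(
      name = as.character(name),
      first_residue = first_residue,
      last_residue = last_residue,
      sequence = sequence,
      n_residues = n
    ),
    class = "construct"
  )
}

#' @rdname construct
#' @param x A `construct`.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "construct"))
  x$n_residues
}

#' @export
print.construct <- function(x, ...) {
  cat(
    "<construct> ", x$name, ": residues ", x$first_residue, "-",
    x$last_residue, " (", x$n_residues, " residues",
    if (is.null(x$sequence)) ", no sequence" else ", sequence attached",
    ")\n",
    sep = ""
  )
  invisible(x)
}
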