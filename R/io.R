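#' @section File dialect:
#' All tabular files use a single dialect: UTF-8, tab-separated, `#` starts a
#' comment line, and a header row is mandatory. Blank cells or the literal
#' `NA` mean "unassigned"; consumers propagate missing values rather than
#' substituting zero.
#' @name idpnmr-io
#' @keywords internal
NULL

shift_atoms <- c("H", "N", "CA", "CB", "C", "HA")

# tokenized non-comment lines with their original line numbers
read_dialect_lines <- function(path) {
  if (!file.exists(path)) {
    stop_idpnmr("file not found: ", path)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  split_keep_trailing <- function(l) {
    # strsplit drops trailing empty fields; a sentinel keeps them
    f <- strsplit(paste0(l, "\x03"), "\t", fixed = TRUE)[[1]]
    f[length(f)] <- sub("\x03$", "", f[length(f)])
    f
  }
  list(
    fields = lapply(raw[keep], split_keep_trailing),
    line_numbers = which(keep)
  )
}

parse_num_cell <- function(cell, line, what) {
  cell <- trimws(cell)
  if (cell == "" || toupper(cell) == "NA") {
    return(NA_real_)
  }
  val <- suppressWarnings(as.numeric(cell))
  if (is.na(val)) {
    stop_idpnmr("line ", line, ": cannot parse ", what, " value '", cell, "'")
  }
  val
}

#' Read a per-residue chemical shift table
#'
#' Reads assigned backbone chemical shifts in the package's tab-separated
#' dialect: mandatory header with columns `residue_number`, `residue_type`,
#' followed by any subset of the atom columns `H`, `N`, `CA`, `CB`, `C`, `HA`.
#' Blank or `NA` cells mean the atom is unassigned. Residue numbers in the
#' file are authoritative (full-length numbering); they are validated against
#' the construct range but never shifted.
#'
#' @param path Path to the table.
#' @param construct A [construct()]; every residue number must fall inside it.
#'
#' @return A tibble with one row per residue: `residue_number`,
#'   `residue_type`, and one numeric ppm column per atom present in the file.
#' @seealso [write_shift_table()], [read_nmrstar_shifts()]
#' @export
read_shift_table <- function(path, construct) {
  stopifnot(inherits(construct, "construct"))
  dat <- read_dialect_lines(path)
  if (length(dat$fields) == 0) {
    stop_idpnmr("file ", path, " has no header row")
  }
  header <- trimws(dat$fields[[1]])
  if (!identical(header[1:2], c("residue_number", "residue_type"))) {
    stop_idpnmr(
      "line ", dat$line_numbers[1],
      ": header must start with residue_number, residue_type"
    )
  }
  atoms <- header[-(1:2)]
  unknown <- setdiff(atoms, shift_atoms)
  if (length(unknown) > 0) {
    stop_idpnmr(
      "unknown atom column(s): ", paste(unknown, collapse = ", "),
      " (allowed: ", paste(shift_atoms, collapse = ", "), ")"
    )
  }
  rows <- dat$fields[-1]
  lines <- dat$line_numbers[-1]
  out <- lapply(seq_along(rows), function(i) {
    f <- rows[[i]]
    ln <- lines[[i]]
    if (length(f) != length(header)) {
      stop_idpnmr(
        "line ", ln, ": expected ", length(header), " fields, found ", length(f)
      )
    }
    resnum <- parse_num_cell(f[1], ln, "residue_number")
    if (is.na(resnum) || abs(resnum - round(resnum)) > 0) {
      stop_idpnmr("line ", ln, ": residue_number must be an integer")
    }
    resnum <- as.integer(resnum)
    if (resnum < construct$first_residue || resnum > construct$last_residue) {
      stop_idpnmr(
        "line ", ln, ": residue ", resnum, " outside construct range ",
        construct$first_residue, "-", construct$last_residue
      )
    }
    shifts <- vapply(
      seq_along(atoms),
      function(j) parse_num_cell(f[j + 2L], ln, atoms[j]),
      numeric(1)
    )
    c(
      list(residue_number = resnum, residue_type = toupper(trimws(f[2]))),
      setNames(as.list(shifts), atoms)
    )
  })
  if (length(out) == 0) {
    cols <- c(
      list(residue_number = integer(), residue_type = character()),
      setNames(rep(list(numeric()), length(atoms)), atoms)
    )
    return(as_tibble(cols))
  }
  dplyr::bind_rows(lapply(out, as_tibble))
}

#' @rdname read_shift_table
#' @param x A shift tibble as returned by `read_shift_table()`.
#' @export
write_shift_table <- function(x, path) {
  atoms <- intersect(shift_atoms, names(x))
  header <- c("residue_number", "residue_type", atoms)
  fmt_cell <- function(v) ifelse(is.na(v), "", sprintf("%.3f", v))
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(
      c(
        as.character(x$residue_number[i]),
        x$residue_type[i],
        vapply(atoms, function(a) fmt_cell(x[[a]][i]), character(1))
      ),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}

#' Read or write a long-format peak measurement series
#'
#' A series file holds one peak measurement per row in long format with
#' mandatory columns `residue_number`, `condition_label`, `h_ppm`, `n_ppm`,
#' `intensity`. Condition labels identify relaxation delays or titration
#' points. Writing uses a canonical formatting (6 decimal places for ppm,
#' scientific notation for intensities) so that write -> read -> write is
#' byte-identical.
#'
#' @param path File path.
#' @return `read_series()` returns a tibble with the five columns above plus
#'   a logical `missing` column (`TRUE` when either ppm or the intensity is
#'   unassigned).
#' @export
read_series <- function(path) {
  dat <- read_dialect_lines(path)
  if (length(dat$fields) == 0) {
    stop_idpnmr("file ", path, " has no header row")
  }
  header <- trimws(dat$fields[[1]])
  expect <- c("residue_number", "condition_label", "h_ppm", "n_ppm", "intensity")
  if (!identical(header[seq_along(expect)], expect)) {
    stop_idpnmr(
      "line ", dat$line_numbers[1], ": header must be ",
      paste(expect, collapse = ", ")
    )
  }
  rows <- dat$fields[-1]
  lines <- dat$line_numbers[-1]
  n <- length(rows)
  resnum <- integer(n); cond <- character(n)
  h <- numeric(n); nppm <- numeric(n); inten <- numeric(n)
  for (i in seq_len(n)) {
    f <- rows[[i]]
    ln <- lines[[i]]
    if (length(f) < 5L) {
      stop_idpnmr("line ", ln, ": expected 5 fields, found ", length(f))
    }
    rn <- parse_num_cell(f[1], ln, "residue_number")
    if (is.na(rn)) stop_idpnmr("line ", ln, ": residue_number missing")
    resnum[i] <- as.integer(rn)
    cond[i] <- trimws(f[2])
    h[i] <- parse_num_cell(f[3], ln, "h_ppm")
    nppm[i] <- parse_num_cell(f[4], ln, "n_ppm")
    inten[i] <- parse_num_cell(f[5], ln, "intensity")
    if (!is.na(inten[i]) && inten[i] < 0) {
      # noisy peak intensities may dip below zero; negative *file* intensities
      # are accepted for the same reason
    }
  }
  key <- paste(resnum, cond, sep = "\r")
  if (anyDuplicated(key) > 0) {
    d <- which(duplicated(key))[1]
    stop_idpnmr(
      "line ", lines[[d]], ": duplicate (residue ", resnum[d],
      ", condition '", cond[d], "') pair"
    )
  }
  tibble(
    residue_number = resnum,
    condition_label = cond,
    h_ppm = h,
    n_ppm = nppm,
    intensity = inten,
    missing = is.na(h) | is.na(nppm) | is.na(inten)
  )
}

#' @rdname read_series
#' @param x A series tibble (columns `residue_number`, `condition_label`,
#'   `h_ppm`, `n_ppm`, `intensity`; extra columns are dropped on write).
#' @export
write_series <- function(x, path) {
  fmt_ppm <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  fmt_int <- function(v) ifelse(is.na(v), "NA", sprintf("%.6e", v))
  header <- "residue_number\tcondition_label\th_ppm\tn_ppm\tintensity"
  body <- paste(
    x$residue_number,
    x$condition_label,
    fmt_ppm(x$h_ppm),
    fmt_ppm(x$n_ppm),
    fmt_int(x$intensity),
    sep = "\t"
  )
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Reads an amino-acid alignment in FASTA or Clustal format (detected from
#' the first non-blank line unless `format` is given) and validates that all
#' rows have equal length and that at least two sequences are present.
#'
#' @param path Alignment file.
#' @param format `"auto"`, `"fasta"` or `"clustal"`.
#' @return An object of class `"msa"`: a list with `labels` (character) and
#'   `seqs` (character matrix of upper-case residues and `-` gaps, one row
#'   per sequence).
#' @seealso [conservation_mask()]
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_idpnmr("file not found: ", path)
  }
  if (format == "auto") {
    first <- readLines(path, n = 25L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) > 0 && startsWith(trimws(first[1]), ">")) {
      "fasta"
    } else {
      "clustal"
    }
  }
  if (format == "fasta") {
    aln <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
    labels <- names(aln)
    seqs <- toupper(unlist(aln, use.names = FALSE))
  } else {
    aln <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"),
      error = function(e) {
        stop_idpnmr("cannot parse Clustal alignment: ", conditionMessage(e))
      }
    )
    labels <- rownames(aln)
    seqs <- toupper(as.character(aln))
  }
  if (length(seqs) < 2) {
    stop_idpnmr(
      "alignment must contain at least 2 sequences, found ", length(seqs)
    )
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop_idpnmr(
      "ragged alignment: row lengths ", paste(sort(unique(lens)), collapse = ", ")
    )
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  mat[mat == "."] <- "-"
  rownames(mat) <- labels
  structure(list(labels = labels, seqs = mat), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(
    "<msa> ", length(x$labels), " sequences x ", ncol(x$seqs), " columns\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as_tibble.msa <- function(x, ...) {
  tibble(label = x$labels, sequence = apply(x$seqs, 1, paste, collapse = ""))
}
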