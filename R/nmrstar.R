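#' Import backbone chemical shifts from an NMR-STAR v3 file
#'
#' Reads the minimal `_Atom_chem_shift` loop of an NMR-STAR v3 file (the
#' format used for BMRB depositions): sequence ID, residue type, atom ID and
#' shift value. Every other frame and tag is ignored. Only backbone atoms
#' `H`, `N`, `CA`, `CB`, `C`, `HA` are retained; `HN` is accepted as a
#' synonym for `H`.
#'
#' Deposited tables may be numbered construct-locally rather than in
#' full-length coordinates; because the deposition itself does not say which,
#' the caller states the offset explicitly instead of the importer guessing.
#'
#' @param path NMR-STAR file.
#' @param offset Integer added to every sequence ID to convert the file's
#'   numbering to full-length numbering (default 0: file numbering kept).
#' @return A wide shift tibble (`residue_number`, `residue_type`, atom
#'   columns in ppm), as from [read_shift_table()]. Three-letter residue
#'   codes are converted to one-letter codes.
#' @export
read_nmrstar_shifts <- function(path, offset = 0) {
  check_number(offset, "offset", integerish = TRUE)
  offset <- as.integer(round(offset))
  if (!file.exists(path)) {
    stop_idpnmr("file not found: ", path)
  }
  lines <- trimws(readLines(path, warn = FALSE))

  # locate the loop whose tag block contains _Atom_chem_shift.* tags
  loop_starts <- which(lines == "loop_")
  target <- NULL
  for (s in loop_starts) {
    i <- s + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i])
      i <- i + 1L
    }
    if (any(grepl("^_Atom_chem_shift\\.", tags))) {
      target <- list(tags = tags, data_start = i)
      break
    }
  }
  if (is.null(target)) {
    stop_idpnmr("no _Atom_chem_shift loop found in ", path)
  }
  tagname <- sub("^_Atom_chem_shift\\.", "", target$tags)
  idx_of <- function(candidates) {
    hit <- which(tagname %in% candidates)
    if (length(hit) == 0) {
      stop_idpnmr(
        "required _Atom_chem_shift tag missing: ",
        paste(candidates, collapse = " / ")
      )
    }
    hit[1]
  }
  i_seq <- idx_of(c("Seq_ID", "Comp_index_ID"))
  i_comp <- idx_of("Comp_ID")
  i_atom <- idx_of("Atom_ID")
  i_val <- idx_of("Val")

  i <- target$data_start
  rows <- list()
  while (i <= length(lines) && lines[i] != "stop_") {
    if (nzchar(lines[i]) && !startsWith(lines[i], "#")) {
      f <- strsplit(lines[i], "\\s+")[[1]]
      if (length(f) >= max(i_seq, i_comp, i_atom, i_val)) {
        val <- suppressWarnings(as.numeric(f[i_val]))
        atom <- toupper(f[i_atom])
        if (atom == "HN") atom <- "H"
        if (!is.na(val) && atom %in% shift_atoms) {
          rows[[length(rows) + 1L]] <- tibble(
            residue_number = as.integer(f[i_seq]) + offset,
            residue_type = aa3to1(f[i_comp]),
            atom = atom,
            ppm = val
          )
        }
      }
    }
    i <- i + 1L
  }
  if (length(rows) == 0) {
    stop_idpnmr("the _Atom_chem_shift loop of ", path, " holds no usable rows")
  }
  long <- dplyr::bind_rows(rows)
  long |>
    tidyr::pivot_wider(names_from = "atom", values_from = "ppm") |>
    arrange(.data$residue_number)
}

aa3to1 <- function(x) {
  tab <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V"
  )
  x <- toupper(x)
  out <- ifelse(nchar(x) == 1, x, unname(tab[x]))
  if (anyNA(out)) {
    stop_idpnmr(
      "unknown residue code(s): ", paste(unique(x[is.na(out)]), collapse = ", ")
    )
  }
  out
}
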