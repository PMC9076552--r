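# File I/O: FASTA (via Biostrings), PDB ATOM records, CSV/JSON helpers.

#' Read protein sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a named
#' character vector (record ID up to the first whitespace = name). Works for
#' plain and aligned FASTA (gaps preserved).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read ATOM records from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records. The element symbol is taken
#' from columns 77-78, falling back to the first alphabetic character of the
#' atom name when the element field is blank.
#'
#' @param path PDB file.
#' @return `data.frame` with columns `serial`, `atom_name`, `resname`,
#'   `chain`, `resid`, `x`, `y`, `z`, `element`.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(lines) == 0) {
    return(data.frame(serial = integer(0), atom_name = character(0),
                      resname = character(0), chain = character(0),
                      resid = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), element = character(0)))
  }
  sub_ <- function(a, b) trimws(substr(lines, a, b))
  element <- sub_(77, 78)
  fallback <- toupper(gsub("[^A-Za-z].*$", "",
                           gsub("^[^A-Za-z]*", "", sub_(13, 16))))
  fallback <- substr(fallback, 1, 1)
  element <- ifelse(nzchar(element), toupper(element), fallback)
  data.frame(
    serial = as.integer(sub_(7, 11)),
    atom_name = sub_(13, 16),
    resname = sub_(18, 20),
    chain = substr(lines, 22, 22),
    resid = as.integer(sub_(23, 26)),
    x = as.numeric(sub_(31, 38)),
    y = as.numeric(sub_(39, 46)),
    z = as.numeric(sub_(47, 54)),
    element = element,
    stringsAsFactors = FALSE)
}

#' Write an atom table as PDB ATOM records
#'
#' @param atoms `data.frame` as returned by [read_pdb_atoms()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  fmt_name <- function(nm) {
    # standard PDB convention: 1-2 char element names start in column 14
    ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), nm)
  }
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial, fmt_name(atoms$atom_name), atoms$resname, atoms$chain,
    atoms$resid, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
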