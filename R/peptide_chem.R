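# Peptide mass arithmetic with isotope labels, tryptic digestion,
# precursor/fragment m/z, and MRM transition lists.

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, .AA_ALPHABET)
  if (length(bad) > 0) {
    stop("sequence contains non-standard residue(s): ",
         paste(unique(bad), collapse = ", "))
  }
  aa
}

.residue_masses <- function(aa) {
  vapply(aa, function(a) compose_mass(.RESIDUE_FORMULAS[[a]]), numeric(1),
         USE.NAMES = FALSE)
}

.resolve_labels <- function(site_labels) {
  # site_labels: named list/character vector, names = 1-based positions,
  # values = label names from the registry (or LabelDefinition objects)
  if (length(site_labels) == 0) return(list())
  if (is.null(names(site_labels))) {
    stop("site_labels must be named by 1-based residue position")
  }
  reg <- label_registry()
  lapply(stats::setNames(seq_along(site_labels), names(site_labels)),
         function(i) {
    lab <- site_labels[[i]]
    if (inherits(lab, "LabelDefinition")) return(lab)
    if (!lab %in% names(reg)) stop("unknown label: ", lab)
    reg[[lab]]
  })
}

#' Neutral monoisotopic peptide mass
#'
#' Sums residue masses, adds one water, and adds the elemental deltas of any
#' cysteine labels. Labels are given as a named vector/list mapping 1-based
#' positions within the peptide to label names from [label_registry()];
#' assigning a label to a non-cysteine position is an error.
#'
#' @param sequence peptide sequence (uppercase one-letter codes).
#' @param site_labels named character vector or list: position -> label name.
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' peptide_mass("G")                               # 75.03203
#' peptide_mass("TSPYECGFDPMGSAR", c("6" = "IAM-light"))
#' @export
peptide_mass <- function(sequence, site_labels = NULL) {
  aa <- .check_sequence(sequence)
  labs <- .resolve_labels(site_labels)
  mass <- sum(.residue_masses(aa)) + WATER_MASS
  for (pos_chr in names(labs)) {
    pos <- as.integer(pos_chr)
    if (is.na(pos) || pos < 1 || pos > length(aa)) {
      stop("label position out of range: ", pos_chr)
    }
    if (aa[pos] != labs[[pos_chr]]$target) {
      stop("label ", labs[[pos_chr]]$name, " assigned to non-cysteine ",
           "position ", pos, " (", aa[pos], ")")
    }
    mass <- mass + compose_mass(labs[[pos_chr]]$delta)
  }
  mass
}

#' m/z of a protonated species
#'
#' `(neutral_mass + z * 1.00728) / z`. The same convention is applied to the
#' intrinsically cationic triphenylphosphonium adduct (its printed
#' composition is treated as a neutral delta; see the methods vignette).
#'
#' @param neutral_mass neutral monoisotopic mass (Da).
#' @param z charge state, integer >= 1.
#' @return m/z.
#' @examples
#' mz(peptide_mass("ANPYECGFDPTSSAR", c("6" = "IAM-light")), 2) # 836.3570
#' @export
mz <- function(neutral_mass, z) {
  stopifnot(is.numeric(neutral_mass), is.numeric(z))
  if (any(z < 1) || any(z != round(z))) stop("charge z must be an integer >= 1")
  (neutral_mass + z * PROTON_MASS) / z
}

#' Labeled peptide species
#'
#' Bundles a peptide (with precursor coordinates), a per-cysteine-site label
#' assignment and a charge state, and carries the derived neutral mass and
#' m/z.
#'
#' @param sequence peptide sequence.
#' @param site_labels named vector: peptide position -> label name.
#' @param z charge state (>= 1).
#' @param protein parent protein identifier.
#' @param start 1-based start coordinate in the precursor sequence.
#' @return Object of class `LabeledPeptideSpecies` with fields `sequence`,
#'   `site_labels`, `z`, `neutral_mass`, `mz`, `protein`, `start`, `end`.
#' @examples
#' sp <- labeled_peptide("TSPYECGFDPMGSAR", c("6" = "IAM-heavy"), z = 2)
#' sp$mz # 839.8576
#' @export
labeled_peptide <- function(sequence, site_labels = NULL, z = 2L,
                            protein = NA_character_, start = 1L) {
  aa <- .check_sequence(sequence)
  m <- peptide_mass(sequence, site_labels)
  structure(
    list(sequence = sequence, site_labels = site_labels, z = as.integer(z),
         neutral_mass = m, mz = mz(m, z), protein = protein,
         start = as.integer(start),
         end = as.integer(start) + length(aa) - 1L),
    class = "LabeledPeptideSpecies"
  )
}

#' @export
print.LabeledPeptideSpecies <- function(x, ...) {
  labs <- if (length(x$site_labels)) {
    paste0(names(x$site_labels), ":", unlist(x$site_labels), collapse = ",")
  } else "none"
  cat(sprintf("%s (%d-%d) z=%d labels[%s] M=%.4f m/z=%.4f\n",
              x$sequence, x$start, x$end, x$z, labs, x$neutral_mass, x$mz))
  invisible(x)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the following residue is proline,
#' and emits every peptide with 0..`missed_cleavages_max` missed cleavages.
#' Coordinates are 1-based inclusive in the input (precursor) sequence, so
#' the 0-missed-cleavage peptides tile the protein exactly.
#'
#' @param protein_sequence protein sequence (uppercase one-letter codes).
#' @param missed_cleavages_max maximum number of missed cleavages (>= 0).
#' @param protein parent protein identifier carried into the output.
#' @return `data.frame` with columns `protein`, `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' digest("AKRPGK", 0)  # AK (1-2), RPGK (3-6)
#' @export
digest <- function(protein_sequence, missed_cleavages_max = 0L,
                   protein = NA_character_) {
  aa <- .check_sequence(protein_sequence)
  stopifnot(missed_cleavages_max >= 0)
  n <- length(aa)
  # cut sites: after position i if aa[i] in K/R and aa[i+1] != P
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts == n | aa[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts[cuts < n], n)   # segment boundaries (cut after index)
  nseg <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (k in 0:missed_cleavages_max) {
      j <- i + k
      if (j > nseg) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      out[[length(out) + 1L]] <- data.frame(
        protein = protein,
        sequence = paste(aa[s:e], collapse = ""),
        start = s, end = e, missed_cleavages = k,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Fragment ion m/z (y and b series)
#'
#' For a [labeled_peptide()] species, computes the m/z of the `n`-th y ion
#' (C-terminal `n` residues plus water) or b ion (N-terminal `n` residues) at
#' fragment charge `z`. Site labels are included when the labeled residue
#' falls inside the fragment.
#'
#' @param species a `LabeledPeptideSpecies`.
#' @param series `"y"` or `"b"`.
#' @param n fragment index, `1 <= n < nchar(sequence)`.
#' @param z fragment charge (>= 1).
#' @return Fragment ion m/z.
#' @examples
#' sp <- labeled_peptide("ANPYECGFDPTSSAR", c("6" = "IAM-light"), z = 2)
#' fragment_mz(sp, "y", 13, 2)
#' @export
fragment_mz <- function(species, series = c("y", "b"), n, z = 1L) {
  stopifnot(inherits(species, "LabeledPeptideSpecies"))
  series <- match.arg(series)
  len <- nchar(species$sequence)
  if (n < 1 || n >= len) stop("fragment index n must satisfy 1 <= n < ", len)
  aa <- strsplit(species$sequence, "")[[1]]
  idx <- if (series == "y") (len - n + 1L):len else 1:n
  m <- sum(.residue_masses(aa[idx]))
  if (series == "y") m <- m + WATER_MASS
  labs <- .resolve_labels(species$site_labels)
  for (pos_chr in names(labs)) {
    if (as.integer(pos_chr) %in% idx) {
      m <- m + compose_mass(labs[[pos_chr]]$delta)
    }
  }
  mz(m, z)
}

#' MRM transition list
#'
#' Builds a computed (not instrument-tuned) transition table: one row per
#' label channel, each pairing the labeled precursor m/z with the m/z of a
#' single product ion named by `fragment_spec`.
#'
#' @param sequence peptide sequence containing exactly the cysteine sites to
#'   be labeled.
#' @param labels character vector of label names from [label_registry()];
#'   each is applied to every cysteine in the peptide.
#' @param precursor_z precursor charge.
#' @param fragment_spec list with elements `series` ("y"/"b"), `n`, `z`.
#' @param species_name identifier prefix for the output rows.
#' @return `data.frame` with columns `species`, `label`, `z`, `precursor_mz`,
#'   `product_mz`, suitable for CSV export.
#' @examples
#' transition_list("ANPYECGFDPTSSAR", c("IAM-light", "IAM-heavy"), 2,
#'                 list(series = "y", n = 13, z = 2))
#' @export
transition_list <- function(sequence, labels, precursor_z = 2L,
                            fragment_spec = list(series = "y", n = 13, z = 2),
                            species_name = sequence) {
  if (length(labels) == 0) {
    return(data.frame(species = character(0), label = character(0),
                      z = integer(0), precursor_mz = numeric(0),
                      product_mz = numeric(0), stringsAsFactors = FALSE))
  }
  aa <- .check_sequence(sequence)
  cys <- which(aa == "C")
  if (length(cys) == 0) stop("peptide contains no cysteine to label")
  rows <- lapply(labels, function(lab) {
    site_labels <- stats::setNames(rep(lab, length(cys)), cys)
    sp <- labeled_peptide(sequence, site_labels, z = precursor_z)
    data.frame(
      species = species_name, label = lab, z = precursor_z,
      precursor_mz = sp$mz,
      product_mz = fragment_mz(sp, fragment_spec$series, fragment_spec$n,
                               fragment_spec$z),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Labeled-peptide m/z table
#'
#' Convenience wrapper reproducing the package's reference mass table: for a
#' peptide with one cysteine, computes the precursor m/z for each requested
#' label at each charge state.
#'
#' @param sequence peptide sequence with at least one cysteine.
#' @param labels label names (default: all irreversible labels).
#' @param charges integer vector of charge states.
#' @return `data.frame` with columns `sequence`, `label`, `z`, `mz`.
#' @export
mass_table <- function(sequence,
                       labels = c("IAM-light", "IAM-heavy", "NEM", "d5-NEM",
                                  "TPP-IAM", "d15-TPP-IAM"),
                       charges = c(2L, 3L)) {
  aa <- .check_sequence(sequence)
  cys <- which(aa == "C")
  if (length(cys) == 0) stop("peptide contains no cysteine")
  grid <- expand.grid(label = labels, z = charges, stringsAsFactors = FALSE)
  grid$sequence <- sequence
  grid$mz <- mapply(function(lab, z) {
    site_labels <- stats::setNames(rep(lab, length(cys)), cys)
    labeled_peptide(sequence, site_labels, z = z)$mz
  }, grid$label, grid$z)
  grid[, c("sequence", "label", "z", "mz")]
}
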