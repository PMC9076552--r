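# Comparative cysteine survey: conservation mapping, tryptic detectability,
# gamma-sulfur solvent accessibility (Shrake-Rupley), survey summary.

#' Survey parameters
#'
#' @param sasa_cutoff exposed/occluded cutoff for gamma-S SASA (A^2).
#' @param probe_radius solvent probe radius (A).
#' @param min_peptide_length minimum tryptic peptide length for detectability.
#' @param min_mh2 minimum doubly-protonated m/z.
#' @param max_mass maximum monoisotopic peptide mass (Da).
#' @param max_cys maximum cysteines per peptide.
#' @return List of class `SurveyParams`.
#' @export
survey_params <- function(sasa_cutoff = 5, probe_radius = 1.4,
                          min_peptide_length = 7, min_mh2 = 400,
                          max_mass = 6000, max_cys = 3) {
  p <- list(sasa_cutoff = sasa_cutoff, probe_radius = probe_radius,
            min_peptide_length = min_peptide_length, min_mh2 = min_mh2,
            max_mass = max_mass, max_cys = max_cys)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(p, class = "SurveyParams")
}

#' Map conserved cysteines from a multiple alignment
#'
#' For every cysteine in the (gapped) reference sequence, reports whether all
#' subject species carry a cysteine in the homologous alignment column.
#' Positions are reported in ungapped reference coordinates.
#'
#' @param alignment named character vector of equal-length gapped sequences
#'   (`-` or `.` as gap), e.g. from [read_fasta()] on an aligned FASTA.
#' @param reference_species name of the reference record.
#' @param subject_species names of subject records (default: all others).
#' @return `data.frame` with columns `position` (ungapped reference),
#'   `column` (alignment column), `conserved`.
#' @export
map_conserved_cysteines <- function(alignment, reference_species,
                                    subject_species = NULL) {
  stopifnot(is.character(alignment), !is.null(names(alignment)))
  if (!reference_species %in% names(alignment)) {
    stop("reference species not in alignment: ", reference_species)
  }
  if (length(unique(nchar(alignment))) != 1) {
    stop("ragged alignment: sequences differ in length")
  }
  if (is.null(subject_species)) {
    subject_species <- setdiff(names(alignment), reference_species)
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  ref <- mat[reference_species, ]
  is_gap <- ref %in% c("-", ".")
  ungapped <- cumsum(!is_gap)
  cols <- which(ref == "C")
  if (length(cols) == 0) {
    return(data.frame(position = integer(0), column = integer(0),
                      conserved = logical(0)))
  }
  conserved <- vapply(cols, function(j) {
    all(mat[subject_species, j] == "C")
  }, logical(1))
  data.frame(position = ungapped[cols], column = cols, conserved = conserved)
}

#' Classify MS detectability of a cysteine site
#'
#' Forms the fully-tryptic (0 missed cleavage) peptide containing the site
#' and applies four threshold rules in order: peptide length, doubly
#' protonated m/z (with carbamidomethyl on every cysteine), monoisotopic
#' mass, and cysteine count. The first violated rule names the
#' `undetectable:<reason>` class. Peptides carrying more than one cysteine
#' are additionally flagged (`multi_cys`) because their channel areas are not
#' site-resolvable.
#'
#' @param protein_sequence full protein (precursor) sequence.
#' @param cys_position 1-based position of a cysteine in that sequence.
#' @param params a [survey_params()] object.
#' @return List with `class` (`"detectable"` or `"undetectable:<reason>"`),
#'   `peptide`, `peptide_start`, `peptide_end`, `n_cys`, `multi_cys`, `mh2`,
#'   `mass`.
#' @export
classify_detectability <- function(protein_sequence, cys_position,
                                   params = survey_params()) {
  aa <- .check_sequence(protein_sequence)
  if (cys_position < 1 || cys_position > length(aa) ||
      aa[cys_position] != "C") {
    stop("position ", cys_position, " is not a cysteine")
  }
  peps <- digest(protein_sequence, 0L)
  row <- peps[peps$start <= cys_position & peps$end >= cys_position, ]
  stopifnot(nrow(row) == 1)
  pep <- row$sequence
  n_cys <- sum(strsplit(pep, "")[[1]] == "C")
  cam_sites <- which(strsplit(pep, "")[[1]] == "C")
  site_labels <- stats::setNames(rep("IAM-light", n_cys), cam_sites)
  mass_cam <- peptide_mass(pep, site_labels)
  mh2 <- mz(mass_cam, 2)
  cls <- if (nchar(pep) < params$min_peptide_length) {
    "undetectable:length"
  } else if (mh2 < params$min_mh2) {
    "undetectable:mz"
  } else if (mass_cam > params$max_mass) {
    "undetectable:mass"
  } else if (n_cys > params$max_cys) {
    "undetectable:cys-count"
  } else {
    "detectable"
  }
  list(class = cls, peptide = pep, peptide_start = row$start,
       peptide_end = row$end, n_cys = n_cys, multi_cys = n_cys > 1,
       mh2 = mh2, mass = mass_cam)
}

# Near-uniform points on the unit sphere (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Places near-uniform test points on a sphere of radius
#' `r_atom + probe_radius` around each target atom and counts the fraction
#' not occluded by any neighbouring atom's probe-expanded sphere:
#' `SASA = 4 * pi * (r + probe)^2 * unoccluded fraction`.
#'
#' @param atoms `data.frame` with columns `x`, `y`, `z`, `element` (and
#'   typically `atom_name`, `resname`, `chain`, `resid` from
#'   [read_pdb_atoms()]). All atoms act as occluders.
#' @param targets integer row indices of the atoms whose SASA is wanted;
#'   default: gamma-sulfur (`SG`) atoms of cysteine residues.
#' @param probe_radius solvent probe radius (A), default 1.4.
#' @param n_sphere_points number of test points per atom (default 960).
#' @param radii named per-element van der Waals radii; defaults to
#'   [VDW_RADII]; unknown elements fall back to 1.7 A.
#' @return `data.frame`: the target atom rows plus a `sasa` column (A^2);
#'   zero rows when the structure has no matching target atom.
#' @export
gamma_s_sasa <- function(atoms, targets = NULL, probe_radius = 1.4,
                         n_sphere_points = 960, radii = VDW_RADII) {
  stopifnot(is.data.frame(atoms),
            all(c("x", "y", "z", "element") %in% names(atoms)))
  if (is.null(targets)) {
    targets <- which(atoms$element == "S" &
                       toupper(atoms$resname) == "CYS" &
                       trimws(atoms$atom_name) == "SG")
  }
  if (length(targets) == 0) {
    out <- atoms[integer(0), , drop = FALSE]
    out$sasa <- numeric(0)
    return(out)
  }
  r_atom <- radii[atoms$element]
  r_atom[is.na(r_atom)] <- 1.7
  r_ext <- r_atom + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  sp <- .sphere_points(n_sphere_points)
  sasa <- vapply(targets, function(i) {
    pts <- sweep(sp * r_ext[i], 2, xyz[i, ], `+`)
    # neighbours whose expanded sphere can reach the test sphere
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], `-`)^2)
    nb <- which(d2 < (r_ext + r_ext[i])^2 & seq_len(nrow(xyz)) != i)
    free <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
             (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 > r_ext[j]^2
    }
    4 * pi * r_ext[i]^2 * mean(free)
  }, numeric(1))
  out <- atoms[targets, , drop = FALSE]
  out$sasa <- sasa
  rownames(out) <- NULL
  out
}

#' Classify a cysteine's exposure across structural states
#'
#' Labels the site exposed (`SASA > cutoff`, strictly) or occluded in each
#' of the two structural states and derives the candidate pattern:
#' occluded-in-active AND exposed-in-deactive. A residue unmodeled in the
#' deactive structure (`NA` SASA) counts as exposed there, following the
#' disordered-loop convention (an unresolved loop is presumed mobile and
#' solvent exposed).
#'
#' @param sasa_active,sasa_deactive gamma-S SASA in the two states (A^2);
#'   `NA` marks an unmodeled residue.
#' @param cutoff exposure cutoff (A^2), default 5.
#' @return List with `active` and `deactive` (`"exposed"`, `"occluded"` or
#'   `"unmodeled-exposed"`) and logical `candidate`.
#' @export
classify_exposure_states <- function(sasa_active, sasa_deactive, cutoff = 5) {
  lab <- function(s) {
    if (is.na(s)) "unmodeled-exposed"
    else if (s > cutoff) "exposed" else "occluded"
  }
  a <- lab(sasa_active)
  d <- lab(sasa_deactive)
  list(active = a, deactive = d,
       candidate = (a == "occluded") && d %in% c("exposed",
                                                 "unmodeled-exposed"))
}

#' Build cysteine survey records
#'
#' Combines conservation mapping, detectability classification, per-state
#' gamma-S SASA and an annotation table into one record per cysteine of the
#' reference protein.
#'
#' @param alignment gapped alignment (named character vector) containing the
#'   reference.
#' @param reference_species reference record name.
#' @param sasa_active,sasa_deactive optional named numeric vectors of gamma-S
#'   SASA keyed by residue position (character names); positions absent from
#'   a vector are treated as unmodeled (`NA`).
#' @param annotations optional `data.frame` with columns `position`,
#'   `annotation` (values among `FeS-ligand`, `intramolecular-disulfide`,
#'   `targeting-sequence`).
#' @param quantified optional integer vector of positions with a measured
#'   exposure value.
#' @param params a [survey_params()].
#' @return `data.frame` of `CysteineRecord` rows: `position`, `conserved`,
#'   `annotation`, `detectability`, `multi_cys`, `sasa_active`,
#'   `sasa_deactive`, `state_active`, `state_deactive`, `candidate`,
#'   `quantified`.
#' @export
cysteine_survey <- function(alignment, reference_species,
                            sasa_active = NULL, sasa_deactive = NULL,
                            annotations = NULL, quantified = integer(0),
                            params = survey_params()) {
  cons <- map_conserved_cysteines(alignment, reference_species)
  refseq <- gsub("[-.]", "", alignment[[reference_species]])
  if (nrow(cons) == 0) return(cons)
  recs <- lapply(seq_len(nrow(cons)), function(i) {
    pos <- cons$position[i]
    det <- classify_detectability(refseq, pos, params)
    sa <- if (!is.null(sasa_active)) sasa_active[as.character(pos)] else NA
    sd_ <- if (!is.null(sasa_deactive)) sasa_deactive[as.character(pos)]
           else NA
    sa <- ifelse(is.null(sa) || length(sa) == 0, NA_real_, unname(sa))
    sd_ <- ifelse(is.null(sd_) || length(sd_) == 0, NA_real_, unname(sd_))
    st <- classify_exposure_states(sa, sd_, params$sasa_cutoff)
    ann <- "none"
    if (!is.null(annotations)) {
      hit <- annotations$annotation[annotations$position == pos]
      if (length(hit) > 0) ann <- hit[1]
    }
    data.frame(position = pos, conserved = cons$conserved[i],
               annotation = ann, detectability = det$class,
               multi_cys = det$multi_cys,
               sasa_active = sa, sasa_deactive = sd_,
               state_active = st$active, state_deactive = st$deactive,
               candidate = st$candidate,
               quantified = pos %in% quantified,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, recs)
  rownames(res) <- NULL
  res
}

.pct1 <- function(num, den) {
  if (is.na(den) || den == 0) return(NA_real_)
  # round half away from zero at one decimal
  x <- 100 * num / den
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Survey summary counts and percentages
#'
#' Reproduces the survey's count cascade: of the conserved cysteines, how
#' many were quantified; of the residues with no data, how many are
#' iron-sulfur ligands, disulfide-bonded, or undetectable; how many
#' unquantified candidates remain and how many of those are FeS or disulfide
#' cysteines. Percentages are `100 x count / denominator` rounded (half away
#' from zero) to one decimal:
#' quantified and candidates are percentages of the conserved count; FeS,
#' disulfide and undetectable are percentages of the no-data count;
#' FeS-or-disulfide is a percentage of the candidate count.
#'
#' @param records `data.frame` from [cysteine_survey()], or a list of counts
#'   with elements `total`, `conserved`, `quantified`, `no_data`,
#'   `fes_no_data`, `disulfide_no_data`, `undetectable_no_data`,
#'   `candidates`, `fes_or_disulfide_candidates` (the printed cascade can be
#'   fed in directly).
#' @return List of class `SurveySummary` with the counts and the derived
#'   one-decimal percentages (`pct_quantified`, `pct_fes_no_data`,
#'   `pct_disulfide_no_data`, `pct_undetectable_no_data`, `pct_candidates`,
#'   `pct_fes_or_disulfide_candidates`).
#' @export
survey_summary <- function(records) {
  if (is.data.frame(records)) {
    if (nrow(records) == 0) {
      counts <- list(total = 0L, conserved = 0L, quantified = 0L,
                     no_data = 0L, fes_no_data = 0L, disulfide_no_data = 0L,
                     undetectable_no_data = 0L, candidates = 0L,
                     fes_or_disulfide_candidates = 0L)
    } else {
      cons <- records[records$conserved, , drop = FALSE]
      nod <- cons[!cons$quantified, , drop = FALSE]
      fes_ds <- function(df) df$annotation %in% c("FeS-ligand",
                                                  "intramolecular-disulfide")
      counts <- list(
        total = nrow(records),
        conserved = nrow(cons),
        quantified = sum(cons$quantified),
        no_data = nrow(nod),
        fes_no_data = sum(nod$annotation == "FeS-ligand"),
        disulfide_no_data = sum(nod$annotation == "intramolecular-disulfide"),
        undetectable_no_data = sum(grepl("^undetectable", nod$detectability)),
        candidates = nrow(nod),  # unquantified conserved residues
        fes_or_disulfide_candidates = sum(fes_ds(nod)))
    }
  } else {
    counts <- records
  }
  need <- c("total", "conserved", "quantified", "no_data", "fes_no_data",
            "disulfide_no_data", "undetectable_no_data", "candidates",
            "fes_or_disulfide_candidates")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count(s): ", paste(miss, collapse = ", "))
  structure(c(counts, list(
    pct_quantified = .pct1(counts$quantified, counts$conserved),
    pct_fes_no_data = .pct1(counts$fes_no_data, counts$no_data),
    pct_disulfide_no_data = .pct1(counts$disulfide_no_data, counts$no_data),
    pct_undetectable_no_data = .pct1(counts$undetectable_no_data,
                                     counts$no_data),
    pct_candidates = .pct1(counts$candidates, counts$conserved),
    pct_fes_or_disulfide_candidates = .pct1(
      counts$fes_or_disulfide_candidates, counts$candidates))),
    class = "SurveySummary")
}

#' @export
print.SurveySummary <- function(x, ...) {
  cat(sprintf(
    "Cysteine survey: %d total, %d conserved; %d quantified (%.1f%%)\n",
    x$total, x$conserved, x$quantified, x$pct_quantified))
  cat(sprintf(
    "  no data: %d  [FeS %d (%.1f%%), disulfide %d (%.1f%%), undetectable %d (%.1f%%)]\n",
    x$no_data, x$fes_no_data, x$pct_fes_no_data, x$disulfide_no_data,
    x$pct_disulfide_no_data, x$undetectable_no_data,
    x$pct_undetectable_no_data))
  cat(sprintf(
    "  unquantified candidates: %d (%.1f%%), of which FeS/disulfide %d (%.1f%%)\n",
    x$candidates, x$pct_candidates, x$fes_or_disulfide_candidates,
    x$pct_fes_or_disulfide_candidates))
  invisible(x)
}
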