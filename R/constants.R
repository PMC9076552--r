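# Physical constants and embedded lookup tables shared across modules.

#' Monoisotopic atomic masses (Da)
#'
#' Embedded table of monoisotopic atomic masses used for all mass arithmetic.
#' Keys are isotope-species codes: the bare element symbol denotes the most
#' abundant (default) isotope; `C13` and `H2` denote carbon-13 and deuterium.
#'
#' @format Named numeric vector (Da).
#' @export
ATOMIC_MASSES <- c(
  H   = 1.0078250,
  C   = 12.0000000,
  N   = 14.0030740,
  O   = 15.9949146,
  S   = 31.9720707,
  P   = 30.9737615,
  C13 = 13.0033548,
  H2  = 2.0141018
)

#' Proton mass used for m/z computation (Da)
#' @export
PROTON_MASS <- 1.00728

#' Monoisotopic mass of water (Da), H2O from [ATOMIC_MASSES]
#' @export
WATER_MASS <- 2 * 1.0078250 + 15.9949146

# Residue elemental compositions (residue = amino acid minus water).
.RESIDUE_FORMULAS <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.AA_ALPHABET <- names(.RESIDUE_FORMULAS)

#' Built-in thiol label registry
#'
#' Returns the registry of cysteine-directed labels known to the package.
#' Each entry is a `LabelDefinition`: the elemental delta added to the thiol,
#' a channel tag (`light`/`heavy`/`other`), whether the adduct is reversible
#' (only MMTS, which is displaced before MS analysis and therefore carries no
#' detectable delta), and the name of its heavy isotopologue counterpart.
#'
#' Registered labels: `IAM-light` (carbamidomethyl, +C2H3NO), `IAM-heavy`
#' (13C2, 2-d2 carbamidomethyl), `NEM`, `d5-NEM`, `TPP-IAM`, `d15-TPP-IAM`,
#' and `MMTS`.
#'
#' @return Named list of `LabelDefinition` objects.
#' @examples
#' names(label_registry())
#' label_registry()[["IAM-light"]]$delta
#' @export
label_registry <- function() .LABEL_REGISTRY

.make_label <- function(name, delta, channel, reversible = FALSE,
                        heavy_counterpart = NA_character_) {
  structure(
    list(name = name, target = "C", delta = delta, channel = channel,
         reversible = reversible, heavy_counterpart = heavy_counterpart),
    class = "LabelDefinition"
  )
}

.LABEL_REGISTRY <- list(
  "IAM-light" = .make_label("IAM-light",
    elemental_composition(c(C = 2, H = 3, N = 1, O = 1)),
    channel = "light", heavy_counterpart = "IAM-heavy"),
  "IAM-heavy" = .make_label("IAM-heavy",
    elemental_composition(c(C13 = 2, H2 = 2, H = 1, N = 1, O = 1)),
    channel = "heavy"),
  "NEM" = .make_label("NEM",
    elemental_composition(c(C = 6, H = 7, N = 1, O = 2)),
    channel = "light", heavy_counterpart = "d5-NEM"),
  "d5-NEM" = .make_label("d5-NEM",
    elemental_composition(c(C = 6, H2 = 5, H = 2, N = 1, O = 2)),
    channel = "heavy"),
  # The phosphonium adduct is intrinsically cationic; by convention its
  # printed composition is treated as a neutral delta and protonated like any
  # other species (documented in the methods vignette).
  "TPP-IAM" = .make_label("TPP-IAM",
    elemental_composition(c(C = 25, H = 27, N = 1, O = 1, P = 1)),
    channel = "light", heavy_counterpart = "d15-TPP-IAM"),
  "d15-TPP-IAM" = .make_label("d15-TPP-IAM",
    elemental_composition(c(C = 25, H = 12, H2 = 15, N = 1, O = 1, P = 1)),
    channel = "heavy"),
  # MMTS blocks thiols reversibly and is displaced before analysis: it is
  # never assigned a detectable MS species, so its delta is empty.
  "MMTS" = .make_label("MMTS", elemental_composition(), channel = "other",
                       reversible = TRUE)
)

#' Van der Waals radii for SASA computation
#'
#' Embedded per-element radii (Angstrom) used by [gamma_s_sasa()].
#' @format Named numeric vector.
#' @export
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Spectrophotometric assay constants
#'
#' Extinction coefficients and the default optical path length used by the
#' kinetics module:
#' * `eps_nadh_340_380`: 4.81 mM^-1 cm^-1, dual-wavelength NADH (A340 - A380)
#' * `eps_tnb_412`: 13600 M^-1 cm^-1, TNB2- (citrate synthase/DTNB assay)
#' * `eps_h2o2_240`: 43.5 M^-1 cm^-1, hydrogen peroxide stock quantification
#' * `path_cm`: default 0.55 cm (200 uL in a 96-well plate), overridable
#'
#' @param path_cm optical path length in cm.
#' @return List of assay constants.
#' @export
assay_constants <- function(path_cm = 0.55) {
  stopifnot(is.numeric(path_cm), path_cm > 0)
  list(eps_nadh_340_380 = 4.81,    # mM^-1 cm^-1
       eps_tnb_412      = 13600,   # M^-1 cm^-1
       eps_h2o2_240     = 43.5,    # M^-1 cm^-1
       path_cm          = path_cm)
}
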