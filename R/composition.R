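# ElementalComposition: signed isotope-species counts with exact mass.

#' Create an elemental composition
#'
#' An `ElementalComposition` is a named integer vector of signed counts keyed
#' by isotope-species code (`"C"`, `"H"`, `"N"`, `"O"`, `"S"`, `"P"`, and the
#' fixed isotopes `"C13"`, `"H2"`). Addition and subtraction are element-wise;
#' the monoisotopic mass is the dot product with [ATOMIC_MASSES].
#'
#' @param counts named numeric vector of integer counts; may be empty.
#' @return An object of class `ElementalComposition`.
#' @examples
#' cam <- elemental_composition(c(C = 2, H = 3, N = 1, O = 1))
#' compose_mass(cam) # 57.02146, the carbamidomethyl delta
#' @seealso [compose_mass()], [parse_composition()]
#' @export
elemental_composition <- function(counts = numeric(0)) {
  if (length(counts) == 0) {
    counts <- stats::setNames(numeric(0), character(0))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("composition counts must be a named vector")
  }
  if (any(counts != round(counts))) stop("composition counts must be integers")
  unknown <- setdiff(names(counts), names(ATOMIC_MASSES))
  if (length(unknown) > 0) {
    stop("unknown isotope-species key(s): ", paste(unknown, collapse = ", "))
  }
  # merge duplicate keys, drop zeros
  counts <- tapply(counts, names(counts), sum)
  counts <- counts[counts != 0]
  structure(as.numeric(counts), names = names(counts),
            class = "ElementalComposition")
}

#' Parse a composition string
#'
#' Parses compact formulas such as `"C2 H3 N O"` or `"13C2 2H2 H N O"` into
#' an [elemental_composition()]. Isotope prefixes `13C` and `2H` map to the
#' carbon-13 and deuterium keys.
#'
#' @param text formula string; tokens are element symbols with optional
#'   leading mass number and trailing count.
#' @return An `ElementalComposition`.
#' @examples
#' compose_mass(parse_composition("13C2 2H2 H N O")) -
#'   compose_mass(parse_composition("C2 H3 N O")) # heavy-light IAM delta
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- regmatches(text, gregexpr("(13C|2H|[A-Z][a-z]?)([0-9]+)?",
                                      text))[[1]]
  if (length(tokens) == 0) return(elemental_composition())
  m <- regmatches(tokens, regexec("^(13C|2H|[A-Z][a-z]?)([0-9]+)?$", tokens))
  keys <- vapply(m, function(x) switch(x[2], "13C" = "C13", "2H" = "H2", x[2]),
                 character(1))
  n <- vapply(m, function(x) if (nzchar(x[3])) as.numeric(x[3]) else 1,
              numeric(1))
  elemental_composition(stats::setNames(n, keys))
}

#' @export
`+.ElementalComposition` <- function(e1, e2) {
  all_keys <- union(names(e1), names(e2))
  a <- stats::setNames(rep(0, length(all_keys)), all_keys)
  a[names(e1)] <- a[names(e1)] + unclass(e1)
  a[names(e2)] <- a[names(e2)] + unclass(e2)
  elemental_composition(a)
}

#' @export
`-.ElementalComposition` <- function(e1, e2) {
  if (missing(e2)) {
    return(elemental_composition(stats::setNames(-unclass(e1), names(e1))))
  }
  e1 + (-e2)
}

#' @export
print.ElementalComposition <- function(x, ...) {
  if (length(x) == 0) {
    cat("<empty composition>\n")
  } else {
    cat(paste0(names(x), unclass(x), collapse = " "),
        sprintf(" (%.5f Da)\n", compose_mass(x)))
  }
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Dot product of isotope counts with the embedded [ATOMIC_MASSES] table.
#' The empty composition has mass exactly 0; mass is linear in counts.
#'
#' @param composition an [elemental_composition()] (or a bare named vector).
#' @return Monoisotopic mass in Da.
#' @examples
#' compose_mass(parse_composition("C2 H3 N O")) # 57.02146
#' @export
compose_mass <- function(composition) {
  if (!inherits(composition, "ElementalComposition")) {
    composition <- elemental_composition(composition)
  }
  if (length(composition) == 0) return(0)
  sum(ATOMIC_MASSES[names(composition)] * unclass(composition))
}
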