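# Independent oracles used to freeze expected values. These deliberately do
# not share code paths with the package implementation.

# Monoisotopic atomic masses, re-stated from CODATA/NIST.
.orc_atom <- c(H = 1.0078250, C = 12, N = 14.0030740, O = 15.9949146,
               S = 31.9720707, P = 30.9737615)

# residue masses by direct summation of elemental formulas
.orc_res <- local({
  f <- list(
    G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),
    M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1))
  vapply(f, function(x) sum(.orc_atom[names(x)] * x), numeric(1))
})

# peptide neutral mass: residue sum + water + flat modification mass
orc_peptide_mass <- function(seq, mod_mass = 0) {
  sum(.orc_res[strsplit(seq, "")[[1]]]) + 18.0105646 + mod_mass
}

# brute-force tryptic digestion: enumerate all subsets of candidate cut
# sites and keep peptides whose internal skipped-cut count <= max_mc
orc_digest <- function(seq, max_mc) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n & aa[sites + 1] != "P"]
  bounds <- c(0, sites, n)
  res <- list()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:(length(bounds) - 1)) {
      mc <- j - i
      if (mc > max_mc) next
      s <- bounds[i] + 1
      e <- bounds[j + 1]
      res[[length(res) + 1]] <- data.frame(
        sequence = paste(aa[s:e], collapse = ""), start = s, end = e,
        missed_cleavages = mc)
    }
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$end), ]
}

# detectability oracle: independent re-statement of the four rules
orc_detectability <- function(protein, pos) {
  peps <- orc_digest(protein, 0)
  row <- peps[peps$start <= pos & peps$end >= pos, ]
  pep <- row$sequence
  ncys <- sum(strsplit(pep, "")[[1]] == "C")
  mass <- orc_peptide_mass(pep, mod_mass = ncys * 57.021464)
  mh2 <- (mass + 2 * 1.00728) / 2
  if (nchar(pep) < 7) "undetectable:length"
  else if (mh2 < 400) "undetectable:mz"
  else if (mass > 6000) "undetectable:mass"
  else if (ncys > 3) "undetectable:cys-count"
  else "detectable"
}

# random protein sequence; guaranteed to contain >= 1 cysteine
orc_random_protein <- function(n, alphabet = c(names(.orc_res))) {
  s <- sample(alphabet, n, replace = TRUE)
  if (!"C" %in% s) s[sample(n, 1)] <- "C"
  paste(s, collapse = "")
}
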