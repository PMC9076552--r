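# Mass arithmetic, digestion, fragments, transition lists.

test_that("compose_mass reproduces frozen oracle values", {
  expect_equal(compose_mass(parse_composition("C2 H3 N O")),
               2 * 12 + 3 * 1.0078250 + 14.0030740 + 15.9949146,
               tolerance = 1e-10)
  expect_equal(compose_mass(parse_composition("C2 H3 N O")), 57.02146,
               tolerance = 1e-5)
  expect_identical(compose_mass(elemental_composition()), 0)
  heavy <- compose_mass(parse_composition("13C2 2H2 H N O"))
  light <- compose_mass(parse_composition("C2 H3 N O"))
  expect_equal(heavy - light,
               2 * (13.0033548 - 12) + 2 * (2.0141018 - 1.0078250),
               tolerance = 1e-10)
  expect_equal(heavy - light, 4.01926, tolerance = 1e-5)
  expect_error(compose_mass(c(Xx = 1)), "Xx")
})

test_that("composition algebra is element-wise and commutative", {
  a <- parse_composition("C2 H3 N O")
  b <- parse_composition("13C2 2H2 H N O")
  expect_equal(compose_mass(a + b), compose_mass(b + a))
  expect_equal(compose_mass(a + b), compose_mass(a) + compose_mass(b))
  expect_equal(compose_mass(b - a), compose_mass(b) - compose_mass(a))
  expect_equal(unclass(a - a), stats::setNames(numeric(0), character(0)),
               ignore_attr = TRUE)
})

test_that("peptide_mass matches residue-sum oracle and label additivity", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-5)
  # anchor back-calculated from the printed 2+ m/z of the light species
  expect_equal(peptide_mass("TSPYECGFDPMGSAR", c("6" = "IAM-light")),
               837.8480 * 2 - 2 * 1.00728, tolerance = 1e-3)
  d <- peptide_mass("TSPYECGFDPMGSAR", c("6" = "IAM-heavy")) -
    peptide_mass("TSPYECGFDPMGSAR", c("6" = "IAM-light"))
  expect_equal(d, 4.01926, tolerance = 1e-5)
  expect_error(peptide_mass("TSPYECGFDPMGSAR", c("1" = "IAM-light")),
               "non-cysteine")
  expect_error(peptide_mass("ABCZ"), "non-standard")
  expect_error(peptide_mass(""), "non-empty")
})

test_that("mass additivity holds for random sequences and labels", {
  set.seed(42)
  reg_labels <- c("IAM-light", "IAM-heavy", "NEM", "d5-NEM", "TPP-IAM",
                  "d15-TPP-IAM")
  deltas <- vapply(reg_labels,
                   function(l) compose_mass(label_registry()[[l]]$delta),
                   numeric(1))
  for (rep in 1:25) {
    seq <- orc_random_protein(sample(5:30, 1))
    cys <- which(strsplit(seq, "")[[1]] == "C")
    labs <- sample(reg_labels, length(cys), replace = TRUE)
    site_labels <- stats::setNames(labs, cys)
    expect_equal(peptide_mass(seq, site_labels),
                 peptide_mass(seq) + sum(deltas[labs]), tolerance = 1e-10)
    expect_equal(peptide_mass(seq), orc_peptide_mass(seq), tolerance = 1e-5)
  }
})

test_that("the eight printed reference m/z values are reproduced", {
  bov <- "TSPYECGFDPMGSAR"
  mou <- "ANPYECGFDPTSSAR"
  mzv <- function(seq, lab, z) {
    labeled_peptide(seq, stats::setNames(lab, which(
      strsplit(seq, "")[[1]] == "C")), z = z)$mz
  }
  expect_equal(mzv(bov, "IAM-light", 2), 837.8480, tolerance = 1e-3)
  expect_equal(mzv(bov, "IAM-heavy", 2), 839.8576, tolerance = 1e-3)
  expect_equal(mzv(bov, "NEM", 2), 871.8611, tolerance = 1e-3)
  expect_equal(mzv(bov, "d5-NEM", 2), 874.3768, tolerance = 1e-3)
  expect_equal(mzv(bov, "TPP-IAM", 3), 669.2883, tolerance = 1e-3)
  expect_equal(mzv(bov, "d15-TPP-IAM", 3), 674.3196, tolerance = 1e-3)
  expect_equal(mzv(mou, "IAM-light", 2), 836.3570, tolerance = 1e-3)
  expect_equal(mzv(mou, "IAM-heavy", 2), 838.3667, tolerance = 1e-3)
})

test_that("mz applies the protonation convention", {
  m <- 1234.567
  expect_equal(mz(m, 1) - m, 1.00728)
  expect_equal(mz(m, 2), (m + 2 * 1.00728) / 2)
  expect_error(mz(m, 0), "charge")
  expect_error(mz(m, 1.5), "charge")
})

test_that("digest applies the trypsin rule with proline suppression", {
  d0 <- digest("AKRPGK", 0)
  expect_equal(d0$sequence, c("AK", "RPGK"))
  expect_equal(d0$start, c(1, 3))
  expect_equal(d0$end, c(2, 6))
  d1 <- digest("KKK", 1)
  expect_setequal(paste(d1$sequence, d1$start),
                  c("K 1", "K 2", "K 3", "KK 1", "KK 2"))
  expect_error(digest(""), "non-empty")
})

test_that("digestion matches the enumeration oracle on random proteins", {
  set.seed(7)
  for (rep in 1:20) {
    seq <- orc_random_protein(sample(8:30, 1))
    mc <- sample(0:2, 1)
    got <- digest(seq, mc)
    want <- orc_digest(seq, mc)
    expect_equal(got$sequence, want$sequence)
    expect_equal(got$start, want$start)
    expect_equal(got$missed_cleavages, want$missed_cleavages)
    # partition property: 0-missed peptides tile the protein
    d0 <- digest(seq, 0)
    expect_identical(paste(d0$sequence, collapse = ""), seq)
    expect_true(all(d0$end - d0$start + 1 == nchar(d0$sequence)))
  }
})

test_that("fragment ions obey complementarity and include labels", {
  sp <- labeled_peptide("ANPYECGFDPTSSAR", c("6" = "IAM-light"), z = 2)
  # frozen oracle: residue sum of C-terminal 13 residues + CAM + water
  y13 <- (orc_peptide_mass("PYECGFDPTSSAR", 57.021464) + 2 * 1.00728) / 2
  expect_equal(fragment_mz(sp, "y", 13, 2), y13, tolerance = 1e-4)
  expect_equal(fragment_mz(sp, "y", 13, 2), 743.82, tolerance = 0.01)
  L <- nchar(sp$sequence)
  for (n in 1:(L - 1)) {
    lhs <- fragment_mz(sp, "y", n, 1) + fragment_mz(sp, "b", L - n, 1)
    expect_equal(lhs, sp$neutral_mass + 2 * 1.00728, tolerance = 1e-9)
  }
  # label only counted when the labeled residue is inside the fragment
  expect_equal(fragment_mz(sp, "b", 5, 1),
               (orc_peptide_mass("ANPYE") - 18.0105646) + 1.00728,
               tolerance = 1e-4)
  expect_error(fragment_mz(sp, "y", L, 1), "fragment index")
  expect_error(fragment_mz(sp, "y", 0, 1), "fragment index")
})

test_that("transition_list builds computed channel rows", {
  tl <- transition_list("ANPYECGFDPTSSAR",
                        c("IAM-light", "IAM-heavy"), 2,
                        list(series = "y", n = 13, z = 2))
  expect_equal(nrow(tl), 2)
  expect_named(tl, c("species", "label", "z", "precursor_mz", "product_mz"))
  expect_equal(diff(tl$precursor_mz), 4.01926 / 2, tolerance = 1e-5)
  expect_equal(diff(tl$product_mz), 4.01926 / 2, tolerance = 1e-5)
  expect_equal(nrow(transition_list("ACR", character(0), 2,
                                    list(series = "y", n = 2, z = 1))), 0)
})
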