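# Conservation mapping, detectability, SASA, exposure-state classification,
# survey summary.

test_that("map_conserved_cysteines handles conservation and gaps", {
  aln <- c(mouse = "AAAAC", human = "AAAAC", carp = "AAAAC")
  r <- map_conserved_cysteines(aln, "mouse")
  expect_equal(r$position, 5)
  expect_true(r$conserved)
  aln2 <- c(mouse = "AAAAC", human = "AAAAC", carp = "AAAAS")
  expect_false(map_conserved_cysteines(aln2, "mouse")$conserved)
  # gapped reference: ungapped positions
  aln3 <- c(ref = "AC-CG", sp2 = "ACCCG")
  r3 <- map_conserved_cysteines(aln3, "ref")
  expect_equal(r3$position, c(2, 3))
  expect_equal(r3$column, c(2, 4))
  expect_true(all(r3$conserved))
  expect_error(map_conserved_cysteines(aln, "rat"), "reference")
  expect_error(map_conserved_cysteines(c(a = "AC", b = "ACC"), "a"),
               "ragged")
})

test_that("classify_detectability applies the four rules in order", {
  # tryptic peptide ACK has length 3
  r <- classify_detectability("ACKGGGGGGR", 2)
  expect_equal(r$class, "undetectable:length")
  # >3 cysteines in the peptide
  r2 <- classify_detectability("ACCGGCGCGGR", 2)
  expect_equal(r2$n_cys, 4)
  expect_equal(r2$class, "undetectable:cys-count")
  # the reference peptide is detectable; MH2+ matches the printed table
  r3 <- classify_detectability("ANPYECGFDPTSSAR", 6)
  expect_equal(r3$class, "detectable")
  expect_equal(r3$mh2, 836.3570, tolerance = 1e-3)
  expect_false(r3$multi_cys)
  expect_error(classify_detectability("ANPYECGFDPTSSAR", 1), "not a cysteine")
})

test_that("detectability agrees with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:10) {
    prot <- orc_random_protein(200)
    cys <- which(strsplit(prot, "")[[1]] == "C")
    for (pos in cys) {
      expect_equal(classify_detectability(prot, pos)$class,
                   orc_detectability(prot, pos),
                   info = paste(substr(prot, 1, 20), pos))
    }
  }
})

test_that("gamma_s_sasa matches the closed form and burial geometry", {
  lone <- data.frame(serial = 1, atom_name = "SG", resname = "CYS",
                     chain = "A", resid = 1, x = 0, y = 0, z = 0,
                     element = "S")
  closed <- 4 * pi * (1.80 + 1.40)^2
  expect_equal(gamma_s_sasa(lone, n_sphere_points = 960)$sasa, closed,
               tolerance = 0.01)
  expect_equal(gamma_s_sasa(lone, n_sphere_points = 2000)$sasa, closed,
               tolerance = 0.005)
  # fully caged sulfur -> 0
  cage <- gen_toy_complex(cys = data.frame(position = 10, conserved = TRUE,
                                           buried_active = TRUE,
                                           buried_deactive = TRUE))
  s <- gamma_s_sasa(cage$atoms_active)
  expect_equal(s$sasa, 0)
  # two identical S atoms at symmetric positions get equal SASA
  pair <- data.frame(serial = 1:3,
                     atom_name = c("SG", "C", "SG"),
                     resname = c("CYS", "DUM", "CYS"), chain = "A",
                     resid = 1:3, x = c(-3, 0, 3), y = 0, z = 0,
                     element = c("S", "C", "S"))
  sp <- gamma_s_sasa(pair)
  expect_equal(sp$sasa[1], sp$sasa[2], tolerance = 1e-9)
  expect_true(all(sp$sasa < closed))
  # no cysteine sulfur -> empty result
  expect_equal(nrow(gamma_s_sasa(pair[2, , drop = FALSE])), 0)
})

test_that("classify_exposure_states applies the strict 5 A^2 cutoff", {
  r <- classify_exposure_states(2, 30)
  expect_equal(r$active, "occluded")
  expect_equal(r$deactive, "exposed")
  expect_true(r$candidate)
  expect_false(classify_exposure_states(12, 14)$candidate)
  # boundary is strictly greater
  r3 <- classify_exposure_states(4.9, 5.0)
  expect_equal(r3$active, "occluded")
  expect_equal(r3$deactive, "occluded")
  # unmodeled deactive counts as exposed (disordered-loop convention)
  r4 <- classify_exposure_states(2, NA)
  expect_equal(r4$deactive, "unmodeled-exposed")
  expect_true(r4$candidate)
})

test_that("engineered toy-complex cysteines are classified with zero error", {
  cys <- data.frame(position = c(10, 22, 34, 46),
                    conserved = c(TRUE, TRUE, TRUE, FALSE),
                    buried_active = c(TRUE, FALSE, TRUE, FALSE),
                    buried_deactive = c(FALSE, FALSE, TRUE, FALSE))
  toy <- gen_toy_complex(n_species = 4, length_aa = 60, cys = cys, seed = 5)
  sasa_of <- function(atoms) {
    s <- gamma_s_sasa(atoms)
    stats::setNames(s$sasa, as.character(s$resid))
  }
  recs <- cysteine_survey(toy$alignment, "species1",
                          sasa_active = sasa_of(toy$atoms_active),
                          sasa_deactive = sasa_of(toy$atoms_deactive),
                          annotations = toy$annotations)
  recs <- recs[order(recs$position), ]
  expect_equal(recs$position, cys$position)
  expect_equal(recs$conserved, cys$conserved)
  want_candidate <- cys$buried_active & !cys$buried_deactive
  expect_equal(recs$candidate, want_candidate)
  expect_equal(recs$state_active == "occluded", cys$buried_active)
  expect_equal(recs$state_deactive == "occluded", cys$buried_deactive)
})

test_that("survey_summary percentages are self-consistent count ratios", {
  # the printed cascade fed as explicit counts
  s <- survey_summary(list(total = 116, conserved = 114, quantified = 43,
                           no_data = 62, fes_no_data = 19,
                           disulfide_no_data = 18,
                           undetectable_no_data = 32, candidates = 71,
                           fes_or_disulfide_candidates = 44))
  expect_equal(s$pct_quantified, 37.7)
  expect_equal(s$pct_undetectable_no_data, 51.6)
  expect_equal(s$pct_candidates, 62.3)
  expect_equal(s$pct_disulfide_no_data, 29.0)
  expect_equal(s$pct_fes_or_disulfide_candidates, 62.0)
  # self-consistency on random counts
  set.seed(12)
  for (rep in 1:20) {
    cons <- sample(10:200, 1)
    q <- sample(0:cons, 1)
    nod <- cons - q
    cnt <- list(total = cons + 2, conserved = cons, quantified = q,
                no_data = nod, fes_no_data = sample(0:nod, 1),
                disulfide_no_data = sample(0:nod, 1),
                undetectable_no_data = sample(0:nod, 1), candidates = nod,
                fes_or_disulfide_candidates = sample(0:nod, 1))
    ss <- survey_summary(cnt)
    expect_equal(ss$pct_quantified, round2 <- floor(100 * q / cons * 10 + 0.5) / 10)
    if (nod > 0) {
      expect_equal(ss$pct_fes_no_data,
                   floor(100 * cnt$fes_no_data / nod * 10 + 0.5) / 10)
    }
  }
  # empty record set: zero counts, undefined percentages
  s0 <- survey_summary(data.frame())
  expect_equal(s0$total, 0)
  expect_true(is.na(s0$pct_quantified))
})

test_that("survey records aggregate into a summary", {
  cys <- data.frame(position = c(10, 22, 34, 46),
                    conserved = c(TRUE, TRUE, TRUE, FALSE),
                    buried_active = c(TRUE, FALSE, TRUE, FALSE),
                    buried_deactive = c(FALSE, FALSE, TRUE, FALSE),
                    annotation = c("none", "FeS-ligand", "none", "none"))
  toy <- gen_toy_complex(n_species = 3, length_aa = 60, cys = cys, seed = 8)
  recs <- cysteine_survey(toy$alignment, "species1",
                          annotations = toy$annotations,
                          quantified = c(10))
  s <- survey_summary(recs)
  expect_equal(s$total, 4)
  expect_equal(s$conserved, 3)
  expect_equal(s$quantified, 1)
  expect_equal(s$no_data, 2)
  expect_equal(s$fes_no_data, 1)
  expect_equal(s$pct_quantified, 33.3)
})
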