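# Tryptic digestion, peptide masses, emPAI, filters, summaries.

test_that("tryptic digestion cleaves after K/R except before proline", {
  expect_setequal(tryptic_digest("AKRPGKMR", 0), c("AK", "RPGK", "MR"))
  expect_equal(tryptic_digest("MR", 0), "MR")
  expect_setequal(tryptic_digest("AKRPGKMR", 1),
                  c("AK", "RPGK", "MR", "AKRPGK", "RPGKMR"))
  expect_equal(tryptic_digest("AKRPGKMR", 2),
               unique(c(tryptic_digest("AKRPGKMR", 1), "AKRPGKMR")))
  expect_error(tryptic_digest("ABX"), "position 2")
})

test_that("peptide masses are monoisotopic with carbamidomethyl cysteine", {
  expect_equal(peptide_mass("GK"), 57.02146 + 128.09496 + 18.010565,
               tolerance = 1e-6)
  expect_equal(peptide_mass("C") - peptide_mass("A"),
               103.00919 + 57.02146 - 71.03711, tolerance = 1e-6)
})

test_that("observable peptides respect the instrument mass window", {
  # GK (~203 Da) falls below the default window
  expect_equal(observable_peptides("GKGK"), 0L)
  sq <- "MAGWINSTEKLLVDYPEILTRVVGGGGKFFYTWDNMMR"
  expect_equal(observable_peptides(sq, mass_window = c(0, Inf)),
               length(tryptic_digest(sq, 0)))
  # no internal K/R: the whole chain is the single peptide
  expect_equal(observable_peptides("MAGWINSTE", c(0, Inf)), 1L)
  win <- default_mass_window()
  expect_equal(win[1], 375 * 2 - 2 * 1.007276, tolerance = 1e-6)
  expect_equal(win[2], 1500 * 5 - 5 * 1.007276, tolerance = 1e-6)
})

test_that("emPAI is the exponentially modified coverage ratio", {
  expect_equal(empai(4, 20), 10^0.2 - 1)
  expect_equal(empai(0, 10), 0)
  expect_equal(empai(10, 10), 9)
  expect_warning(got <- empai(11, 10), "capping")
  expect_equal(got, 9)
  expect_error(empai(1, 0), "observable")
  # monotone: increasing observed raises it, increasing observable lowers it
  obs <- empai(1:10, 10)
  expect_true(all(diff(obs) > 0))
  den <- empai(5, 5:20)
  expect_true(all(diff(den) < 0))
})

test_that("identification filters drop weak matches then sparse proteins", {
  filt <- filter_identifications(toy_evidence())
  expect_true(all(filt$matches$expect <= 0.05))
  # P1 keeps 2 peptides; P2 has 1 -> dropped; P3 has 1 per sample -> dropped
  expect_setequal(unique(filt$matches$protein_id), "P1")
  expect_false(filt$retention$retained[filt$retention$protein_id == "P2"])
  # empty in, empty out
  empty <- filter_identifications(toy_evidence()[0, ])
  expect_equal(nrow(empty$retention), 0)
  # idempotence
  again <- filter_identifications(filt$matches)
  expect_equal(again$matches, filt$matches)
})

test_that("the 'any sample' scope keeps a protein everywhere once qualified", {
  ev <- rbind(toy_evidence(),
              data.frame(protein_id = "P3", peptide = "GGGK", expect = 0.01,
                         sample = "s2", compartment = "gut_fluid",
                         replicate = 2L))
  any_scope <- filter_identifications(ev, scope = "any sample")
  expect_true("s1" %in% any_scope$matches$sample[any_scope$matches$protein_id == "P3"])
  per_scope <- filter_identifications(ev, scope = "per sample")
  expect_false("s1" %in% per_scope$matches$sample[per_scope$matches$protein_id == "P3"])
  expect_true("s2" %in% per_scope$matches$sample[per_scope$matches$protein_id == "P3"])
})

test_that("molar percentages are emPAI shares within each group", {
  q <- data.frame(protein_id = c("A", "B"), compartment = "gut_fluid",
                  replicate = 1L, empai = c(1, 3))
  mol <- molar_percentages(q)
  expect_equal(mol$mol_percent, c(25, 75))
  q1 <- data.frame(protein_id = "A", compartment = "x", replicate = 1L,
                   empai = 2)
  expect_equal(molar_percentages(q1)$mol_percent, 100)
  qn <- data.frame(protein_id = letters[1:5], compartment = "x",
                   replicate = 1L, empai = rep(0.37, 5))
  expect_equal(molar_percentages(qn)$mol_percent, rep(20, 5))
  # zero-sum group flagged and excluded
  qz <- rbind(q, data.frame(protein_id = "C", compartment = "gut_fluid",
                            replicate = 2L, empai = 0))
  mz <- molar_percentages(qz)
  expect_equal(attr(mz, "dropped_groups"), "gut_fluid 2")
})

test_that("replicate normalization equalizes cross-organ totals", {
  q <- data.frame(replicate = rep(1:3, each = 2),
                  compartment = rep(c("gut", "hp"), 3),
                  empai = c(30, 50, 40, 60, 70, 50))   # totals 80, 100, 120
  norm <- normalize_replicates(q, organs = c("gut", "hp"))
  totals <- tapply(norm$empai, norm$replicate, sum)
  expect_equal(as.numeric(totals), rep(100, 3))
  # identical replicates unchanged
  qe <- data.frame(replicate = rep(1:2, each = 2),
                   compartment = rep(c("gut", "hp"), 2), empai = c(1, 2, 1, 2))
  expect_equal(normalize_replicates(qe)$empai, qe$empai)
  # scaling one replicate's raw data leaves the normalized *profile*
  # unchanged: outputs agree up to a single global factor (the mean total),
  # so all downstream molar percentages are identical
  qs <- qe; qs$empai[qs$replicate == 2] <- 2 * qs$empai[qs$replicate == 2]
  ratio <- normalize_replicates(qs)$empai / normalize_replicates(qe)$empai
  expect_equal(ratio, rep(ratio[1], length(ratio)))
  expect_equal(molar_percentages(normalize_replicates(qs))$mol_percent,
               molar_percentages(normalize_replicates(qe))$mol_percent)
  qm <- qe[-4, ]
  expect_error(normalize_replicates(qm, organs = c("gut", "hp")), "missing")
})

test_that("family shares renormalize within the GH subset", {
  q <- data.frame(protein_id = c("a", "b", "c"), compartment = "gut_fluid",
                  replicate = 1L, mol_percent = c(30, 25, 45))
  ann <- c(a = "GH7", b = "GH9", c = "GH5")
  fam <- family_summary(q, ann)
  gh79 <- sum(fam$gh_shares$share_percent[fam$gh_shares$family %in%
                                            c("GH7", "GH9")])
  expect_equal(gh79, 55)
  expect_gt(gh79, 50)
  one <- family_summary(data.frame(protein_id = "a", compartment = "x",
                                   replicate = 1L, mol_percent = 100),
                        c(a = "GH7"))
  expect_equal(one$gh_shares$share_percent, 100)
  none <- family_summary(q, c(a = "other", b = "other", c = "hemocyanin"))
  expect_true(none$empty)
})

test_that("mol% sums to 100 within every group after every transformation", {
  ev <- gen_proteome_evidence(digestome_preset(seed = 21))
  filt <- filter_identifications(ev$evidence)
  q <- empai_quantify(filt$matches, ev$fasta)
  qn <- normalize_replicates(q, organs = unique(q$compartment))
  for (tab in list(molar_percentages(q), molar_percentages(qn))) {
    sums <- tapply(tab$mol_percent, paste(tab$compartment, tab$replicate), sum)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-6)
  }
})

test_that("hemocyanin is enriched in gut fluids relative to tissue", {
  pre <- digestome_preset(seed = 31)
  ev <- gen_proteome_evidence(pre)
  filt <- filter_identifications(ev$evidence)
  mol <- molar_percentages(empai_quantify(filt$matches, ev$fasta))
  fam <- family_summary(mol, preset_annotations(pre))
  hc <- fam$hemocyanin
  expect_gt(hc$mean[hc$compartment == "gut_fluid"],
            hc$mean[hc$compartment == "gut_tissue"])
})
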