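test_that("RSCU matches a brute-force recount and normalises per family", {
  orf <- orfeome(c(g1 = "AAAAAAAAAAAG"))  # Lys: AAA x3, AAG x1
  r <- rscu(orf)
  expect_equal(r$weight[r$codon == "AAA"], 1.5)
  expect_equal(r$weight[r$codon == "AAG"], 0.5)

  withr::with_seed(21, {
    orf2 <- orfeome(setNames(vapply(1:15, function(i) random_cds(40),
                                    character(1)), paste0("g", 1:15)))
  })
  counts <- codon_usage(orf2)
  r2 <- rscu(orf2)
  expect_equal(setNames(r2$weight, r2$codon)[names(counts)],
               ref_rscu(counts))
  # family mean 1 (equivalently sum = k) for every present amino acid
  fam_means <- tapply(r2$weight[r2$count > 0 | TRUE], r2$aa, mean)
  present <- setdiff(unique(r2$aa[r2$count > 0]), NULL)
  expect_true(all(abs(fam_means[present] - 1) < 1e-12))
})

test_that("uniform codon usage gives RSCU 1 and absent families are flagged", {
  # one of each Phe codon -> uniform family
  orf <- orfeome(c(g = "TTTTTC"))
  r <- rscu(orf)
  expect_equal(r$weight[r$aa == "F"], c(1, 1))
  expect_true("K" %in% attr(r, "flagged_aa"))
  expect_equal(r$weight[r$aa == "K"], c(1, 1))
})

test_that("CAI weights are RSCU scaled to the family maximum", {
  orf <- orfeome(c(g1 = "AAAAAAAAAAAG"))
  w <- cai_weights(orf)
  expect_equal(w$weight[w$codon == "AAA"], 1)
  expect_equal(w$weight[w$codon == "AAG"], 1 / 3)
  withr::with_seed(22, {
    orf2 <- orfeome(setNames(vapply(1:10, function(i) random_cds(50),
                                    character(1)), paste0("g", 1:10)))
  })
  w2 <- cai_weights(orf2)
  # every family max is exactly 1 and weights stay in [0, 1]
  expect_true(all(tapply(w2$weight, w2$aa, max) == 1))
  expect_true(all(w2$weight >= 0 & w2$weight <= 1))
})

test_that("tAI weights agree exactly with an independent reference", {
  pool <- tibble::tibble(
    anticodon = c("AGC", "GGC", "AAC", "GAC", "TTC", "CAT",
                  "GAA", "TGA", "GCT", "CCA"),
    tgcn = c(2, 1, 3, 1, 2, 4, 1, 2, 1, 1))
  mine <- tai_weights(pool, s = s_prokaryote, sking = 1)
  ref <- ref_tai(pool, s_prokaryote, sking = 1)
  lut <- setNames(mine$weight, mine$codon)
  expect_equal(lut[names(ref)], ref, tolerance = 1e-12)
  expect_true(all(mine$weight > 0 & mine$weight <= 1))
  expect_true(all(mine$weight[mine$codon != "ATG"] ==
                    unname(ref[mine$codon[mine$codon != "ATG"]])))
})

test_that("tAI normalisation and zero-coverage fill behave as defined", {
  # single perfect-match anticodon: its codon has the maximal weight 1
  pool <- tibble::tibble(anticodon = "AGC", tgcn = 1)  # reads GCT (Ala)
  w <- tai_weights(pool)
  lut <- setNames(w$weight, w$codon)
  expect_equal(unname(lut["GCT"]), 1)
  # uncovered codons share the geometric mean of the nonzero weights
  # (GCT by Watson-Crick, GCC by wobble, GCA faintly via the I:A pair,
  # ATA via the bacterial lysidine route under sking = 1)
  covered <- c("GCT", "GCC", "GCA", "ATA")
  gm <- exp(mean(log(lut[covered])))
  expect_equal(unname(lut["TTT"]), unname(gm), tolerance = 1e-12)
  # with sking = 0 an empty pool covers nothing at all
  expect_error(tai_weights(tibble::tibble(anticodon = character(),
                                          tgcn = numeric()), sking = 0),
               "empty tRNA pool")
})

test_that("unpaired-probability tables aggregate bases into codons", {
  path <- withr::local_tempfile(fileext = ".lunp")
  writeLines(c("#unpaired probabilities",
               " #i$\tl=1",
               paste(1:6, c(0.2, 0.4, 0.6, 1.0, 1.0, 1.0), sep = "\t")),
             path)
  up <- read_unpaired_probabilities(path)
  expect_equal(up$base$unpaired, c(0.2, 0.4, 0.6, 1, 1, 1))
  expect_equal(up$codon$unpaired, c(0.4, 1))
  expect_equal(up$codon$structure, c(0.6, 0))
  expect_equal(up$base$unpaired + (1 - up$base$unpaired), rep(1, 6))
})

test_that("span-averaging modes differ as documented and inputs are checked", {
  path <- withr::local_tempfile(fileext = ".lunp")
  writeLines(c("#unpaired probabilities", " #i$\tl=1\t2",
               "1\t0.8\tNA", "2\t0.6\t0.4", "3\t0.2\t0.6"), path)
  ending <- read_unpaired_probabilities(path, mode = "ending")
  containing <- read_unpaired_probabilities(path, mode = "containing")
  expect_equal(ending$base$unpaired, c(0.8, 0.5, 0.4))
  # base 1: spans (1,l1), (2,l2); base 2: (2,l1), (2,l2), (3,l2); base 3: (3,l1), (3,l2)
  expect_equal(containing$base$unpaired,
               c(mean(c(0.8, 0.4)), mean(c(0.6, 0.4, 0.6)),
                 mean(c(0.2, 0.6))))
  bad <- withr::local_tempfile(fileext = ".lunp")
  writeLines(c("#x", "1\t1.5"), bad)
  expect_error(read_unpaired_probabilities(bad), "\\[0,1\\]")
})

test_that("positional metric profiles delegate with the no-bias fallback", {
  orf <- qc_filter(orfeome(c(a = "ATGAAAGCG", b = "ATGAAGCTG")), 2)
  mat <- build_codon_matrix(orf)
  flat <- rscu(orf)
  flat$weight <- 1
  pf <- positional_metric(mat, flat, n_boot = 50, seed = 1)
  expect_equal(pf$mean, c(1, 1))
  cai <- positional_metric(mat, cai_weights(orf), n_boot = 50, seed = 1)
  expect_true(all(cai$mean > 0 & cai$mean <= 1))
  # single CDS: profile equals that CDS's weight sequence
  w <- cai_weights(orf)
  lut <- setNames(w$weight, w$codon)
  one <- positional_metric(mat[1, , drop = FALSE], w, n_boot = 10, seed = 1)
  expect_equal(one$mean, unname(lut[mat[1, ]]))
})
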