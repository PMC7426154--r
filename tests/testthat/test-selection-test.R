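test_that("synonymous shuffling preserves translation and codon multisets", {
  gc <- Biostrings::GENETIC_CODE
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(10:40, 1)
      cods <- substring(random_cds(n), 3 * seq_len(n) - 2, 3 * seq_len(n))
      shuf <- shuffle_synonymous(cods)
      expect_equal(unname(gc[shuf]), unname(gc[cods]))
      expect_equal(sort(shuf), sort(cods))
    }
  })
})

test_that("single-codon families and stop codons never move", {
  expect_equal(shuffle_synonymous(c("ATG", "TGG")), c("ATG", "TGG"))
  withr::with_seed(5, {
    cods <- c("TAA", "AAA", "TGA", "AAG", "TAG")
    for (i in 1:5) {
      shuf <- shuffle_synonymous(cods)
      expect_equal(shuf[c(1, 3, 5)], c("TAA", "TGA", "TAG"))
    }
  })
})

test_that("an invariant ORFeome yields a degenerate null", {
  orf <- qc_filter(orfeome(c(a = "ATGATGTGGATG", b = "ATGTGGATGTGG")), 3)
  null <- null_distribution(orf, n_sims = 50, seed = 1)
  expect_equal(null$sigma, rep(0, 3))
  mat <- build_codon_matrix(orf)
  sp <- selection_profile(mat, null)
  expect_equal(sp$z_sq, rep(0, 3))
  expect_true(all(sp$sigma_zero))
})

test_that("the null is seeded and matches enumeration for a single Lys pair", {
  orf <- qc_filter(orfeome(c(a = "ATGAAAAAG")), 2)
  n1 <- null_distribution(orf, n_sims = 400, seed = 3)
  n2 <- null_distribution(orf, n_sims = 400, seed = 3)
  expect_identical(n1, n2)
  # exact null: permutations {AAA,AAG} and {AAG,AAA}, E = 6.5 per position
  expect_equal(n1$E, c(6.5, 6.5), tolerance = 0.05)
  expect_equal(n1$sigma, c(0.5, 0.5), tolerance = 0.05)
})

test_that("Monte-Carlo null converges to the fully enumerated null", {
  # two CDSs: one with Lys x3 (AAA,AAA,AAG), one with Phe x2 + Leu pair
  orf <- qc_filter(orfeome(c(
    a = paste0("ATG", "AAA", "AAA", "AAG"),
    b = paste0("ATG", "TTT", "TTC", "TTA")
  )), 3)
  # brute force: enumerate all within-family arrangements of each CDS
  perms_a <- unique(combinat_perms(c("AAA", "AAA", "AAG")))
  perms_b <- lapply(combinat_perms(c("TTT", "TTC")), function(p) {
    c(p, "TTA")  # Leu codon is alone in its family here: fixed
  })
  totals <- NULL
  for (pa in perms_a) for (pb in perms_b) {
    totals <- rbind(totals, hbond_count(pa) + hbond_count(pb))
  }
  exact_E <- colMeans(totals)
  exact_sd <- apply(totals, 2, function(v) sqrt(mean((v - mean(v))^2)))
  mc <- null_distribution(orf, n_sims = 200, seed = 11)
  # Monte-Carlo error bounds: 4 sigma for E, generous relative band for sigma
  se_E <- exact_sd / sqrt(200)
  expect_true(all(abs(mc$E - exact_E) <= 4 * se_E + 1e-9))
  expect_true(all(abs(mc$sigma - exact_sd) <= 0.35 * exact_sd + 1e-9))
})

test_that("selection statistics implement the z-squared and chi-gram forms", {
  orf <- qc_filter(orfeome(c(a = "ATGTTAGCGAAA", b = "ATGTTAGCGAAA")), 3)
  mat <- build_codon_matrix(orf)
  # O per position: 2*6, 2*9, 2*6 = (12, 18, 12); craft a null around it
  null <- tibble::tibble(position = 2:4, E = c(10, 20, 12),
                         sigma = c(2, 1, 0))
  class(null) <- c("hb_null", class(null))
  sp <- selection_profile(mat, null)
  expect_equal(sp$O, c(12, 18, 12))
  expect_equal(sp$z_sq, c(1, 4, 0))        # ((12-10)/2)^2, ((18-20)/1)^2, flagged
  expect_equal(sp$chigram, c(0.2, -0.1, 0))
  expect_equal(attr(sp, "chi_sq_total"), 5)
  # min-max normalisation attains 0 and 1
  expect_equal(sp$normalized_z_sq, c(0.25, 1, 0))
  sp2 <- selection_profile(mat, null, chigram_denominator = "sqrtE")
  expect_equal(sp2$chigram, c(2 / sqrt(10), -2 / sqrt(20), 0))
  # scaled chi-gram is centered and scaled
  expect_equal(mean(sp$scaled_chigram), 0, tolerance = 1e-12)
  expect_equal(sd(sp$scaled_chigram), 1, tolerance = 1e-12)
})

test_that("min-max normalisation maps a z-squared triple to (0, 0.5, 1)", {
  z <- c(2, 4, 6)
  rng <- range(z)
  expect_equal((z - rng[1]) / diff(rng), c(0, 0.5, 1))
})

test_that("ramp_of_selection summarises the 5' region against the rest", {
  withr::with_seed(41, {
    orf <- orfeome(setNames(vapply(1:60, function(i) random_cds(30),
                                   character(1)), paste0("g", 1:60)))
  })
  orf <- qc_filter(orf, 25)
  null <- null_distribution(orf, n_sims = 100, seed = 2)
  sp <- selection_profile(build_codon_matrix(orf), null)
  rs <- ramp_of_selection(sp)
  expect_equal(rs$sign_5prime, sign(rs$mean_chigram_5prime))
  expect_error(ramp_of_selection(sp[1:10, ]), "too short")
})

test_that("whole-ORFeome shuffling is reproducible and synonymous", {
  withr::with_seed(51, {
    orf <- orfeome(setNames(vapply(1:5, function(i) random_cds(20),
                                   character(1)), paste0("g", 1:5)))
  })
  s1 <- shuffle_orfeome(orf, seed = 9)
  s2 <- shuffle_orfeome(orf, seed = 9)
  expect_identical(s1$seq, s2$seq)
  translate <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAStringSet(s)))
  }
  expect_equal(translate(s1$seq), translate(orf$seq))
})
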