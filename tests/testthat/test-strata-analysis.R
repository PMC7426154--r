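make_grouped_orfeome <- function(n_per_group = 60, delta = 0.4, seed = 71) {
  # group "lo" generated with a 5' target delta bonds/codon below group "hi"
  hi <- generate_orfeome(generator_spec(
    n_cds = n_per_group, length_codons = 41, flat_mu = 7.6, seed = seed))
  lo <- generate_orfeome(generator_spec(
    n_cds = n_per_group, length_codons = 41, flat_mu = 7.6 - delta,
    seed = seed + 1))
  lo$cds_id <- sub("cds_", "lo_", lo$cds_id)
  hi$cds_id <- sub("cds_", "hi_", hi$cds_id)
  orf <- dplyr::bind_rows(hi, lo)
  attr(orf, "provenance") <- "synthetic"
  orf
}

test_that("operon comparison detects an implanted first-gene deficit", {
  orf <- qc_filter(make_grouped_orfeome(200, delta = 0.5), 40)
  mat <- build_codon_matrix(orf)
  operons <- tibble::tibble(
    cds_id = orf$cds_id,
    operon_id = sprintf("op_%03d", rep(seq_len(200), 2)),
    position = rep(c(2L, 1L), each = 200))  # "lo_*" CDSs sit at position 1
  rep <- operon_comparison(mat, operons, orf = orf)
  win <- rep[rep$region == "window" & rep$test == "wilcoxon", ]
  expect_lt(win$p_adjusted, 0.001)
  kw <- rep[rep$region == "window" & rep$test == "kruskal_wallis", ]
  expect_lt(kw$p_value, 0.001)
  # direction: group 1 (lo) below group 2 (hi)
  g1 <- .rowMeans(matrix(hbond_count(as.vector(
    mat[grepl("^lo_", rownames(mat)), ])), nrow = 200), 200, 40)
  g2 <- .rowMeans(matrix(hbond_count(as.vector(
    mat[grepl("^hi_", rownames(mat)), ])), nrow = 200), 200, 40)
  expect_lt(median(g1), median(g2))
})

test_that("identical operon groups are not called different", {
  withr::with_seed(72, {
    orf <- orfeome(setNames(vapply(1:40, function(i) random_cds(25),
                                   character(1)), paste0("g", 1:40)))
  })
  orf <- qc_filter(orf, 20)
  mat <- build_codon_matrix(orf)
  # the same 40 CDSs serve as both position-1 and position-2 members
  operons <- tibble::tibble(
    cds_id = rep(orf$cds_id, 2),
    operon_id = paste0("op", c(seq_len(40), seq_len(40))),
    position = rep(1:2, each = 40))
  rep <- operon_comparison(mat, operons)
  expect_true(all(rep$p_value[rep$test == "wilcoxon"] > 0.9))
  expect_error(
    operon_comparison(mat, tibble::tibble(cds_id = "missing",
                                          operon_id = "op1", position = 1)),
    "missing")
})

test_that("BY adjustment never decreases p-values and keeps their order", {
  p <- c(0.001, 0.01, 0.02, 0.2, 0.5)
  adj <- p.adjust(p, method = "BY")
  expect_true(all(adj >= p))
  expect_true(all(diff(adj) >= 0))
})

test_that("expression strata intersect ranked sets across experiments", {
  expr <- tibble::tibble(
    cds_id = rep(c("a", "b", "c", "d"), 2),
    experiment = rep(c("e1", "e2"), each = 4),
    rpkm = c(40, 30, 20, 10, 41, 31, 21, 11))
  st <- expression_strata(expr, high_pct = 50, low_pct = 50)
  expect_setequal(st$high, c("a", "b"))
  expect_setequal(st$low, c("c", "d"))
  # reversed rankings empty the intersection
  expr2 <- expr
  expr2$rpkm[5:8] <- rev(expr2$rpkm[5:8])
  expect_warning(st2 <- expression_strata(expr2, 25, 25), "empty")
  expect_length(st2$high, 0)
  # a single experiment reduces to a quantile cut
  one <- expr[expr$experiment == "e1", ]
  st3 <- expression_strata(one, 25, 25)
  expect_equal(st3$high, "a")
  expect_equal(st3$low, "d")
})

test_that("stratum size is non-increasing in the number of experiments", {
  withr::with_seed(73, {
    orf <- generate_orfeome(generator_spec(n_cds = 100, length_codons = 22,
                                           flat_mu = 7.5, seed = 73))
    expr <- generate_expression(orf, n_experiments = 6, noise_sd = 1,
                                seed = 73)
  })
  sizes <- vapply(1:6, function(k) {
    sub <- expr[expr$experiment %in% sprintf("exp_%02d", 1:k), ]
    length(expression_strata(sub, 30, 30)$high)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("strata profiles smooth per group and separate implanted strata", {
  orf <- qc_filter(make_grouped_orfeome(80, delta = 0.4, seed = 74), 40)
  mat <- build_codon_matrix(orf)
  groups <- list(high = grep("^lo_", orf$cds_id, value = TRUE),
                 low = grep("^hi_", orf$cds_id, value = TRUE))
  sp <- strata_profiles(mat, groups, n_boot = 100, seed = 1)
  hi_curve <- sp$smoothed[sp$group == "high"]
  lo_curve <- sp$smoothed[sp$group == "low"]
  expect_true(all(hi_curve < lo_curve))  # 0.4 bonds/codon separation
  # identical groups give identical smooths
  same <- strata_profiles(mat, list(a = groups$high, b = groups$high),
                          n_boot = 100, seed = 1)
  expect_equal(same$smoothed[same$group == "a"],
               same$smoothed[same$group == "b"])
  expect_error(strata_profiles(mat, list(tiny = orf$cds_id[1])), "fewer")
})

test_that("LOESS on constant data returns a constant curve", {
  orf <- qc_filter(orfeome(c(a = paste0("ATG", strrep("AAA", 30)),
                             b = paste0("ATG", strrep("AAA", 30)))), 30)
  mat <- build_codon_matrix(orf)
  sp <- strata_profiles(mat, list(g = c("a", "b")), n_boot = 20, seed = 1)
  expect_equal(sp$smoothed, rep(6, 30), tolerance = 1e-9)
})

test_that("correlation networks recover perfect and null associations", {
  base <- tibble::tibble(position = 2:101,
                         mean = seq(7, 7.9, length.out = 100))
  neg <- base
  neg$mean <- -base$mean
  net <- metric_correlation_network(
    list(a = base, b = base, c = neg), method = "spearman")
  expect_equal(net$rho[net$from == "a" & net$to == "b"], 1)
  expect_equal(net$rho[net$from == "a" & net$to == "c"], -1)
  expect_true(all(net$p_adjusted >= net$p_value - 1e-15))
  short <- base[1:2, ]
  expect_error(metric_correlation_network(list(a = short, b = short)),
               "3 shared")
  # independent random profiles rarely correlate strongly
  withr::with_seed(75, {
    hits <- vapply(1:40, function(i) {
      r1 <- tibble::tibble(position = 1:100, mean = rnorm(100))
      r2 <- tibble::tibble(position = 1:100, mean = rnorm(100))
      abs(metric_correlation_network(list(x = r1, y = r2))$rho)
    }, numeric(1))
  })
  expect_gte(mean(hits < 0.3), 0.95)
})

test_that("region correlations respect windows and rank invariance", {
  hb <- tibble::tibble(position = 2:121,
                       mean = bounded_exponential(0:119, 7.9, 0.25, 7))
  # structure profile as a monotone transform of the hbond profile
  struct <- hb
  struct$mean <- plogis(hb$mean - 7.4)
  rc <- region_correlation(hb, struct)
  expect_equal(rc$spearman, rep(1, 3))
  expect_equal(region_correlation(hb, hb)$pearson, rep(1, 3))
  expect_error(region_correlation(hb, struct, regions = list(c(2, 3))),
               "fewer than 3")
})
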