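#' Read an operon membership table from TSV
#'
#' @param path TSV with columns `cds_id`, `operon_id`, `position`
#'   (1-based position of the CDS within its operon).
#' @return tibble; operons with fewer than 2 CDSs are dropped.
#' @export
read_operon_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("cds_id", "operon_id", "position") %in% names(tb))) {
    stop("operon TSV needs columns cds_id, operon_id, position",
         call. = FALSE)
  }
  tb |>
    dplyr::group_by(.data$operon_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()
}

# per-CDS mean hbond over a set of matrix columns
.cds_region_means <- function(mat, cols) {
  vals <- matrix(hbond_count(as.vector(mat[, cols, drop = FALSE])),
                 nrow = nrow(mat))
  rowMeans(vals)
}

#' Compare hydrogen bonding by CDS position within operons
#'
#' Groups CDSs by their 1-based position within an operon (positions 1 to
#' `max_cds_position`) and compares per-CDS mean hydrogen-bond content
#' between groups in several regions: consecutive 20-codon windows across
#' the analysis window, the whole window, and (when the ORFeome is
#' supplied) the full CDS length. Pairwise two-sided unpaired Wilcoxon
#' rank-sum tests are adjusted with the Benjamini-Yekutieli procedure; a
#' Kruskal-Wallis test covers each region jointly.
#'
#' @param mat a `codon_matrix`.
#' @param operons operon table (see [read_operon_table()]); every `cds_id`
#'   must be a matrix row.
#' @param max_cds_position deepest operon position to keep as its own
#'   group (default 3).
#' @param orf optional QC-filtered ORFeome tibble, enabling the
#'   "full_length" region.
#' @return a tibble of class `operon_comparison` with one row per test:
#'   columns `region`, `test`, `group1`, `group2`, `statistic`, `p_value`,
#'   `p_adjusted`, `n1`, `n2`.
#' @export
operon_comparison <- function(mat, operons, max_cds_position = 3,
                              orf = NULL) {
  unknown <- setdiff(operons$cds_id, rownames(mat))
  if (length(unknown) > 0) {
    stop("cds_id not in matrix: ", paste(head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  operons <- dplyr::filter(operons, .data$position <= max_cds_position)
  groups <- split(operons$cds_id, operons$position)

  positions <- matrix_positions(mat)
  n_pos <- length(positions)
  win_starts <- seq(1, n_pos - 19, by = 20)
  regions <- lapply(win_starts, function(s) seq(s, s + 19))
  names(regions) <- vapply(regions, function(ix) {
    paste0("codons_", positions[ix[1]], "_", positions[ix[length(ix)]])
  }, character(1))
  regions[["window"]] <- seq_len(n_pos)

  region_values <- lapply(regions, function(cols) {
    v <- .cds_region_means(mat, cols)
    names(v) <- rownames(mat)
    v
  })
  if (!is.null(orf)) {
    full <- vapply(orf$seq, function(s) {
      n <- nchar(s) %/% 3L
      mean(hbond_count(substring(s, 3L * seq(2L, n) - 2L, 3L * seq(2L, n))))
    }, numeric(1))
    names(full) <- orf$cds_id
    region_values[["full_length"]] <- full
  }

  rows <- list()
  for (rg in names(region_values)) {
    vals <- region_values[[rg]]
    gv <- lapply(groups, function(ids) vals[intersect(ids, names(vals))])
    ok <- vapply(gv, length, integer(1)) >= 2
    gv <- gv[ok]
    if (length(gv) >= 2) {
      kw <- kruskal.test(gv)
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = rg, test = "kruskal_wallis",
        group1 = paste(names(gv), collapse = ","), group2 = NA_character_,
        statistic = unname(kw$statistic), p_value = kw$p.value,
        n1 = sum(lengths(gv)), n2 = NA_integer_)
      pairs <- utils::combn(names(gv), 2, simplify = FALSE)
      for (pr in pairs) {
        wt <- wilcox.test(gv[[pr[1]]], gv[[pr[2]]], exact = FALSE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          region = rg, test = "wilcoxon",
          group1 = pr[1], group2 = pr[2],
          statistic = unname(wt$statistic), p_value = wt$p.value,
          n1 = length(gv[[pr[1]]]), n2 = length(gv[[pr[2]]]))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- NA_real_
  wil <- out$test == "wilcoxon"
  out$p_adjusted[wil] <- p.adjust(out$p_value[wil], method = "BY")
  attr(out, "skipped_groups") <- names(groups)[
    vapply(groups, length, integer(1)) < 2]
  class(out) <- c("operon_comparison", class(out))
  out
}

#' Read an expression table from TSV
#'
#' @param path TSV with columns `cds_id`, `experiment`, `rpkm`.
#' @return long tibble.
#' @export
read_expression_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("cds_id", "experiment", "rpkm") %in% names(tb))) {
    stop("expression TSV needs columns cds_id, experiment, rpkm",
         call. = FALSE)
  }
  if (any(tb$rpkm < 0)) stop("negative abundance", call. = FALSE)
  tb
}

#' Paired high/low expression threshold presets
#'
#' The six (high, low) percentage pairs used for expression stratification:
#' top 5/10/15/20/25/30% against bottom 13/18/23/26/30/35%, chosen so the
#' two strata contain comparable numbers of CDSs.
#'
#' @return tibble with columns `high_pct`, `low_pct`.
#' @export
strata_presets <- function() {
  tibble::tibble(high_pct = c(5, 10, 15, 20, 25, 30),
                 low_pct = c(13, 18, 23, 26, 30, 35))
}

#' Highly and minimally expressed CDS sets
#'
#' Ranks CDSs by abundance within every experiment and intersects across
#' experiments: the high set contains the CDSs in the top `high_pct`% of
#' every experiment, the low set those in the bottom `low_pct`% of every
#' experiment. Rank ties are broken by stable CDS order.
#'
#' @param expr long expression tibble (`cds_id`, `experiment`, `rpkm`).
#' @param high_pct,low_pct percentage thresholds in (0, 100).
#' @return list with character vectors `high`, `low`; empty intersections
#'   are returned empty (with a warning).
#' @export
expression_strata <- function(expr, high_pct = 5, low_pct = 13) {
  stopifnot(high_pct > 0, high_pct < 100, low_pct > 0, low_pct < 100)
  by_exp <- split(expr[, c("cds_id", "rpkm")], expr$experiment)
  top_sets <- lapply(by_exp, function(d) {
    k <- ceiling(high_pct / 100 * nrow(d))
    ord <- order(-d$rpkm)   # stable: ties keep input order
    d$cds_id[ord][seq_len(k)]
  })
  bottom_sets <- lapply(by_exp, function(d) {
    k <- ceiling(low_pct / 100 * nrow(d))
    ord <- order(d$rpkm)
    d$cds_id[ord][seq_len(k)]
  })
  high <- Reduce(intersect, top_sets)
  low <- Reduce(intersect, bottom_sets)
  if (length(high) == 0 || length(low) == 0) {
    warning("empty expression stratum after intersecting experiments",
            call. = FALSE)
  }
  list(high = high, low = low)
}

#' Positional profiles by CDS group, with LOESS smoothing
#'
#' Computes a positional hydrogen-bond profile for each named group of
#' CDSs and overlays a local-regression smooth (span 0.75 by default) with
#' a standard-error band.
#'
#' @param mat a `codon_matrix`.
#' @param groups named list of character vectors of `cds_id`s (each of
#'   size >= 2).
#' @param span LOESS span (default 0.75).
#' @param metric per-codon valuation (default [hbond_count()]).
#' @param n_boot,seed bootstrap controls passed to [positional_profile()].
#' @return a tibble of class `strata_profiles`: per group and position,
#'   the profile columns plus `smoothed` and `smoothed_se`.
#' @export
strata_profiles <- function(mat, groups, span = 0.75, metric = hbond_count,
                            n_boot = 1000, seed = NULL) {
  stopifnot(length(groups) >= 1)
  out <- purrr::imap(groups, function(ids, label) {
    ids <- intersect(ids, rownames(mat))
    if (length(ids) < 2) {
      stop("group '", label, "' has fewer than 2 CDSs in the matrix",
           call. = FALSE)
    }
    pf <- positional_profile(mat[ids, , drop = FALSE], metric,
                             n_boot = n_boot, seed = seed,
                             metric_name = "hbonds")
    lo <- loess(mean ~ position, data = pf, span = span,
                degree = 2, family = "gaussian")
    pred <- predict(lo, se = TRUE)
    pf$smoothed <- as.numeric(pred$fit)
    pf$smoothed_se <- as.numeric(pred$se.fit)
    pf$group <- label
    pf
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("strata_profiles", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.strata_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), size = 0.6,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8) +
    ggplot2::labs(x = "codon position", y = "mean hydrogen bonds / codon",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Correlation network among positional metric profiles
#'
#' All pairwise rank correlations (Spearman by default) among the
#' positional mean vectors of two or more profiles over shared positions,
#' with Benjamini-Yekutieli adjusted p-values and a significance flag.
#'
#' @param profiles named list of `positional_profile` tibbles sharing at
#'   least 3 positions.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha adjusted-p significance threshold for edge annotation
#'   (default 0.01).
#' @return an edge-list tibble: `from`, `to`, `rho`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
metric_correlation_network <- function(profiles, method = "spearman",
                                       alpha = 0.01) {
  stopifnot(length(profiles) >= 2)
  shared <- Reduce(intersect, lapply(profiles, function(p) p$position))
  if (length(shared) < 3) {
    stop("fewer than 3 shared positions", call. = FALSE)
  }
  vecs <- lapply(profiles, function(p) p$mean[match(shared, p$position)])
  pairs <- utils::combn(names(profiles), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    ct <- suppressWarnings(
      cor.test(vecs[[pr[1]]], vecs[[pr[2]]], method = method,
               exact = FALSE))
    tibble::tibble(from = pr[1], to = pr[2],
                   rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out$p_adjusted <- p.adjust(out$p_value, method = "BY")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Region-wise correlation between two positional profiles
#'
#' Pearson and Spearman correlations between two profiles restricted to
#' windows of original codon positions (e.g. 2-120, 2-60, 2-30).
#'
#' @param a,b `positional_profile` tibbles.
#' @param regions list of length-2 numeric vectors `c(first, last)` in
#'   original codon positions.
#' @return tibble with columns `region`, `n_positions`, `pearson`,
#'   `spearman`.
#' @export
region_correlation <- function(a, b,
                               regions = list(c(2, 120), c(2, 60),
                                              c(2, 30))) {
  purrr::map_dfr(regions, function(rg) {
    keep <- intersect(a$position[a$position >= rg[1] & a$position <= rg[2]],
                      b$position[b$position >= rg[1] & b$position <= rg[2]])
    if (length(keep) < 3) {
      stop("region ", rg[1], "-", rg[2],
           " covers fewer than 3 shared positions", call. = FALSE)
    }
    va <- a$mean[match(keep, a$position)]
    vb <- b$mean[match(keep, b$position)]
    tibble::tibble(
      region = paste0("P", rg[1], "-P", rg[2]),
      n_positions = length(keep),
      pearson = stats::cor(va, vb, method = "pearson"),
      spearman = stats::cor(va, vb, method = "spearman")
    )
  })
}
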