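#' Position-dependent profile of a per-codon metric
#'
#' For each codon position of a left-aligned codon matrix, computes the mean
#' of a per-codon valuation over all CDSs, with a nonparametric bootstrap
#' confidence interval for the mean (percentile method, resampling whole CDS
#' rows with replacement).
#'
#' @param mat a `codon_matrix` (see [build_codon_matrix()]).
#' @param metric either a function mapping codon strings to numeric values
#'   (e.g. [hbond_count()]) or a named numeric vector keyed by codon. Codons
#'   missing from a vector metric receive `ambiguous_value`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional integer seed; the RNG state is restored afterwards.
#' @param conf confidence level for the percentile interval (default 0.95).
#' @param metric_name label stored with the profile.
#' @param ambiguous_value value for codons not covered by a vector metric
#'   (default 1, the "no bias" convention of codon-usage metrics).
#' @return a tibble of class `positional_profile` with columns `position`
#'   (original codon position, start codon = 1), `mean`, `se` (bootstrap
#'   standard error), `ci_low`, `ci_high`, `n`, `metric`.
#' @examples
#' orf <- orfeome(c(g1 = "ATGTTAGCG", g2 = "ATGCTGGCA"))
#' mat <- build_codon_matrix(qc_filter(orf, n_positions = 2))
#' positional_profile(mat, hbond_count, n_boot = 100, seed = 1)
#' @export
positional_profile <- function(mat, metric, n_boot = 1000, seed = NULL,
                               conf = 0.95, metric_name = NULL,
                               ambiguous_value = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  stopifnot(nrow(mat) >= 1)
  if (is.function(metric)) {
    codons <- unique(as.vector(mat))
    lut <- setNames(as.numeric(metric(codons)), codons)
    if (is.null(metric_name)) metric_name <- deparse(substitute(metric))
  } else {
    lut <- metric
    missing <- setdiff(unique(as.vector(mat)), names(lut))
    if (length(missing) > 0) {
      lut[missing] <- ambiguous_value
    }
    if (is.null(metric_name)) metric_name <- "metric"
  }
  vals <- matrix(lut[as.vector(mat)], nrow = nrow(mat))
  if (anyNA(vals)) {
    stop("metric undefined for some codons in the matrix", call. = FALSE)
  }
  .profile_from_values(vals, positions = matrix_positions(mat),
                       n_boot = n_boot, seed = seed, conf = conf,
                       metric_name = metric_name)
}

.profile_from_values <- function(vals, positions, n_boot, seed, conf,
                                 metric_name) {
  n_cds <- nrow(vals)
  means <- colMeans(vals)
  run_boot <- function() {
    b <- matrix(0, nrow = n_boot, ncol = ncol(vals))
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n_cds, n_cds, replace = TRUE)
      b[i, ] <- colMeans(vals[idx, , drop = FALSE])
    }
    b
  }
  boot <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  se <- apply(boot, 2, sd)
  out <- tibble::tibble(
    position = positions,
    mean = means,
    se = se,
    ci_low = pmin(ci[1, ], means),
    ci_high = pmax(ci[2, ], means),
    n = n_cds,
    metric = metric_name
  )
  class(out) <- c("positional_profile", class(out))
  out
}

#' Positional frequencies of cheap and expensive codons
#'
#' Per codon position, the fraction of CDSs whose codon is cheap (6--7
#' hydrogen bonds) and expensive (8--9), each with a bootstrap CI. The two
#' fractions sum to 1 at every position.
#'
#' @inheritParams positional_profile
#' @return a named list of two `positional_profile` tibbles: `cheap` and
#'   `expensive`.
#' @export
class_frequencies <- function(mat, n_boot = 1000, seed = NULL) {
  cheap <- positional_profile(
    mat, function(c) as.numeric(hbond_class(c) == "cheap"),
    n_boot = n_boot, seed = seed, metric_name = "cheap_frequency")
  expensive <- cheap
  expensive$mean <- 1 - cheap$mean
  expensive$ci_low <- 1 - cheap$ci_high
  expensive$ci_high <- 1 - cheap$ci_low
  expensive$metric <- "expensive_frequency"
  list(cheap = cheap, expensive = expensive)
}

#' Difference between two positional profiles
#'
#' @param a,b `positional_profile` tibbles over identical positions.
#' @return a tibble with columns `position`, `diff` (`mean_a - mean_b`).
#' @export
difference_profile <- function(a, b) {
  if (!identical(a$position, b$position)) {
    stop("profiles cover different positions", call. = FALSE)
  }
  tibble::tibble(position = a$position, diff = a$mean - b$mean)
}

#' Write / read a positional profile as TSV
#'
#' @param profile a `positional_profile`.
#' @param path output path.
#' @return `path`, invisibly (writer); a `positional_profile` (reader).
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  class(out) <- c("positional_profile", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.positional_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "codon position", y = object$metric[1]) +
    ggplot2::theme_minimal()
}
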