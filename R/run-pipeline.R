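#' Run configuration for pipeline commands
#'
#' Bundles the tunables shared by the `run_*()` pipeline wrappers. Defaults
#' mirror the standard analysis: 100 analyzed codon positions, 1000
#' bootstrap resamples, 200 shuffled ORFeomes for the null.
#'
#' @param n_positions analyzed codon positions, 100 or 250 (default 100).
#' @param n_boot bootstrap resamples (default 1000).
#' @param n_sims shuffled ORFeomes for the null model (default 200).
#' @param seed integer seed threaded through all stochastic steps.
#' @param chigram_denominator `"E"` or `"sqrtE"`.
#' @param fit_weights `"inverse_variance"` or `"uniform"`.
#' @param p_threshold Wald p threshold for the rate parameter.
#' @param out_dir output directory (created if missing).
#' @return list of class `run_config`.
#' @export
run_config <- function(n_positions = 100, n_boot = 1000, n_sims = 200,
                       seed = 1, chigram_denominator = "E",
                       fit_weights = "inverse_variance",
                       p_threshold = 0.001, out_dir = ".") {
  stopifnot(n_positions >= 1, n_boot >= 1, n_sims >= 2)
  cfg <- list(n_positions = n_positions, n_boot = n_boot, n_sims = n_sims,
              seed = as.integer(seed),
              chigram_denominator = chigram_denominator,
              fit_weights = fit_weights, p_threshold = p_threshold,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

.config_header <- function(cfg) {
  hash <- substr(rlang::hash(cfg[setdiff(names(cfg), "out_dir")]), 1, 12)
  c(paste0("# hbramp ", as.character(utils::packageVersion("hbramp"))),
    paste0("# seed=", cfg$seed, " config=", hash,
           " n_positions=", cfg$n_positions,
           " n_boot=", cfg$n_boot, " n_sims=", cfg$n_sims))
}

.write_tsv_with_header <- function(x, path, cfg) {
  writeLines(.config_header(cfg), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.load_qc <- function(fasta, cfg) {
  orf <- read_orfeome(fasta)
  qc_filter(orf, n_positions = cfg$n_positions)
}

#' Pipeline command: positional profiles from a FASTA
#'
#' Reads and QC-filters an ORFeome, then writes the hydrogen-bond
#' positional profile, the cheap/expensive class frequencies, and the QC
#' rejection log as TSV into the config's output directory.
#'
#' @param fasta path to a multi-FASTA of CDSs.
#' @param config a [run_config()].
#' @return named character vector of output paths, invisibly.
#' @export
run_profile <- function(fasta, config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  orf <- .load_qc(fasta, config)
  mat <- build_codon_matrix(orf)
  prof <- positional_profile(mat, hbond_count, n_boot = config$n_boot,
                             seed = config$seed, metric_name = "hbonds")
  freq <- class_frequencies(mat, n_boot = config$n_boot, seed = config$seed)
  paths <- c(
    hbond_profile = file.path(config$out_dir, "hbond_profile.tsv"),
    class_frequencies = file.path(config$out_dir, "class_frequencies.tsv"),
    qc_log = file.path(config$out_dir, "qc_log.tsv"))
  .write_tsv_with_header(prof, paths["hbond_profile"], config)
  .write_tsv_with_header(dplyr::bind_rows(freq),
                         paths["class_frequencies"], config)
  .write_tsv_with_header(qc_log(orf), paths["qc_log"], config)
  invisible(paths)
}

#' Pipeline command: ramp model fits
#'
#' Fits the uniform, linear and bounded exponential models to the
#' hydrogen-bond profile of a FASTA (or to a previously written profile
#' TSV) and writes one JSON report with all fits, the selected model and
#' the fallback parameters.
#'
#' @param input path to a FASTA (`.fa`/`.fasta`/`.fna`) or a profile TSV.
#' @param config a [run_config()].
#' @return path of the JSON report, invisibly.
#' @export
run_fit <- function(input, config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- if (grepl("\\.(fa|fasta|fna)$", input, ignore.case = TRUE)) {
    orf <- .load_qc(input, config)
    positional_profile(build_codon_matrix(orf), hbond_count,
                       n_boot = config$n_boot, seed = config$seed,
                       metric_name = "hbonds")
  } else {
    read_profile(input)
  }
  fits <- fit_models(prof, weights = config$fit_weights)
  sel <- select_model(fits, p_threshold = config$p_threshold)
  report <- list(
    package = paste0("hbramp ",
                     as.character(utils::packageVersion("hbramp"))),
    seed = config$seed,
    selected = sel$model,
    success = isTRUE(sel$success),
    aic_bic_agree = isTRUE(sel$aic_bic_agree),
    fits = lapply(unclass(fits), function(f) {
      list(model = f$model, params = as.list(f$params),
           std_errors = as.list(f$std_errors),
           p_values = as.list(f$p_values),
           aic = f$aic, bic = f$bic, converged = f$converged)
    }),
    fallback = as.list(fallback_parameters(prof)))
  path <- file.path(config$out_dir, "ramp_fit.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Pipeline command: selection test against the shuffling null
#'
#' Builds the codon-shuffling null, computes the per-position selection
#' profile (O, E, sigma, z-squared, chi-gram and normalisations) and a 5'
#' vs rest summary, and writes them as TSV + JSON.
#'
#' @param fasta path to a multi-FASTA of CDSs.
#' @param config a [run_config()].
#' @return named character vector of output paths, invisibly.
#' @export
run_selection <- function(fasta, config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  orf <- .load_qc(fasta, config)
  mat <- build_codon_matrix(orf)
  null <- null_distribution(orf, n_sims = config$n_sims, seed = config$seed)
  sp <- selection_profile(mat, null,
                          chigram_denominator = config$chigram_denominator)
  summary <- ramp_of_selection(sp)
  paths <- c(
    selection_profile = file.path(config$out_dir, "selection_profile.tsv"),
    selection_summary = file.path(config$out_dir, "selection_summary.json"))
  .write_tsv_with_header(sp, paths["selection_profile"], config)
  jsonlite::write_json(
    c(list(seed = config$seed,
           chigram_denominator = config$chigram_denominator),
      as.list(summary)),
    paths["selection_summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Pipeline command: simulate a synthetic ORFeome
#'
#' Generates a ramped (or flat) synthetic ORFeome and writes the FASTA plus
#' a ground-truth JSON.
#'
#' @param spec a [generator_spec()].
#' @param config a [run_config()] (used for the output directory).
#' @return named character vector of output paths, invisibly.
#' @export
run_simulate <- function(spec = generator_spec(), config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  orf <- generate_orfeome(spec)
  truth <- attr(orf, "truth")
  paths <- c(fasta = file.path(config$out_dir, "synthetic_orfeome.fasta"),
             truth = file.path(config$out_dir, "truth.json"))
  write_orfeome(orf, paths["fasta"])
  jsonlite::write_json(
    list(model = truth$model, ramp = as.list(truth$ramp),
         flat_mu = truth$flat_mu, mu = truth$mu, theta = truth$theta,
         seed = truth$seed, n_cds = spec$n_cds,
         length_codons = spec$length_codons),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Pipeline command: operon and expression strata reports
#'
#' Runs the operon-position comparison (when an operon table is given) and
#' the expression stratification with per-stratum smoothed profiles (when
#' an expression table is given); writes TSV reports.
#'
#' @param fasta path to a multi-FASTA of CDSs.
#' @param operon_tsv optional operon table TSV.
#' @param expression_tsv optional expression table TSV.
#' @param high_pct,low_pct expression thresholds (default preset 5/13).
#' @param config a [run_config()].
#' @return named character vector of output paths, invisibly.
#' @export
run_strata <- function(fasta, operon_tsv = NULL, expression_tsv = NULL,
                       high_pct = 5, low_pct = 13, config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  orf <- .load_qc(fasta, config)
  mat <- build_codon_matrix(orf)
  paths <- character()
  if (!is.null(operon_tsv)) {
    operons <- read_operon_table(operon_tsv)
    rep <- operon_comparison(mat, operons, orf = orf)
    p <- file.path(config$out_dir, "operon_comparison.tsv")
    .write_tsv_with_header(rep, p, config)
    paths <- c(paths, operon_comparison = p)
  }
  if (!is.null(expression_tsv)) {
    expr <- read_expression_table(expression_tsv)
    strata <- expression_strata(expr, high_pct, low_pct)
    profs <- strata_profiles(mat, strata, n_boot = config$n_boot,
                             seed = config$seed)
    p <- file.path(config$out_dir, "strata_profiles.tsv")
    .write_tsv_with_header(profs, p, config)
    paths <- c(paths, strata_profiles = p)
  }
  if (length(paths) == 0) {
    stop("provide an operon table and/or an expression table",
         call. = FALSE)
  }
  invisible(paths)
}
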