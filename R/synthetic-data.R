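#' Specification for a synthetic ORFeome generator
#'
#' Describes the study conditions a generated ORFeome emulates: the number
#' of CDSs, their length in codons (start codon included), the target
#' positional mean hydrogen-bond curve — either a bounded-exponential ramp
#' `(A, B, C)` or a flat level — and the amino-acid frequencies (uniform
#' over the 20 amino acids by default).
#'
#' Codons are drawn by exponential tilting within synonym families:
#' at each position the codon of amino acid `a` is drawn with probability
#' proportional to `exp(theta_x * hbonds)`, where `theta_x` is solved by
#' bisection so the population-expected hydrogen-bond mean equals the
#' target curve (clamped 1e-6 inside the feasible interval given the
#' amino-acid pool). Tilting is the maximum-entropy family matching a mean
#' constraint, so nothing beyond the positional mean is imposed.
#'
#' @param n_cds number of CDSs (default 2000).
#' @param length_codons codons per CDS including the start codon
#'   (default 101, i.e. 100 analyzed positions).
#' @param ramp named vector `c(A=, B=, C=)` of bounded-exponential
#'   parameters (default `A = 7.9, B = 0.3, C = 7.0`); ignored when
#'   `flat_mu` is given.
#' @param flat_mu flat target mean (bonds/codon) for no-ramp controls.
#' @param aa_frequencies named vector of amino-acid frequencies (one-letter
#'   codes); uniform by default. Normalised internally.
#' @param seed integer seed for all generator randomness.
#' @return a list of class `generator_spec`.
#' @export
generator_spec <- function(n_cds = 2000, length_codons = 101,
                           ramp = c(A = 7.9, B = 0.3, C = 7.0),
                           flat_mu = NULL, aa_frequencies = NULL,
                           seed = 1) {
  stopifnot(n_cds >= 1, length_codons >= 2)
  if (is.null(flat_mu)) {
    stopifnot(all(c("A", "B", "C") %in% names(ramp)))
    stopifnot(ramp["C"] >= 6, ramp["A"] <= 9, ramp["C"] <= ramp["A"])
  }
  aas <- setdiff(unique(codon_table()$aa), "*")
  if (is.null(aa_frequencies)) {
    aa_frequencies <- setNames(rep(1 / length(aas), length(aas)), aas)
  } else {
    stopifnot(all(names(aa_frequencies) %in% aas), all(aa_frequencies >= 0))
    aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  }
  spec <- list(n_cds = n_cds, length_codons = length_codons,
               ramp = if (is.null(flat_mu)) ramp else NULL,
               flat_mu = flat_mu, aa_frequencies = aa_frequencies,
               seed = seed)
  class(spec) <- "generator_spec"
  spec
}

# per-family hydrogen-bond data for the tilting machinery
.family_data <- function(aa_frequencies) {
  tb <- dplyr::filter(codon_table(), .data$aa != "*")
  fams <- split(tb[, c("codon", "hbonds")], tb$aa)
  fams <- fams[names(aa_frequencies)]
  list(fams = fams, f = aa_frequencies)
}

# population-expected hbond mean under tilt theta
.tilted_mean <- function(theta, fd) {
  m <- vapply(fd$fams, function(fam) {
    w <- exp(theta * (fam$hbonds - max(fam$hbonds)))
    sum(fam$hbonds * w) / sum(w)
  }, numeric(1))
  sum(fd$f * m)
}

# solve theta so that the expected mean equals mu (mu already clamped)
.solve_theta <- function(mu, fd) {
  vapply(mu, function(m) {
    if (abs(.tilted_mean(0, fd) - m) < 1e-12) return(0)
    stats::uniroot(function(t) .tilted_mean(t, fd) - m,
                   interval = c(-80, 80), tol = 1e-10)$root
  }, numeric(1))
}

.feasible_interval <- function(fd) {
  lo <- sum(fd$f * vapply(fd$fams, function(x) min(x$hbonds), numeric(1)))
  hi <- sum(fd$f * vapply(fd$fams, function(x) max(x$hbonds), numeric(1)))
  c(lo, hi)
}

#' Generate a synthetic ORFeome with a known hydrogen-bond ramp
#'
#' Draws CDS sequences whose per-position expected hydrogen-bond mean
#' follows the spec's target curve (see [generator_spec()] for the
#' mechanism). Every CDS starts with ATG; all positions after the start
#' codon are tilted toward the target curve. The ground truth
#' (target curve, solved tilts, seed) is stored in the `"truth"`
#' attribute. Output is bit-reproducible from `(spec, seed)`.
#'
#' @param spec a `generator_spec`.
#' @return an ORFeome tibble with attribute `truth`.
#' @export
generate_orfeome <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n_gen <- spec$length_codons - 1L
  x <- seq_len(n_gen) - 1L
  mu <- if (is.null(spec$flat_mu)) {
    bounded_exponential(x, spec$ramp["A"], spec$ramp["B"], spec$ramp["C"])
  } else {
    rep(spec$flat_mu, n_gen)
  }
  fd <- .family_data(spec$aa_frequencies)
  feas <- .feasible_interval(fd)
  if (any(mu < feas[1] | mu > feas[2])) {
    stop(sprintf(
      "target mean outside achievable range [%.4f, %.4f] for this amino-acid pool",
      feas[1], feas[2]), call. = FALSE)
  }
  mu_c <- pmin(pmax(mu, feas[1] + 1e-6), feas[2] - 1e-6)
  theta <- .solve_theta(mu_c, fd)

  aas <- names(fd$fams)
  gen <- function() {
    aamat <- matrix(sample(aas, spec$n_cds * n_gen, replace = TRUE,
                           prob = fd$f), nrow = spec$n_cds)
    codmat <- matrix("", nrow = spec$n_cds, ncol = n_gen)
    for (j in seq_len(n_gen)) {
      for (a in aas) {
        idx <- which(aamat[, j] == a)
        if (length(idx) == 0) next
        fam <- fd$fams[[a]]
        w <- exp(theta[j] * (fam$hbonds - max(fam$hbonds)))
        codmat[idx, j] <- fam$codon[
          sample.int(nrow(fam), length(idx), replace = TRUE, prob = w)]
      }
    }
    do.call(paste0, c(list("ATG"), asplit(codmat, 2)))
  }
  seqs <- withr::with_seed(spec$seed, gen())
  ids <- sprintf("cds_%05d", seq_len(spec$n_cds))
  orf <- tibble::tibble(cds_id = ids, seq = seqs)
  attr(orf, "provenance") <- "synthetic"
  attr(orf, "truth") <- list(
    model = if (is.null(spec$flat_mu)) "bounded_exponential" else "flat",
    ramp = spec$ramp, flat_mu = spec$flat_mu,
    mu = mu_c, theta = theta, seed = spec$seed, spec = spec)
  orf
}

#' Assign synthetic CDSs to operons, optionally with a 5' first-gene effect
#'
#' Partitions the first `sum(sizes)` CDSs of a synthetic ORFeome into
#' operons of the given sizes (consecutive positions 1, 2, ...). When
#' `delta > 0`, the CDSs in position 1 of each operon are regenerated with
#' the target curve lowered by `delta` bonds/codon over the first
#' `n5` analyzed positions, emulating a promoter-proximal reduction in
#' hydrogen bonding.
#'
#' @param orf a synthetic ORFeome from [generate_orfeome()].
#' @param sizes integer vector of operon sizes (each >= 2, summing to at
#'   most the number of CDSs).
#' @param delta 5' hydrogen-bond reduction for first-position CDSs
#'   (bonds/codon, default 0).
#' @param n5 number of analyzed positions affected by `delta` (default 20).
#' @return list with elements `orfeome` (possibly regenerated) and
#'   `operons` (tibble `cds_id`, `operon_id`, `position`).
#' @export
generate_operons <- function(orf, sizes, delta = 0, n5 = 20) {
  stopifnot(all(sizes >= 2))
  if (sum(sizes) > nrow(orf)) {
    stop("operon sizes sum to more than the number of CDSs", call. = FALSE)
  }
  operon_id <- rep(seq_along(sizes), sizes)
  position <- unlist(lapply(sizes, seq_len))
  ids <- orf$cds_id[seq_len(sum(sizes))]
  operons <- tibble::tibble(
    cds_id = ids,
    operon_id = sprintf("op_%04d", operon_id),
    position = position)
  if (delta > 0) {
    truth <- attr(orf, "truth")
    if (is.null(truth)) {
      stop("delta > 0 needs a synthetic ORFeome with a truth attribute",
           call. = FALSE)
    }
    spec <- truth$spec
    n_gen <- spec$length_codons - 1L
    mu <- truth$mu
    mu2 <- mu
    k <- min(n5, n_gen)
    mu2[seq_len(k)] <- mu[seq_len(k)] - delta
    fd <- .family_data(spec$aa_frequencies)
    feas <- .feasible_interval(fd)
    mu2 <- pmin(pmax(mu2, feas[1] + 1e-6), feas[2] - 1e-6)
    theta2 <- .solve_theta(mu2, fd)
    first_ids <- operons$cds_id[operons$position == 1]
    aas <- names(fd$fams)
    regen <- function() {
      vapply(first_ids, function(id) {
        aadraw <- sample(aas, n_gen, replace = TRUE, prob = fd$f)
        cods <- vapply(seq_len(n_gen), function(j) {
          fam <- fd$fams[[aadraw[j]]]
          w <- exp(theta2[j] * (fam$hbonds - max(fam$hbonds)))
          fam$codon[sample.int(nrow(fam), 1, prob = w)]
        }, character(1))
        paste0("ATG", paste(cods, collapse = ""))
      }, character(1), USE.NAMES = FALSE)
    }
    new_seqs <- withr::with_seed(spec$seed + 1L, regen())
    orf$seq[match(first_ids, orf$cds_id)] <- new_seqs
    truth$delta <- delta
    truth$theta_first_position <- theta2
    attr(orf, "truth") <- truth
  }
  list(orfeome = orf, operons = operons)
}

#' Generate a synthetic expression table
#'
#' Log-normal abundances per CDS with experiment-level replicate noise and
#' an optional negative coupling between a CDS's 5' hydrogen-bond content
#' and its abundance (highly expressed CDSs then prefer fewer bonds at the
#' 5' end, as in real transcriptomes showing the effect).
#'
#' @param orf an ORFeome tibble.
#' @param n_experiments number of experiments (default 16).
#' @param coupling strength of the negative association between the 5'
#'   hydrogen-bond mean (z-scored over CDSs) and log abundance (default 0).
#' @param noise_sd experiment-level log-scale noise (default 0.25).
#' @param base_sdlog CDS-level log-scale spread (default 1).
#' @param n5 number of analyzed positions defining the 5' region
#'   (default 20).
#' @param seed integer seed.
#' @return long tibble `cds_id`, `experiment`, `rpkm`.
#' @export
generate_expression <- function(orf, n_experiments = 16, coupling = 0,
                                noise_sd = 0.25, base_sdlog = 1, n5 = 20,
                                seed = 1) {
  stopifnot(n_experiments >= 1)
  five_prime <- vapply(orf$seq, function(s) {
    n <- min(nchar(s) %/% 3L, n5 + 1L)
    mean(hbond_count(substring(s, 3L * seq(2L, n) - 2L, 3L * seq(2L, n))))
  }, numeric(1), USE.NAMES = FALSE)
  z <- as.numeric(scale(five_prime))
  if (anyNA(z)) z <- rep(0, length(five_prime))
  gen <- function() {
    base <- 3 + base_sdlog * rnorm(nrow(orf)) - coupling * z
    purrr::map_dfr(seq_len(n_experiments), function(e) {
      tibble::tibble(
        cds_id = orf$cds_id,
        experiment = sprintf("exp_%02d", e),
        rpkm = exp(base + noise_sd * rnorm(nrow(orf))))
    })
  }
  withr::with_seed(seed, gen())
}

#' Write an ORFeome to multi-FASTA
#'
#' @param orf an ORFeome tibble.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_orfeome <- function(orf, path) {
  set <- Biostrings::DNAStringSet(setNames(orf$seq, orf$cds_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
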