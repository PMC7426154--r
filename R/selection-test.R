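#' Shuffle synonymous codons within a codon sequence
#'
#' For each amino acid independently, randomly permutes the multiset of its
#' codons over the positions where that amino acid occurs. The translated
#' protein and the per-sequence codon multiset are unchanged; stop codons
#' and single-codon families stay fixed.
#'
#' @param codons character vector of codons (one CDS, any length).
#' @return character vector of the same length.
#' @export
shuffle_synonymous <- function(codons) {
  codons <- .normalize_codon(codons)
  aa <- .codon_lookup(codons, "aa")
  for (a in unique(aa)) {
    if (a == "*") next
    idx <- which(aa == a)
    if (length(idx) > 1) {
      codons[idx] <- codons[idx[sample.int(length(idx))]]
    }
  }
  codons
}

# Vectorised shuffling engine over a whole ORFeome: pre-computes one long
# hbond vector grouped by (CDS, amino acid); each simulation permutes the
# values within groups by a single order() call.
.shuffle_engine <- function(orf, n_positions) {
  cod_list <- .cds_codon_list(orf)
  lens <- lengths(cod_list)
  if (any(lens < n_positions)) {
    stop("CDS shorter than the analysis window; run qc_filter() first",
         call. = FALSE)
  }
  cods <- unlist(cod_list, use.names = FALSE)
  aa <- .codon_lookup(cods, "aa")
  hb <- .codon_lookup(cods, "hbonds")
  cds_idx <- rep(seq_along(cod_list), lens)
  aa_idx <- match(aa, c(unique(codon_table()$aa)))
  g <- (cds_idx - 1L) * 21L + aa_idx
  # stop codons never move: give each occurrence its own group
  is_stop <- aa == "*"
  if (any(is_stop)) {
    g[is_stop] <- max(g) + seq_len(sum(is_stop))
  }
  ord0 <- order(g)
  g_sorted <- g[ord0]
  h_base <- hb[ord0]
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  lin <- outer(offsets, seq_len(n_positions), `+`)
  list(g_sorted = g_sorted, h_base = h_base, ord0 = ord0,
       lin = lin, n_cds = length(cod_list), n_positions = n_positions,
       n_total = length(hb), hb = hb)
}

.shuffle_totals_once <- function(eng) {
  perm <- order(eng$g_sorted, runif(eng$n_total))
  h_new <- numeric(eng$n_total)
  h_new[eng$ord0] <- eng$h_base[perm]
  colSums(matrix(h_new[eng$lin], eng$n_cds, eng$n_positions))
}

#' Null distribution of per-position hydrogen-bond totals
#'
#' Builds `n_sims` synonymously shuffled copies of the ORFeome (shuffling
#' acts on the full-length CDSs, so synonyms can move in and out of the
#' analysis window) and records the per-position total hydrogen-bond count
#' of each. Returns the null mean `E` and standard deviation `sigma` per
#' position.
#'
#' @param orf a QC-filtered ORFeome tibble.
#' @param n_positions number of analyzed codon positions.
#' @param n_sims number of shuffled ORFeomes (default 200; must be >= 2).
#' @param seed optional integer seed.
#' @return a tibble of class `hb_null` with columns `position`, `E`,
#'   `sigma`; attributes `n_sims`, `n_cds`.
#' @export
null_distribution <- function(orf, n_positions = attr(orf, "n_positions"),
                              n_sims = 200, seed = NULL) {
  if (is.null(n_positions)) {
    stop("n_positions not given and ORFeome has not been through qc_filter()",
         call. = FALSE)
  }
  if (n_sims < 2) stop("n_sims must be >= 2 (sigma undefined)", call. = FALSE)
  eng <- .shuffle_engine(orf, n_positions)
  run <- function() {
    vapply(seq_len(n_sims), function(i) .shuffle_totals_once(eng),
           numeric(n_positions))
  }
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- tibble::tibble(
    position = seq_len(n_positions) + 1L,
    E = rowMeans(sims),
    sigma = apply(sims, 1, sd)
  )
  attr(out, "n_sims") <- n_sims
  attr(out, "n_cds") <- eng$n_cds
  class(out) <- c("hb_null", class(out))
  out
}

#' Position-wise selection statistics against the shuffling null
#'
#' Per codon position: the observed total hydrogen-bond count `O`, the null
#' mean `E` and standard deviation `sigma`, the squared z-score
#' `z_sq = ((O - E)/sigma)^2` (positions with `sigma = 0` contribute 0 and
#' are flagged), the hanging chi-gram `(O - E)/E` (or `(O - E)/sqrt(E)`
#' when `chigram_denominator = "sqrtE"`), the min-max normalised z_sq, and
#' the centered-and-scaled chi-gram.
#'
#' @param mat observed `codon_matrix`.
#' @param null an `hb_null` tibble from [null_distribution()].
#' @param chigram_denominator `"E"` (default) or `"sqrtE"`.
#' @return a tibble of class `selection_profile` with columns `position`,
#'   `O`, `E`, `sigma`, `z_sq`, `chigram`, `normalized_z_sq`,
#'   `scaled_chigram`, `sigma_zero`; attribute `chi_sq_total`.
#' @export
selection_profile <- function(mat, null,
                              chigram_denominator = c("E", "sqrtE")) {
  chigram_denominator <- match.arg(chigram_denominator)
  if (nrow(null) != ncol(mat)) {
    stop("null and matrix cover different numbers of positions",
         call. = FALSE)
  }
  O <- colSums(matrix(hbond_count(as.vector(mat)), nrow = nrow(mat)))
  E <- null$E
  sigma <- null$sigma
  if (any(E == 0)) stop("null mean E is zero at some position", call. = FALSE)
  z_sq <- ifelse(sigma > 0, ((O - E) / sigma)^2, 0)
  den <- if (chigram_denominator == "E") E else sqrt(E)
  chigram <- (O - E) / den
  rng <- range(z_sq)
  normalized_z_sq <- if (diff(rng) > 0) {
    (z_sq - rng[1]) / diff(rng)
  } else {
    rep(0, length(z_sq))
  }
  scaled_chigram <- if (sd(chigram) > 0) {
    as.numeric(scale(chigram))
  } else {
    rep(0, length(chigram))
  }
  out <- tibble::tibble(
    position = null$position,
    O = O, E = E, sigma = sigma,
    z_sq = z_sq, chigram = chigram,
    normalized_z_sq = normalized_z_sq,
    scaled_chigram = scaled_chigram,
    sigma_zero = sigma == 0
  )
  attr(out, "chi_sq_total") <- sum(z_sq)
  attr(out, "chigram_denominator") <- chigram_denominator
  class(out) <- c("selection_profile", class(out))
  out
}

#' Summarise the 5' ramp of selection
#'
#' Compares the first `n5` analyzed positions with the remainder: mean
#' normalised z-squared and mean chi-gram in each region, and the sign of
#' the 5' chi-gram (negative means selection toward fewer hydrogen bonds
#' at the 5' end).
#'
#' @param sp a `selection_profile` over at least 20 positions.
#' @param n5 number of 5' positions in the "ramp" region (default 15).
#' @return a one-row tibble with columns `mean_norm_zsq_5prime`,
#'   `mean_norm_zsq_rest`, `mean_chigram_5prime`, `mean_chigram_rest`,
#'   `sign_5prime`, `chi_sq_total`.
#' @export
ramp_of_selection <- function(sp, n5 = 15) {
  if (nrow(sp) < 20) stop("profile too short (need >= 20 positions)",
                          call. = FALSE)
  head_idx <- seq_len(n5)
  tibble::tibble(
    mean_norm_zsq_5prime = mean(sp$normalized_z_sq[head_idx]),
    mean_norm_zsq_rest = mean(sp$normalized_z_sq[-head_idx]),
    mean_chigram_5prime = mean(sp$chigram[head_idx]),
    mean_chigram_rest = mean(sp$chigram[-head_idx]),
    sign_5prime = sign(mean(sp$chigram[head_idx])),
    chi_sq_total = attr(sp, "chi_sq_total")
  )
}

#' Shuffle a whole ORFeome synonymously
#'
#' Returns a copy of the ORFeome in which every CDS has had its synonymous
#' codons shuffled (start codon kept in place). Useful for null
#' calibration and for writing simulated ORFeomes to FASTA.
#'
#' @param orf an ORFeome tibble.
#' @param seed optional integer seed.
#' @return an ORFeome tibble.
#' @export
shuffle_orfeome <- function(orf, seed = NULL) {
  run <- function() {
    shuf <- vapply(orf$seq, function(s) {
      n <- nchar(s) %/% 3L
      cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
      paste0(cods[1], paste(shuffle_synonymous(cods[-1]), collapse = ""))
    }, character(1), USE.NAMES = FALSE)
    out <- orf
    out$seq <- shuf
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @exportS3Method ggplot2::autoplot
autoplot.selection_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("position", "z_sq", "chigram")],
    cols = c("z_sq", "chigram"), names_to = "statistic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "codon position", y = NULL) +
    ggplot2::theme_minimal()
}
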