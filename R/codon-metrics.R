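#' Codon usage counts of an ORFeome
#'
#' Counts every codon over all CDSs of the collection (frame 0, full
#' length). Used as the reference usage for RSCU and CAI weights.
#'
#' @param orf an ORFeome tibble.
#' @return named integer vector over the 64 codons (TCAG table order).
#' @export
codon_usage <- function(orf) {
  tb <- codon_table()
  counts <- setNames(integer(64), tb$codon)
  for (s in orf$seq) {
    n <- nchar(s) %/% 3L
    cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    cods <- cods[cods %in% tb$codon]
    t0 <- table(cods)
    counts[names(t0)] <- counts[names(t0)] + as.integer(t0)
  }
  counts
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon `c` of an amino acid with `k` synonyms, RSCU is the observed
#' count of `c` divided by the mean count over the family, so the family
#' mean RSCU is 1 and family RSCU values sum to `k`. Amino acids entirely
#' absent from the ORFeome get RSCU 1 for all synonyms (no bias) and are
#' flagged in the `"flagged_aa"` attribute.
#'
#' @param orf an ORFeome tibble, or a named numeric vector of codon counts
#'   as returned by [codon_usage()].
#' @return a `codon_weights` tibble with columns `codon`, `aa`, `count`,
#'   `weight`; attribute `metric_name = "rscu"`.
#' @export
rscu <- function(orf) {
  counts <- if (is.data.frame(orf)) codon_usage(orf) else orf
  tb <- codon_table()
  out <- tb |>
    dplyr::select("codon", "aa") |>
    dplyr::mutate(count = as.numeric(counts[.data$codon])) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(weight = ifelse(rep(sum(.data$count) == 0, dplyr::n()),
                                  1, .data$count / mean(.data$count))) |>
    dplyr::ungroup()
  flagged <- out |>
    dplyr::group_by(.data$aa) |>
    dplyr::summarise(absent = sum(.data$count) == 0, .groups = "drop")
  attr(out, "flagged_aa") <- flagged$aa[flagged$absent]
  attr(out, "metric_name") <- "rscu"
  attr(out, "ambiguous_value") <- 1
  class(out) <- c("codon_weights", class(out))
  out
}

#' Codon adaptation index (CAI) weights
#'
#' Relative adaptiveness of each codon: its RSCU divided by the maximum
#' RSCU among its synonyms, so the best codon of each family has weight 1.
#' (No per-CDS geometric mean is taken; the weights are used directly for
#' positional profiling.)
#'
#' @param x an RSCU `codon_weights` tibble (see [rscu()]) or an ORFeome
#'   tibble, from which RSCU is computed first.
#' @return a `codon_weights` tibble with `metric_name = "cai"`.
#' @export
cai_weights <- function(x) {
  if (!inherits(x, "codon_weights")) x <- rscu(x)
  flagged <- attr(x, "flagged_aa")
  out <- x |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(weight = ifelse(rep(max(.data$weight) == 0, dplyr::n()),
                                  1, .data$weight / max(.data$weight))) |>
    dplyr::ungroup()
  attr(out, "flagged_aa") <- flagged
  attr(out, "metric_name") <- "cai"
  attr(out, "ambiguous_value") <- 1
  class(out) <- c("codon_weights", class(out))
  out
}

#' Read a tRNA gene-copy-number pool from TSV
#'
#' @param path TSV with columns `anticodon` (5'->3' DNA or RNA alphabet)
#'   and `tgcn` (gene copy number).
#' @return tibble with columns `anticodon`, `tgcn`.
#' @export
read_trna_pool <- function(path) {
  pool <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("anticodon", "tgcn") %in% names(pool))) {
    stop("tRNA pool TSV needs columns 'anticodon' and 'tgcn'", call. = FALSE)
  }
  pool$anticodon <- .normalize_codon(pool$anticodon, what = "anticodon")
  if (any(pool$tgcn < 0)) stop("negative tGCN", call. = FALSE)
  pool
}

# The nine wobble selective-constraint values, in the fixed pair order of
# the canonical tAI formulation; identical vectors are used for prokaryotes
# and eukaryotes by default.
#' @rdname tai_weights
#' @export
s_prokaryote <- c(0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68, 0.89)

#' @rdname tai_weights
#' @export
s_eukaryote <- c(0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68, 0.89)

#' tRNA adaptation index (tAI) codon weights
#'
#' Computes absolute adaptiveness values `W` for each codon from the gene
#' copy numbers of the tRNAs that can read it (Watson-Crick plus wobble
#' pairs, each pair discounted by a selective-constraint `s` value), then
#' normalises by the maximum `W`. Codons with `W = 0` receive the geometric
#' mean of the nonzero relative weights. Stop codons carry no weight;
#' methionine's ATG, which the canonical formulation leaves out of the
#' normalisation set, is assigned its natural extension
#' `W(ATG)/max(W)` so positional profiles cover every sense codon.
#'
#' @param pool tibble with columns `anticodon`, `tgcn` (see
#'   [read_trna_pool()]).
#' @param s nine selective-constraint values in the canonical wobble-pair
#'   order; defaults to the prokaryote vector.
#' @param sking 1 for Bacteria/Archaea (lysidine-modified tRNA reads the
#'   isoleucine ATA codon), 0 for eukaryotes.
#' @return a `codon_weights` tibble (61 sense codons) with columns `codon`,
#'   `aa`, `W`, `weight`; `metric_name = "tai"`.
#' @export
tai_weights <- function(pool, s = s_prokaryote, sking = 1) {
  stopifnot(length(s) == 9, all(s >= 0 & s <= 1), sking %in% c(0, 1))
  tb <- codon_table()
  # tGCN indexed by the codon each anticodon Watson-Crick pairs with
  wc_codon <- .revcomp(pool$anticodon)
  trna <- setNames(numeric(64), tb$codon)
  agg <- tapply(pool$tgcn, wc_codon, sum)
  trna[names(agg)] <- agg
  p <- 1 - s
  W <- numeric(64)
  for (i in seq(1, 61, by = 4)) {
    W[i]     <- p[1] * trna[i]     + p[5] * trna[i + 1]
    W[i + 1] <- p[2] * trna[i + 1] + p[6] * trna[i]
    W[i + 2] <- p[3] * trna[i + 2] + p[7] * trna[i]
    W[i + 3] <- p[4] * trna[i + 3] + p[8] * trna[i + 2]
  }
  W[36] <- p[4] * trna[36]            # ATG: no wobble contribution
  if (sking == 1) W[35] <- p[9]       # bacterial ATA via modified tRNA
  names(W) <- tb$codon
  drop <- c(11, 12, 15, 36)           # TAA, TAG, TGA, ATG
  W_main <- W[-drop]
  if (max(W_main) == 0) {
    stop("empty tRNA pool coverage", call. = FALSE)
  }
  w <- W_main / max(W_main)
  gm <- if (any(w == 0)) exp(mean(log(w[w != 0]))) else NA_real_
  w[w == 0] <- gm
  w_atg <- min(W[36] / max(W_main), 1)
  if (w_atg == 0 && !is.na(gm)) w_atg <- gm
  w_all <- c(w, ATG = unname(w_atg))
  out <- tb |>
    dplyr::filter(.data$aa != "*") |>
    dplyr::select("codon", "aa") |>
    dplyr::mutate(W = unname(W[.data$codon]),
                  weight = unname(w_all[.data$codon]))
  attr(out, "metric_name") <- "tai"
  attr(out, "ambiguous_value") <- 1
  class(out) <- c("codon_weights", class(out))
  out
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, "", fixed = TRUE),
                function(b) paste(rev(b), collapse = ""), character(1)))
}

#' Read per-base unpaired probabilities from an RNA-folding "lunp" table
#'
#' Adapter for the tabular per-position unpaired-probability output of an
#' external RNA local-folding tool (computed there with window parameters
#' such as L = 40, W = 40, u = 40). Row `i`, column `l` holds the
#' probability that the stretch of `l` bases ending at position `i` is
#' unpaired.
#'
#' @param path path to the table (lines starting with `#` are headers;
#'   first column is the end position, remaining columns span lengths
#'   `1..u`; unavailable entries are `NA`).
#' @param mode how to average span probabilities into one value per base:
#'   `"containing"` (default) averages over all reported spans that contain
#'   the base; `"ending"` averages the row of spans ending at the base.
#' @return an `unpaired_profile` list with elements `base` (tibble `base`,
#'   `unpaired`) and `codon` (tibble `codon_position`, `unpaired`,
#'   `structure` with `structure = 1 - unpaired`).
#' @export
read_unpaired_probabilities <- function(path,
                                        mode = c("containing", "ending")) {
  mode <- match.arg(mode)
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, fill = TRUE,
                      comment.char = "#", na.strings = c("NA", "nan")),
    error = function(e) stop("malformed unpaired-probability table: ",
                             conditionMessage(e), call. = FALSE))
  pos <- as.integer(raw[[1]])
  probs <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(!is.na(probs) & (probs < 0 | probs > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("probability outside [0,1] at line ", bad[1, 1], call. = FALSE)
  }
  n <- max(pos)
  if (mode == "ending") {
    unpaired <- vapply(seq_len(n), function(b) {
      r <- which(pos == b)
      if (length(r) == 0) return(NA_real_)
      mean(probs[r, ], na.rm = TRUE)
    }, numeric(1))
  } else {
    acc <- numeric(n)
    cnt <- numeric(n)
    for (r in seq_along(pos)) {
      i <- pos[r]
      for (l in seq_len(ncol(probs))) {
        pval <- probs[r, l]
        if (is.na(pval)) next
        lo <- i - l + 1L
        if (lo < 1L) next
        acc[lo:i] <- acc[lo:i] + pval
        cnt[lo:i] <- cnt[lo:i] + 1
      }
    }
    unpaired <- ifelse(cnt > 0, acc / cnt, NA_real_)
  }
  base <- tibble::tibble(base = seq_len(n), unpaired = unpaired)
  n_codons <- n %/% 3L
  codon_unpaired <- vapply(seq_len(n_codons), function(j) {
    mean(unpaired[(3L * j - 2L):(3L * j)])
  }, numeric(1))
  codon <- tibble::tibble(
    codon_position = seq_len(n_codons),
    unpaired = codon_unpaired,
    structure = 1 - codon_unpaired
  )
  out <- list(base = base, codon = codon)
  class(out) <- "unpaired_profile"
  out
}

#' Positional profile of a codon-weight metric
#'
#' Applies a `codon_weights` table (RSCU, CAI or tAI) to a codon matrix and
#' delegates to [positional_profile()]. Codons without a weight (stop
#' codons under tAI, or codons containing N) receive the table's
#' no-bias value (1).
#'
#' @param mat a `codon_matrix`.
#' @param weights a `codon_weights` tibble.
#' @inheritParams positional_profile
#' @return a `positional_profile` tibble.
#' @export
positional_metric <- function(mat, weights, n_boot = 1000, seed = NULL) {
  lut <- setNames(weights$weight, weights$codon)
  positional_profile(
    mat, lut, n_boot = n_boot, seed = seed,
    metric_name = attr(weights, "metric_name") %||% "metric",
    ambiguous_value = attr(weights, "ambiguous_value") %||% 1)
}
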