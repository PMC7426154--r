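#' The standard genetic code with per-codon hydrogen-bond counts
#'
#' Builds the lookup table at the heart of every analysis in this package:
#' the 64 codons of the standard genetic code (NCBI table 1), the amino acid
#' each encodes (`*` for stop), the number of Watson-Crick hydrogen bonds the
#' codon's three base pairs carry in double-stranded DNA (A:T = 2, G:C = 3,
#' so 6--9 bonds per codon), and the cheap/expensive class derived from it.
#'
#' Relative and scaled hydrogen-bond values are computed within synonym
#' families (all codons of one amino acid). Stop codons form their own
#' family and are excluded from amino-acid family statistics, so their
#' `relative_hbond` and `scaled_hbond` are `NA`.
#'
#' @return A tibble with one row per codon and columns:
#' \describe{
#'   \item{codon}{trinucleotide over A/C/G/T, in TCAG table order}
#'   \item{aa}{one-letter amino acid, `*` for stop}
#'   \item{hbonds}{integer hydrogen-bond count in 6..9}
#'   \item{class}{`"cheap"` (6--7 bonds) or `"expensive"` (8--9)}
#'   \item{n_syn}{size of the codon's synonym family}
#'   \item{relative_hbond}{hbonds / max hbonds within the amino-acid family}
#'   \item{scaled_hbond}{(hbonds - family mean) / family sd; `NA` when the
#'     family has a single codon (Met, Trp) or is the stop family}
#' }
#' @examples
#' codon_table()
#' @export
codon_table <- function() {
  .hbramp_env$codon_table
}

.hbond_per_base <- c(A = 2, T = 2, G = 3, C = 3)

.build_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codon <- paste0(grid$b1, grid$b2, grid$b3)
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  hb <- .hbond_per_base[grid$b1] + .hbond_per_base[grid$b2] +
    .hbond_per_base[grid$b3]
  tb <- tibble::tibble(
    codon = codon,
    aa = aa,
    hbonds = as.integer(unname(hb)),
    class = unname(ifelse(hb <= 7, "cheap", "expensive"))
  )
  tb <- tb |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      n_syn = dplyr::n(),
      relative_hbond = ifelse(.data$aa == "*", NA_real_,
                              .data$hbonds / max(.data$hbonds)),
      scaled_hbond = ifelse(
        .data$aa == "*" | dplyr::n() < 2 | stats::sd(.data$hbonds) == 0,
        NA_real_,
        (.data$hbonds - mean(.data$hbonds)) / stats::sd(.data$hbonds)
      )
    ) |>
    dplyr::ungroup()
  tb
}

.hbramp_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .hbramp_env$codon_table <- .build_codon_table()
  invisible()
}

# Normalize codon input: uppercase, U -> T. Errors on ambiguous bases.
.normalize_codon <- function(codon, what = "codon") {
  codon <- toupper(as.character(codon))
  codon <- gsub("U", "T", codon, fixed = TRUE)
  bad_len <- nchar(codon) != 3L
  if (any(bad_len)) {
    stop("each ", what, " must be three bases, got: ",
         paste(unique(codon[bad_len]), collapse = ", "), call. = FALSE)
  }
  ambiguous <- grepl("[^ACGT]", codon)
  if (any(ambiguous)) {
    stop("ambiguous codon (non-ACGT base): ",
         paste(unique(codon[ambiguous]), collapse = ", "), call. = FALSE)
  }
  codon
}

.codon_lookup <- function(codon, column) {
  tb <- codon_table()
  unname(tb[[column]][match(codon, tb$codon)])
}

#' Hydrogen-bond count of a codon
#'
#' Sum of the Watson-Crick bond counts of the codon's three bases
#' (A = T = 2, G = C = 3). Vectorised; accepts lowercase and RNA (U) input.
#'
#' @param codon character vector of trinucleotides.
#' @return integer vector of bond counts in 6..9.
#' @examples
#' hbond_count(c("TTA", "CTG", "GCG")) # 6 8 9
#' @export
hbond_count <- function(codon) {
  .codon_lookup(.normalize_codon(codon), "hbonds")
}

#' Cheap/expensive class of a codon
#'
#' Codons with 6 or 7 hydrogen bonds are "cheap", those with 8 or 9 are
#' "expensive".
#'
#' @inheritParams hbond_count
#' @return character vector, `"cheap"` or `"expensive"`.
#' @examples
#' hbond_class(c("TTA", "CTG")) # "cheap" "expensive"
#' @export
hbond_class <- function(codon) {
  .codon_lookup(.normalize_codon(codon), "class")
}

#' Relative hydrogen-bond content within a synonym family
#'
#' A codon's bond count divided by the maximum bond count among the codons
#' of the same amino acid. Stop codons have no amino-acid family and raise
#' an error.
#'
#' @inheritParams hbond_count
#' @return numeric vector in (0, 1].
#' @examples
#' relative_hbond("TTA") # Leu: 6/8 = 0.75
#' @export
relative_hbond <- function(codon) {
  codon <- .normalize_codon(codon)
  aa <- .codon_lookup(codon, "aa")
  if (any(aa == "*")) {
    stop("no amino-acid family for stop codon: ",
         paste(unique(codon[aa == "*"]), collapse = ", "), call. = FALSE)
  }
  .codon_lookup(codon, "relative_hbond")
}

#' Centered-and-scaled hydrogen-bond content within a synonym family
#'
#' (bond count - family mean) / family standard deviation, over the distinct
#' codons of the amino acid. Single-codon families (Met, Trp) have zero
#' variance and return `NA`.
#'
#' @inheritParams hbond_count
#' @return numeric vector; `NA` for single-codon families.
#' @examples
#' scaled_hbond(c("AAA", "AAG", "ATG")) # -0.707, 0.707, NA
#' @export
scaled_hbond <- function(codon) {
  codon <- .normalize_codon(codon)
  aa <- .codon_lookup(codon, "aa")
  if (any(aa == "*")) {
    stop("no amino-acid family for stop codon: ",
         paste(unique(codon[aa == "*"]), collapse = ", "), call. = FALSE)
  }
  .codon_lookup(codon, "scaled_hbond")
}

#' Maximum synonymous reduction in hydrogen-bond content
#'
#' Over all degenerate amino acids, the largest achievable relative drop in
#' per-codon hydrogen bonds by synonymous substitution:
#' `100 * (1 - min(family)/max(family))`, maximised over families. For the
#' standard code this is 25% (Leu: 6 vs 8 bonds).
#'
#' @param table codon table as returned by [codon_table()]; a restricted
#'   table may be supplied to query hypothetical codes.
#' @return percentage (numeric scalar).
#' @examples
#' max_synonymous_reduction() # 25
#' @export
max_synonymous_reduction <- function(table = codon_table()) {
  fam <- table |>
    dplyr::filter(.data$aa != "*") |>
    dplyr::group_by(.data$aa) |>
    dplyr::summarise(
      reduction = 100 * (1 - min(.data$hbonds) / max(.data$hbonds)),
      .groups = "drop"
    )
  max(fam$reduction)
}
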