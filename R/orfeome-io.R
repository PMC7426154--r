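#' Read an ORFeome from a multi-FASTA file
#'
#' Loads a collection of coding sequences (one record per gene), strips
#' whitespace, uppercases, and converts RNA U to DNA T. No quality control
#' is applied at this stage; see [qc_filter()].
#'
#' @param path path to a (multi-)FASTA nucleotide file.
#' @return A tibble with columns `cds_id`, `seq`, carrying the source path
#'   as the `"provenance"` attribute.
#' @export
read_orfeome <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate CDS id(s) in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- gsub("U", "T", toupper(unname(as.character(set))), fixed = TRUE)
  orf <- tibble::tibble(cds_id = ids, seq = seqs)
  attr(orf, "provenance") <- path
  orf
}

#' Construct an ORFeome tibble from in-memory sequences
#'
#' @param seqs named character vector of CDS nucleotide sequences.
#' @param provenance free-text source label.
#' @return A tibble with columns `cds_id`, `seq`.
#' @export
orfeome <- function(seqs, provenance = "in-memory") {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named by CDS id", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate CDS id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- gsub("\\s", "", toupper(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  orf <- tibble::tibble(cds_id = names(seqs), seq = unname(seqs))
  attr(orf, "provenance") <- provenance
  orf
}

#' Quality-control filter for an ORFeome
#'
#' Retains CDSs that (i) have a length divisible by 3, (ii) still contain at
#' least `n_positions` codons after removal of the start codon, and (iii)
#' carry no ambiguous (non-ACGT) base within the analyzed window (codon
#' positions 2 to `n_positions + 1`). Rejections are logged with a reason
#' per CDS, retrievable with [qc_log()].
#'
#' @param orf an ORFeome tibble (columns `cds_id`, `seq`).
#' @param n_positions number of codon positions to analyze downstream
#'   (typically 100 or 250).
#' @return the filtered ORFeome tibble, with the rejection log as the
#'   `"qc_log"` attribute and `n_positions` recorded as `"n_positions"`.
#' @export
qc_filter <- function(orf, n_positions = 100) {
  stopifnot(n_positions >= 1)
  len <- nchar(orf$seq)
  n_codons <- len %/% 3L
  window_nt <- orf$seq
  # analyzed window: bases 4 .. 3*(n_positions+1)
  window <- substr(window_nt, 4L, 3L * (n_positions + 1L))
  reason <- rep(NA_character_, nrow(orf))
  reason[len %% 3L != 0L] <- "length_not_multiple_of_3"
  too_short <- is.na(reason) & (n_codons < n_positions + 1L)
  reason[too_short] <- "too_short"
  ambiguous <- is.na(reason) & grepl("[^ACGT]", window)
  reason[ambiguous] <- "ambiguous_in_window"
  keep <- is.na(reason)
  if (!any(keep)) {
    stop("empty ORFeome after QC", call. = FALSE)
  }
  log <- tibble::tibble(cds_id = orf$cds_id[!keep], reason = reason[!keep])
  out <- orf[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(orf, "provenance")
  attr(out, "qc_log") <- log
  attr(out, "n_positions") <- n_positions
  out
}

#' Rejection log of the last [qc_filter()] applied to an ORFeome
#'
#' @param orf a QC-filtered ORFeome tibble.
#' @return tibble with columns `cds_id`, `reason` (empty if none rejected).
#' @export
qc_log <- function(orf) {
  log <- attr(orf, "qc_log")
  if (is.null(log)) {
    tibble::tibble(cds_id = character(), reason = character())
  } else {
    log
  }
}

#' Left-aligned per-CDS codon matrix
#'
#' Splits each retained CDS into codons, removes the start codon, and
#' arranges the next `n_positions` codons into a character matrix with one
#' row per CDS. Column `j` holds the codon at original position `j + 1`
#' (position 1 being the start codon); column names carry the original
#' positions.
#'
#' @param orf a QC-filtered ORFeome tibble (see [qc_filter()]).
#' @param n_positions number of codon positions (columns); defaults to the
#'   value recorded by [qc_filter()].
#' @return a character matrix of class `"codon_matrix"` with `cds_id`
#'   rownames, original-position column names, and attribute
#'   `position_offset = 2`.
#' @export
build_codon_matrix <- function(orf, n_positions = attr(orf, "n_positions")) {
  if (is.null(n_positions)) {
    stop("n_positions not given and ORFeome has not been through qc_filter()",
         call. = FALSE)
  }
  starts <- 3L * seq_len(n_positions) + 1L
  stops <- starts + 2L
  m <- t(vapply(orf$seq,
                function(s) substring(s, starts, stops),
                character(n_positions)))
  dimnames(m) <- list(orf$cds_id, as.character(seq_len(n_positions) + 1L))
  attr(m, "position_offset") <- 2L
  class(m) <- c("codon_matrix", class(m))
  m
}

#' Original codon positions covered by a codon matrix
#' @param mat a `codon_matrix`.
#' @return integer vector of original codon positions (start codon = 1).
#' @export
matrix_positions <- function(mat) {
  as.integer(colnames(mat))
}

# Full-length per-CDS codon vectors after start-codon removal; used by the
# shuffling null (synonyms may enter the window from downstream positions).
.cds_codon_list <- function(orf) {
  lapply(orf$seq, function(s) {
    n <- nchar(s) %/% 3L
    starts <- 3L * seq_len(n - 1L) + 1L
    substring(s, starts, starts + 2L)
  })
}

#' Per-CDS composition statistics
#'
#' Length, overall GC content, GC content at each of the three codon
#' positions (GC1, GC2, GC3), and the mutational-bias indicator GC3/GC.
#'
#' @param x an ORFeome tibble or a character vector of CDS sequences with
#'   lengths divisible by 3.
#' @return a tibble with columns `cds_id` (when available), `length_nt`,
#'   `gc`, `gc1`, `gc2`, `gc3`, `mutational_bias`.
#' @examples
#' composition("ATGGCA")
#' @export
composition <- function(x) {
  if (is.data.frame(x)) {
    seqs <- x$seq
    ids <- x$cds_id
  } else {
    seqs <- x
    ids <- NULL
  }
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence", call. = FALSE)
  }
  if (any(nchar(seqs) %% 3L != 0L)) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  gc_frac <- function(s) {
    vapply(s, function(si) {
      b <- strsplit(si, "", fixed = TRUE)[[1]]
      mean(b %in% c("G", "C"))
    }, numeric(1), USE.NAMES = FALSE)
  }
  pos_seq <- function(s, k) {
    vapply(s, function(si) {
      b <- strsplit(si, "", fixed = TRUE)[[1]]
      paste0(b[seq(k, length(b), by = 3L)], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  out <- tibble::tibble(
    length_nt = nchar(seqs),
    gc = gc_frac(seqs),
    gc1 = gc_frac(pos_seq(seqs, 1L)),
    gc2 = gc_frac(pos_seq(seqs, 2L)),
    gc3 = gc_frac(pos_seq(seqs, 3L))
  )
  out$mutational_bias <- ifelse(out$gc > 0, out$gc3 / out$gc, NA_real_)
  if (!is.null(ids)) {
    out <- dplyr::bind_cols(tibble::tibble(cds_id = ids), out)
  }
  out
}
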