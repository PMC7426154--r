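# Shared fixtures, built in code at test time.

# toy ORFeome: named codon vectors (start codon included) -> orfeome tibble
toy_orfeome <- function(codon_lists) {
  seqs <- vapply(codon_lists, paste, character(1), collapse = "")
  orfeome(seqs)
}

# random valid CDS of n codons (incl. ATG start), no stops inside
random_cds <- function(n_codons) {
  tb <- codon_table()
  sense <- tb$codon[tb$aa != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 1, replace = TRUE),
                      collapse = ""))
}

# per-base hydrogen-bond lookup, independent of the package's table
ref_hbond <- function(codon) {
  per_base <- c(A = 2, T = 2, G = 3, C = 3)
  vapply(strsplit(codon, "", fixed = TRUE),
         function(b) sum(per_base[b]), numeric(1))
}

# all permutations of a (small) vector, duplicates included
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in combinat_perms(x[-i])) out <- c(out, list(c(x[i], p)))
  }
  out
}

# cache for expensive acceptance fixtures shared between test blocks
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# independent brute-force RSCU from raw codon counts and the genetic code
ref_rscu <- function(counts) {
  gc <- Biostrings::GENETIC_CODE
  out <- setNames(numeric(length(counts)), names(counts))
  for (a in unique(gc)) {
    fam <- names(gc)[gc == a]
    fam_counts <- counts[fam]
    out[fam] <- if (sum(fam_counts) == 0) 1 else
      fam_counts / mean(fam_counts)
  }
  out
}

# independent literal coding of the canonical tAI adaptiveness recursion
ref_tai <- function(pool, s, sking) {
  bases <- c("T", "C", "A", "G")
  codons <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons <- c(codons, paste0(b1, b2, b3))
  }
  rc <- function(x) {
    chartr("ACGT", "TGCA",
           vapply(strsplit(x, ""), function(b) paste(rev(b), collapse = ""),
                  character(1)))
  }
  tgcn <- setNames(numeric(64), codons)
  for (k in seq_len(nrow(pool))) {
    cod <- rc(pool$anticodon[k])
    tgcn[cod] <- tgcn[cod] + pool$tgcn[k]
  }
  p <- 1 - s
  W <- setNames(numeric(64), codons)
  for (i in seq(1, 61, by = 4)) {
    W[i]     <- p[1] * tgcn[i]     + p[5] * tgcn[i + 1]
    W[i + 1] <- p[2] * tgcn[i + 1] + p[6] * tgcn[i]
    W[i + 2] <- p[3] * tgcn[i + 2] + p[7] * tgcn[i]
    W[i + 3] <- p[4] * tgcn[i + 3] + p[8] * tgcn[i + 2]
  }
  W["ATG"] <- p[4] * tgcn["ATG"]
  if (sking == 1) W["ATA"] <- p[9]
  W <- W[!(names(W) %in% c("TAA", "TAG", "TGA", "ATG"))]
  w <- W / max(W)
  if (any(w == 0)) {
    gm <- exp(mean(log(w[w > 0])))
    w[w == 0] <- gm
  }
  w
}

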