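# Test helpers: an independent brute-force six-frame ORF oracle, random
# sequence generators, and a stand-in precursor carrying the published
# A20-Y25 fragment used by the N-terminal constraint checks.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Brute force: walk forward from every start-codon occurrence to the first
# in-frame stop; for each (strand, stop) keep the most upstream start.
# Deliberately position-by-position and substring-based, unlike the
# codon-array scanner under test.
oracle_orfs <- function(dna, min_aa = 25, starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(dna)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    best <- new.env(parent = emptyenv())
    for (i in seq_len(max(L - 2L, 0L))) {
      if (!(substr(s, i, i + 2L) %in% starts)) next
      j <- i + 3L
      found <- FALSE
      while (j + 2L <= L) {
        if (substr(s, j, j + 2L) %in% stops) { found <- TRUE; break }
        j <- j + 3L
      }
      if (!found) next
      key <- as.character(j)
      prev <- if (exists(key, envir = best)) get(key, envir = best) else Inf
      if (i < prev) assign(key, i, envir = best)
    }
    for (key in ls(best)) {
      j <- as.integer(key)
      i <- get(key, envir = best)
      n_aa <- (j - i) %/% 3L
      if (n_aa < min_aa) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, i, j - 1L)), no.init.codon = TRUE
      ))
      s0 <- i - 1L
      e0 <- j + 2L
      rows[[length(rows) + 1L]] <- data.frame(
        start = if (strand == "+") s0 else L - e0,
        end = if (strand == "+") e0 else L - s0,
        strand = strand,
        aa_seq = aa,
        length_aa = n_aa,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), aa_seq = character(),
                      length_aa = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# 64-residue stand-in precursor whose residues 20-25 are A-D-L-G-D-Y (the
# published fragment around the maturation sites), with a leader motif at
# 15-18 and a Ser/Thr/Cys-rich core.
standin_precursor <- function() {
  seq <- paste0(
    "MKTEQNALVRSGES",            # 1-14
    "FDLD",                      # 15-18 leader motif
    "V",                         # 19
    "ADLGDY",                    # 20-25 published fragment
    "GSSTTCCAGSSTTAAGGWQHKRNEPVMFYLIDGSSTTCAG"  # 26-65 -> trim to 64
  )
  substr(seq, 1, 64)
}
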