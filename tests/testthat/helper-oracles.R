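# Independent oracles. Deliberately written by a different route than the
# package code (expansion sets + substring equality, rather than a per-motif
# regex), so scanner bugs cannot cancel out.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_expansions <- function(consensus) {
  cls <- ORACLE_IUPAC[strsplit(consensus, "")[[1]]]
  apply(do.call(expand.grid, c(cls, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}

# Brute force: test every window of s (and of revcomp(s), mapped back to
# forward coordinates) for membership in the consensus expansion set.
oracle_scan <- function(seq, consensus, strands = "both") {
  words <- oracle_expansions(consensus)
  m <- nchar(consensus)
  n <- nchar(seq)
  hits <- data.frame(offset = integer(0), strand = character(0),
                     matched = character(0), stringsAsFactors = FALSE)
  if (n < m) return(hits)
  subs <- substring(seq, 1:(n - m + 1), m:n)
  if (strands %in% c("both", "forward")) {
    off <- which(subs %in% words) - 1L
    if (length(off) > 0L) {
      hits <- rbind(hits, data.frame(offset = off, strand = "+",
                                     matched = subs[off + 1L],
                                     stringsAsFactors = FALSE))
    }
  }
  if (strands %in% c("both", "reverse")) {
    rc <- oracle_revcomp(seq)
    rsubs <- substring(rc, 1:(n - m + 1), m:n)
    off_rc <- which(rsubs %in% words) - 1L
    if (length(off_rc) > 0L) {
      off <- n - off_rc - m
      hits <- rbind(hits, data.frame(offset = off, strand = "-",
                                     matched = subs[off + 1L],
                                     stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

write_temp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
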