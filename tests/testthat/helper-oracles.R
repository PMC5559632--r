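# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive results by the most literal method available
# and share no code with the package internals they check.

# union-find connected components over an explicit edge predicate
oracle_components <- function(ids, linked) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && linked(ids[i], ids[j])) {
        parent[[find(ids[i])]] <- find(ids[j])
      }
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(split(ids, roots))
}

# literal re-derivation of a ranked gap profile from a matrix row
oracle_max_gap <- function(genome_id, m) {
  vals <- m[genome_id, colnames(m) != genome_id]
  ranked <- c(sort(vals, decreasing = TRUE), 0)
  max(ranked[-length(ranked)] - ranked[-1])
}

# exhaustive Hamming scan of every window on both strands
oracle_hamming_scan <- function(seqchr, consensus, max_mismatch) {
  k <- nchar(consensus)
  n <- nchar(seqchr)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus)))
  sv <- strsplit(seqchr, "")[[1]]
  cv <- strsplit(consensus, "")[[1]]
  rv <- strsplit(rc, "")[[1]]
  hits <- NULL
  for (s in seq_len(n - k + 1)) {
    win <- sv[s:(s + k - 1)]
    mm_f <- sum(win != cv)
    if (mm_f <= max_mismatch) {
      hits <- rbind(hits, data.frame(start = s, strand = "+",
                                     n_mismatches = mm_f))
    }
    mm_r <- sum(win != rv)
    if (mm_r <= max_mismatch) {
      hits <- rbind(hits, data.frame(start = s, strand = "-",
                                     n_mismatches = mm_r))
    }
  }
  hits
}

# dynamic-programming maximal common substrings (forward orientation only);
# returns maximal runs of length >= min_len as (start1, start2, length)
oracle_common_substrings <- function(s1, s2, min_len) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  prev <- integer(m)
  ends <- NULL
  for (i in seq_len(n)) {
    cur <- integer(m)
    eq <- a[i] == b
    cur[eq] <- c(0L, prev)[seq_len(m)][eq] + 1L
    # a run ends at (i, j) when it cannot be extended at (i+1, j+1)
    for (j in which(cur >= min_len)) {
      if (i == n || j == m || a[i + 1] != b[j + 1]) {
        ends <- rbind(ends, data.frame(start1 = i - cur[j] + 1,
                                       start2 = j - cur[j] + 1,
                                       length = cur[j]))
      }
    }
    prev <- cur
  }
  ends
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# random pham profiles drawn from a small pham universe, all non-empty
random_profiles <- function(n_genomes, universe = 1:5) {
  profs <- lapply(seq_len(n_genomes), function(i) {
    sort(sample(universe, sample(seq_along(universe), 1)))
  })
  names(profs) <- sprintf("g%02d", seq_len(n_genomes))
  profs
}

make_gene <- function(gene_id, genome_id, translation, start = 1) {
  gene_record(gene_id, genome_id, start, start + 3 * nchar(translation) - 1,
              "+", translation)
}

# pham-partition label vector (gene_id -> pham_id) from build_phams output
pham_labels <- function(phams) {
  out <- integer(0)
  for (p in phams) out[p$member_gene_ids] <- p$pham_id
  out
}
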