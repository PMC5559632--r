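# Degenerate consensus (stoperator) scanning and attP/attB common-core
# discovery with tRNA-overlap annotation.

#' Published stoperator consensus presets
#'
#' Named 13/14-base asymmetric repressor-binding consensus sequences for
#' three temperate actinobacteriophages, usable directly as the
#' `consensus` argument of [scan_consensus()]. The Phlei preset is 14
#' bases as printed in its source.
#'
#' @format Named character vector (`Che12`, `Phlei`, `KatherineG`).
#' @export
stoperator_presets <- c(
  Che12      = "GGTGGTTGTCAAG",
  Phlei      = "GCTTGGGTGTCAAG",
  KatherineG = "GGGGATTGTCAAG")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a genome for a degenerate consensus site
#'
#' Reports every window whose Hamming distance to the consensus (forward
#' strand) or to its reverse complement (minus strand, when `both_strands`)
#' is at most `max_mismatch`. Substitutions only — no indels. Hit `start`
#' is the 1-based leftmost genomic coordinate of the window on the plus
#' strand for both orientations; `matched_seq` is reported in consensus
#' orientation (reverse-complemented for minus-strand hits).
#'
#' @param genome A [genome_record()] with sequence, or a nucleotide string.
#' @param consensus Unambiguous A/C/G/T consensus of length `>= 6`.
#' @param max_mismatch Maximum allowed substitutions (default 2), smaller
#'   than the consensus length.
#' @param both_strands Scan the minus strand too (default `TRUE`)?
#' @return Data frame of hits sorted by `start` then `strand`:
#'   `genome_id`, `start`, `strand`, `matched_seq`, `n_mismatches`,
#'   `intergenic` (`NA` until [intergenic_filter()] is applied).
#' @export
scan_consensus <- function(genome, consensus, max_mismatch = 2,
                           both_strands = TRUE) {
  if (inherits(genome, "genome_record")) {
    gid <- genome$genome_id; seqchr <- genome$sequence
  } else {
    gid <- "genome"; seqchr <- as.character(genome)
  }
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) {
    stop("consensus must contain only A/C/G/T")
  }
  if (nchar(consensus) < 6) stop("consensus must be at least 6 bases")
  if (max_mismatch >= nchar(consensus)) {
    stop("max_mismatch must be smaller than the consensus length")
  }
  subj <- Biostrings::DNAString(toupper(seqchr))
  one_strand <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
    if (length(hits) == 0) return(NULL)
    seqs <- as.character(hits)
    oriented <- if (strand == "+") seqs else vapply(seqs, revcomp,
                                                    character(1))
    mism <- vapply(oriented, function(s) {
      sum(utf8ToInt(s) != utf8ToInt(consensus))
    }, integer(1))
    data.frame(genome_id = gid, start = Biostrings::start(hits),
               strand = strand, matched_seq = unname(oriented),
               n_mismatches = unname(mism), intergenic = NA,
               stringsAsFactors = FALSE)
  }
  out <- one_strand(consensus, "+")
  if (both_strands) {
    out <- rbind(out, one_strand(revcomp(consensus), "-"))
  }
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), start = integer(),
                      strand = character(), matched_seq = character(),
                      n_mismatches = integer(), intergenic = logical(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate or filter motif hits by genic overlap
#'
#' A hit is intergenic iff no base of it lies within any gene's
#' `[start, end]` interval (any overlap, even a single base, makes it
#' genic).
#'
#' @param hits Hit data frame from [scan_consensus()].
#' @param genes List of [gene_record()] objects for the scanned genome.
#' @param remove_genic Drop genic hits instead of annotating (default
#'   `FALSE`)?
#' @return The hit data frame with `intergenic` set.
#' @export
intergenic_filter <- function(hits, genes, remove_genic = FALSE) {
  if (nrow(hits) == 0) return(hits)
  gids <- unique(vapply(genes, `[[`, character(1), "genome_id"))
  if (length(genes) && !all(unique(hits$genome_id) %in% gids)) {
    stop("gene list does not cover scanned genome(s): ",
         paste(setdiff(unique(hits$genome_id), gids), collapse = ", "))
  }
  width <- nchar(hits$matched_seq)
  hit_end <- hits$start + width - 1
  genic <- rep(FALSE, nrow(hits))
  for (g in genes) {
    same <- hits$genome_id == g$genome_id
    genic <- genic | (same & hits$start <= g$end & hit_end >= g$start)
  }
  hits$intergenic <- !genic
  if (remove_genic) hits <- hits[hits$intergenic, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# maximal exact common substrings of length >= k between two strings,
# found by merging diagonal runs of shared k-mers
maximal_common_substrings <- function(s1, s2, k) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < k || n2 < k) return(NULL)
  k1 <- substring(s1, 1:(n1 - k + 1), k:n1)
  k2 <- substring(s2, 1:(n2 - k + 1), k:n2)
  shared <- intersect(k1, k2)
  if (length(shared) == 0) return(NULL)
  pos1 <- split(seq_along(k1), k1)[shared]
  pos2 <- split(seq_along(k2), k2)[shared]
  pairs <- do.call(rbind, lapply(seq_along(shared), function(t) {
    expand.grid(i = pos1[[t]], j = pos2[[t]])
  }))
  d <- pairs$j - pairs$i
  runs <- lapply(split(pairs$i, d), function(is) {
    is <- sort(is)
    breaks <- c(0, which(diff(is) > 1), length(is))
    lapply(seq_len(length(breaks) - 1), function(r) {
      c(is[breaks[r] + 1], is[breaks[r + 1]])
    })
  })
  out <- do.call(rbind, lapply(names(runs), function(dd) {
    do.call(rbind, lapply(runs[[dd]], function(run) {
      i0 <- run[1]; i1 <- run[2] + k - 1
      data.frame(start1 = i0, end1 = i1,
                 start2 = i0 + as.integer(dd), end2 = i1 + as.integer(dd),
                 length = i1 - i0 + 1)
    }))
  }))
  unique(out)
}

#' Find attachment-site common cores between a phage and a host genome
#'
#' Reports maximal exact common substrings of the phage sequence (both
#' orientations) and the host sequence with length at least `min_len`.
#' Cores longer than `max_len` are reported whole, flagged `long_core`,
#' rather than truncated. Each core is reported once per (phage locus,
#' host locus) pair, sorted by descending length. `core_seq` is given on
#' the host plus strand; `orientation = "reverse"` means the phage carries
#' its reverse complement.
#'
#' @param phage_seq,host_seq Nucleotide strings, each of length
#'   `>= min_len`.
#' @param min_len Minimum core length in bp (default 20, must be `>= 12`).
#' @param max_len Length above which a core is flagged long (default 40).
#' @return Data frame: `core_seq`, `length`, `phage_start`, `phage_end`,
#'   `host_start`, `host_end`, `orientation`, `long_core`, plus
#'   `trna_overlap`/`trna_locus` columns initialized to `NA` for
#'   [annotate_trna_overlap()].
#' @export
find_att_cores <- function(phage_seq, host_seq, min_len = 20, max_len = 40) {
  if (min_len < 12) stop("min_len must be at least 12")
  if (max_len < min_len) stop("max_len must be >= min_len")
  phage_seq <- toupper(phage_seq); host_seq <- toupper(host_seq)
  if (nchar(phage_seq) < min_len || nchar(host_seq) < min_len) {
    stop("sequence shorter than min_len = ", min_len)
  }
  lp <- nchar(phage_seq)
  fwd <- maximal_common_substrings(phage_seq, host_seq, min_len)
  rc <- maximal_common_substrings(revcomp(phage_seq), host_seq, min_len)
  rows <- list()
  if (!is.null(fwd)) {
    rows$fwd <- data.frame(
      core_seq = substring(host_seq, fwd$start2, fwd$end2),
      length = fwd$length,
      phage_start = fwd$start1, phage_end = fwd$end1,
      host_start = fwd$start2, host_end = fwd$end2,
      orientation = "same", stringsAsFactors = FALSE)
  }
  if (!is.null(rc)) {
    rows$rc <- data.frame(
      core_seq = substring(host_seq, rc$start2, rc$end2),
      length = rc$length,
      phage_start = lp - rc$end1 + 1, phage_end = lp - rc$start1 + 1,
      host_start = rc$start2, host_end = rc$end2,
      orientation = "reverse", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(core_seq = character(), length = integer(),
                      phage_start = integer(), phage_end = integer(),
                      host_start = integer(), host_end = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  }
  out <- unique(out)
  out$long_core <- out$length > max_len
  out$trna_overlap <- rep(NA, nrow(out))
  out$trna_locus <- rep(NA_character_, nrow(out))
  out <- out[order(-out$length, out$phage_start, out$host_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate att cores with host tRNA overlap
#'
#' A core overlaps a tRNA when its host interval intersects (by at least
#' one base) a host feature of type `"tRNA"`; the overlapping feature's
#' locus tag is recorded (first by coordinate on ties).
#'
#' @param cores Core data frame from [find_att_cores()].
#' @param host_features Data frame with columns `locus_tag`, `type`,
#'   `start`, `end` (1-based inclusive).
#' @return `cores` with `trna_overlap` and `trna_locus` filled in.
#' @export
annotate_trna_overlap <- function(cores, host_features) {
  if (nrow(cores) == 0) {
    cores$trna_overlap <- logical(0)
    return(cores)
  }
  trnas <- host_features[host_features$type == "tRNA", , drop = FALSE]
  trnas <- trnas[order(trnas$start), , drop = FALSE]
  cores$trna_overlap <- FALSE
  cores$trna_locus <- NA_character_
  for (i in seq_len(nrow(cores))) {
    ov <- which(trnas$start <= cores$host_end[i] &
                trnas$end >= cores$host_start[i])
    if (length(ov)) {
      cores$trna_overlap[i] <- TRUE
      cores$trna_locus[i] <- trnas$locus_tag[ov[1]]
    }
  }
  cores
}
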