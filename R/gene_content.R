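# Gene content dissimilarity (GCD), rank-ordered gap profiles and the
# MaxGCDGap statistic, band-fraction statistics, and multi-host pham sharing.

#' Per-genome pham profiles
#'
#' Collapses a gene list with pham assignments into one presence/absence
#' pham set per genome (duplicate phams within a genome are collapsed).
#'
#' @param genes List of [gene_record()] objects with `pham_id` set, or a
#'   data frame with columns `genome_id` and `pham_id`.
#' @return Named list mapping `genome_id` to a sorted integer vector of
#'   distinct pham ids.
#' @export
pham_profiles <- function(genes) {
  if (is.data.frame(genes)) {
    gid <- genes$genome_id; pid <- genes$pham_id
  } else {
    gid <- vapply(genes, `[[`, character(1), "genome_id")
    pid <- vapply(genes, `[[`, integer(1), "pham_id")
  }
  if (anyNA(pid)) stop("gene(s) without pham assignment")
  lapply(split(pid, gid), function(v) sort(unique(v)))
}

#' Gene content dissimilarity between two pham profiles
#'
#' The proportion of shared phams is computed relative to each genome's
#' total pham count, the two directed proportions are averaged, and the
#' average is subtracted from 1:
#' \deqn{GCD(A, B) = 1 - \frac{S/|A| + S/|B|}{2}, \quad S = |A \cap B|.}
#' GCD is 0 only when the two profiles are identical sets and 1 exactly
#' when they share no phams.
#'
#' @param a,b Non-empty vectors of pham ids (one genome each).
#' @return Dissimilarity fraction in `[0, 1]`.
#' @export
gcd <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("GCD is undefined for an empty pham profile")
  }
  s <- length(intersect(a, b))
  1 - (s / length(a) + s / length(b)) / 2
}

#' All-pairs GCD matrix
#'
#' @param profiles Named list of pham-id vectors as returned by
#'   [pham_profiles()]; at least two genomes, all non-empty, unique ids.
#' @return Symmetric matrix of GCD values with zero diagonal and genome ids
#'   as dimnames, rows/columns in the order of `profiles`.
#' @export
gcd_matrix <- function(profiles) {
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("profiles must be uniquely named by genome_id")
  }
  if (length(profiles) < 2) stop("need at least 2 profiles")
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- gcd(profiles[[i]], profiles[[j]])
    }
  }
  m
}

#' Rank-ordered GCD gap profile for one genome
#'
#' The genome's GCD values against every other genome are sorted in
#' descending order and the self-comparison value 0 is appended as the
#' final element; the gaps are the differences between consecutive ranked
#' values and MaxGCDGap is the largest gap. A genome sharing nothing with
#' any other genome therefore has MaxGCDGap 1 (the drop from 1 to its self
#' value), while a genome with a close relative has a small final gap.
#' Ties are ordered by genome id; tie order does not affect gap values.
#'
#' @param genome_id Genome to profile.
#' @param matrix GCD matrix from [gcd_matrix()].
#' @return A list with `genome_id`, `ranked_gcds` (named, `"self"` last),
#'   `gaps`, `max_gap`, and `max_gap_pair` (the two neighbours flanking the
#'   maximal gap; `"self"` allowed).
#' @export
gap_profile <- function(genome_id, matrix) {
  check_symmetric(matrix)
  if (nrow(matrix) < 2) stop("matrix must contain at least 2 genomes")
  if (!genome_id %in% rownames(matrix)) {
    stop("unknown genome_id '", genome_id, "'")
  }
  row <- matrix[genome_id, ]
  row <- row[setdiff(names(row), genome_id)]
  ord <- order(-row, names(row))
  ranked <- c(row[ord], self = 0)
  gaps <- -diff(unname(ranked))
  k <- which.max(gaps)
  list(genome_id = genome_id, ranked_gcds = ranked, gaps = gaps,
       max_gap = gaps[k], max_gap_pair = names(ranked)[c(k, k + 1)])
}

#' MaxGCDGap for every genome
#'
#' @param matrix GCD matrix from [gcd_matrix()].
#' @return Named numeric vector mapping genome_id to its MaxGCDGap.
#' @export
max_gcd_gap_all <- function(matrix) {
  check_symmetric(matrix)
  vapply(rownames(matrix), function(g) gap_profile(g, matrix)$max_gap,
         numeric(1))
}

#' Mid-range GCD band statistics
#'
#' Counts the unordered genome pairs whose GCD falls inside the inclusive
#' band `[lo, hi]` — the mid-range comparisons that distinguish a smooth
#' spectrum of relatedness from well-separated groups.
#'
#' @param matrix GCD matrix.
#' @param lo,hi Band bounds, `0 <= lo < hi <= 1` (defaults 0.3 and 0.7).
#' @param groups Optional named vector mapping genome_id to a group label
#'   (cluster or singleton); when given, participating groups are reported.
#' @return List with `n_pairs_total`, `n_pairs_in_band`, `fraction_in_band`,
#'   `participating_genomes` (genomes in at least one in-band pair) and
#'   `participating_groups` (when `groups` supplied).
#' @export
band_statistics <- function(matrix, lo = 0.3, hi = 0.7, groups = NULL) {
  check_symmetric(matrix)
  if (lo >= hi) stop("band bounds require lo < hi")
  if (lo < 0 || hi > 1) stop("band bounds must lie in [0, 1]")
  ids <- rownames(matrix)
  ut <- upper.tri(matrix)
  vals <- matrix[ut]
  in_band <- vals >= lo & vals <= hi
  pair_idx <- which(ut, arr.ind = TRUE)[in_band, , drop = FALSE]
  participants <- sort(unique(ids[as.vector(pair_idx)]))
  out <- list(n_pairs_total = length(vals),
              n_pairs_in_band = sum(in_band),
              fraction_in_band = if (length(vals)) sum(in_band) / length(vals)
                                 else 0,
              participating_genomes = participants)
  if (!is.null(groups)) {
    out$participating_groups <- sort(unique(unname(groups[participants])))
  }
  out
}

#' Pham sharing across host sets
#'
#' For phage collections grouped by bacterial host, computes the exclusive
#' Venn regions of pham content: for every non-empty subset of hosts, the
#' number of phams present in at least one genome of every host in the
#' subset and absent from all genomes of every host outside it. Region
#' counts sum to the total number of distinct phams.
#'
#' @param profiles_by_host Named list (one element per host, at least two)
#'   of profile lists as returned by [pham_profiles()].
#' @return List with `total_phams` and `regions`, a data frame with
#'   `hosts` (host names joined by `"+"`), `n_hosts`, and `n_phams`.
#' @export
host_set_sharing <- function(profiles_by_host) {
  hosts <- names(profiles_by_host)
  if (length(hosts) < 2) stop("need at least 2 host groups")
  if (any(lengths(profiles_by_host) == 0)) stop("empty host group")
  all_genomes <- unlist(lapply(profiles_by_host, names))
  if (anyDuplicated(all_genomes)) {
    stop("genome(s) appear under more than one host: ",
         paste(unique(all_genomes[duplicated(all_genomes)]), collapse = ", "))
  }
  union_by_host <- lapply(profiles_by_host,
                          function(p) sort(unique(unlist(p))))
  total <- length(unique(unlist(union_by_host)))
  nh <- length(hosts)
  subsets <- lapply(seq_len(2^nh - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(nh) - 1)) > 0)
  })
  regions <- do.call(rbind, lapply(subsets, function(inset) {
    outset <- setdiff(seq_len(nh), inset)
    phs <- Reduce(intersect, union_by_host[inset])
    if (length(outset)) {
      phs <- setdiff(phs, unique(unlist(union_by_host[outset])))
    }
    data.frame(hosts = paste(hosts[inset], collapse = "+"),
               n_hosts = length(inset), n_phams = length(phs),
               stringsAsFactors = FALSE)
  }))
  list(total_phams = total, regions = regions)
}

#' Export per-genome gap profiles as TSV
#'
#' @param matrix GCD matrix.
#' @param path Output TSV path (`genome`, `rank`, `neighbor`, `gcd`, `gap`).
#' @export
write_gap_profiles <- function(matrix, path) {
  rows <- do.call(rbind, lapply(rownames(matrix), function(g) {
    gp <- gap_profile(g, matrix)
    n <- length(gp$ranked_gcds)
    data.frame(genome = g, rank = seq_len(n),
               neighbor = names(gp$ranked_gcds),
               gcd = unname(gp$ranked_gcds),
               gap = c(unname(gp$gaps), NA), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
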