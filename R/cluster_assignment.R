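# Shared-gene-content cluster assignment, fragment-based ANI and
# subclustering, and genometric summaries of a metadata table.

#' Assign phages to clusters by shared gene content
#'
#' Two phages are linked when they share at least `1 - threshold_gcd` of
#' their genes, i.e. when their GCD is at most `threshold_gcd` (default
#' 0.65, the 35%-shared-genes rule). Clusters are the connected components
#' of this share graph — membership requires at least one sufficiently
#' close co-member, not closeness to all members — and components of size 1
#' are singletons.
#'
#' @param matrix GCD matrix from [gcd_matrix()].
#' @param threshold_gcd GCD threshold in `(0, 1)` (default 0.65).
#' @return An object of class `cluster_result`: list with `assignment`
#'   (named vector genome_id -> label `"C1"`, `"C2"`, ... or
#'   `"SINGLETON"`), `clusters` (list of member-id vectors, multi-member
#'   components only, labelled), and `threshold_gcd`. Cluster labels are
#'   numbered by each component's smallest member genome_id.
#' @export
assign_clusters <- function(matrix, threshold_gcd = 0.65) {
  check_symmetric(matrix)
  if (threshold_gcd <= 0 || threshold_gcd >= 1) {
    stop("threshold_gcd must be in (0, 1)")
  }
  ids <- rownames(matrix)
  adj <- matrix <= threshold_gcd
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- split(ids, comp)
  multi <- members[lengths(members) > 1]
  multi <- multi[order(vapply(multi, min, character(1)))]
  assignment <- stats::setNames(rep("SINGLETON", length(ids)), ids)
  clusters <- list()
  for (i in seq_along(multi)) {
    lab <- paste0("C", i)
    assignment[multi[[i]]] <- lab
    clusters[[lab]] <- sort(multi[[i]])
  }
  structure(list(assignment = assignment, clusters = clusters,
                 threshold_gcd = threshold_gcd),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  n <- length(x$assignment)
  ns <- sum(x$assignment == "SINGLETON")
  cat("<cluster_result> ", n, " genomes: ", length(x$clusters),
      " cluster(s), ", ns, " singleton(s) at GCD <= ", x$threshold_gcd,
      "\n", sep = "")
  invisible(x)
}

#' Fragment-based average nucleotide identity
#'
#' The query `a` is cut into consecutive windows of `fragment_bp` bases
#' (the trailing partial window is dropped); each fragment is aligned at
#' its best location in `b` (global on the fragment, local on the subject)
#' and its percent identity recorded. Fragments reaching `min_identity`
#' count as aligned; ANI is the mean identity of aligned fragments. The
#' measure is query-directed: report the mean of both directions when a
#' symmetric value is wanted.
#'
#' @param a Query nucleotide string (length `>= fragment_bp`).
#' @param b Subject nucleotide string.
#' @param fragment_bp Fragment width in bp (default 1000).
#' @param min_identity Identity floor in `[0, 1]` for a fragment to count
#'   as aligned (default 0.7).
#' @return List with `ani_percent` (0-100 scale; `NA` when no fragment
#'   aligns) and `aligned_fraction` (aligned fragments / total fragments).
#' @export
compute_ani <- function(a, b, fragment_bp = 1000, min_identity = 0.7) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < fragment_bp || nchar(b) < fragment_bp) {
    stop("sequence shorter than fragment_bp = ", fragment_bp,
         "; use a smaller fragment size")
  }
  n_frag <- nchar(a) %/% fragment_bp
  starts <- (seq_len(n_frag) - 1) * fragment_bp + 1
  frags <- Biostrings::DNAStringSet(substring(a, starts,
                                              starts + fragment_bp - 1))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    frags, Biostrings::DNAString(b), type = "global-local",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 4)
  ident <- Biostrings::pid(aln, type = "PID1") / 100
  aligned <- ident >= min_identity
  list(ani_percent = if (any(aligned)) mean(ident[aligned]) * 100
                     else NA_real_,
       aligned_fraction = mean(aligned))
}

#' Subdivide a cluster by average nucleotide identity
#'
#' Subclusters are the connected components of the graph with an edge
#' between two members iff their (two-direction mean) ANI is at least
#' `ani_percent_cut` and the mean aligned fraction is at least
#' `min_aligned`. Labels append 1, 2, ... to the cluster label in order of
#' each component's smallest member id; a cluster forming one component is
#' reported undivided (label equal to the cluster label).
#'
#' @param cluster_members List of [genome_record()] objects with sequences.
#' @param cluster_label Base cluster label used for subcluster names.
#' @param ani_percent_cut ANI cutoff on the 0-100 scale (default 95).
#' @param min_aligned Minimum aligned fraction in `[0, 1]` (default 0.5).
#' @param fragment_bp Fragment width passed to [compute_ani()].
#' @return Named character vector genome_id -> subcluster label.
#' @export
assign_subclusters <- function(cluster_members, cluster_label = "C",
                               ani_percent_cut = 95.0, min_aligned = 0.5,
                               fragment_bp = 1000) {
  ids <- vapply(cluster_members, `[[`, character(1), "genome_id")
  seqs <- vapply(cluster_members, `[[`, character(1), "sequence")
  if (anyNA(seqs)) {
    stop("member(s) without sequence: ", paste(ids[is.na(seqs)],
                                               collapse = ", "))
  }
  n <- length(ids)
  if (n == 1) return(stats::setNames(cluster_label, ids))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ab <- compute_ani(seqs[i], seqs[j], fragment_bp = fragment_bp)
      ba <- compute_ani(seqs[j], seqs[i], fragment_bp = fragment_bp)
      ani <- mean(c(ab$ani_percent, ba$ani_percent), na.rm = TRUE)
      afr <- mean(c(ab$aligned_fraction, ba$aligned_fraction))
      adj[i, j] <- adj[j, i] <- !is.nan(ani) && ani >= ani_percent_cut &&
        afr >= min_aligned
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- split(ids, comp)
  if (length(members) == 1) {
    return(stats::setNames(rep(cluster_label, n), ids))
  }
  members <- members[order(vapply(members, min, character(1)))]
  out <- character(0)
  for (i in seq_along(members)) {
    out[members[[i]]] <- paste0(cluster_label, i)
  }
  out[ids]
}

#' Genometric summary of a metadata table
#'
#' Summarizes genome-length and GC ranges and the cluster structure of a
#' collection. Cluster counting normalizes subcluster labels to their base
#' cluster (trailing digits stripped, so `A15 -> A`); a base cluster counts
#' as subdivided when at least two distinct subcluster labels appear among
#' the records.
#'
#' @param records List of [genome_record()] metadata records.
#' @return A list with `n_genomes`, `min_length_bp`, `max_length_bp`,
#'   `min_gc_percent`, `max_gc_percent`, `n_clusters`, `n_clustered`,
#'   `n_singletons`, `n_clusters_with_subclusters`, `n_groups`
#'   (`n_clusters + n_singletons`) and `dtr_lengths` (sorted unique direct
#'   terminal repeat lengths observed).
#' @export
genometrics_summary <- function(records) {
  if (length(records) == 0) stop("empty record list")
  lens <- vapply(records, `[[`, integer(1), "length_bp")
  gcs <- vapply(records, `[[`, numeric(1), "gc_percent")
  clusters <- vapply(records, `[[`, character(1), "cluster_label")
  subs <- vapply(records, `[[`, character(1), "subcluster_label")
  is_singleton <- clusters == "SINGLETON"
  base <- clusters[!is_singleton]
  subs_cl <- subs[!is_singleton]
  with_sub <- vapply(split(subs_cl, base), function(v) {
    length(unique(v[!is.na(v)])) >= 2
  }, logical(1))
  dtr <- unlist(lapply(records, function(r) {
    if (identical(r$end_type$type, "dtr")) r$end_type$n else NULL
  }))
  n_clusters <- length(unique(base))
  n_singletons <- sum(is_singleton)
  list(n_genomes = length(records),
       min_length_bp = min(lens), max_length_bp = max(lens),
       min_gc_percent = min(gcs), max_gc_percent = max(gcs),
       n_clusters = n_clusters,
       n_clustered = sum(!is_singleton),
       n_singletons = n_singletons,
       n_clusters_with_subclusters = sum(with_sub),
       n_groups = n_clusters + n_singletons,
       dtr_lengths = sort(unique(dtr)))
}
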