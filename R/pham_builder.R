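# Phamily (pham) construction: alignment-free grouping of phage protein
# sequences into families by k-mer set similarity with single-linkage merging.

aa_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than word length k = ", k)
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Alignment-free protein similarity
#'
#' Jaccard index of the two sequences' k-mer (k-length subword) sets:
#' 1 for identical sequences, 0 when no k-mer is shared. Symmetric in its
#' arguments.
#'
#' @param a,b Amino-acid sequence strings, each of length `>= k`.
#' @param k Word length (default 4).
#' @return Similarity fraction in `[0, 1]`.
#' @export
protein_similarity <- function(a, b, k = 4) {
  ka <- aa_kmers(a, k)
  kb <- aa_kmers(b, k)
  inter <- length(intersect(ka, kb))
  inter / (length(ka) + length(kb) - inter)
}

#' Group genes into phamilies (phams)
#'
#' Phams are the connected components of the similarity graph with an edge
#' between two genes iff their [protein_similarity()] is at least
#' `threshold` (single linkage, so relatedness is transitive within a pham).
#' Pham ids are assigned 1..N in order of each component's lexicographically
#' smallest gene id, making the output independent of input order.
#'
#' @param genes List of [gene_record()] objects with valid translations.
#' @param k Word length for the k-mer similarity (default 4).
#' @param threshold Similarity threshold in `(0, 1]` (default 0.5).
#' @return A list of `pham` objects, each `list(pham_id, member_gene_ids,
#'   size)`, ordered by `pham_id`. Empty input yields an empty list.
#' @export
build_phams <- function(genes, k = 4, threshold = 0.5) {
  if (length(genes) == 0) return(list())
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id in input")
  ord <- order(gene_ids)
  gene_ids <- gene_ids[ord]
  seqs <- vapply(genes, `[[`, character(1), "translation")[ord]
  n <- length(seqs)

  kmer_sets <- lapply(seqs, aa_kmers, k = k)
  # inverted index: only gene pairs sharing >= 1 k-mer can reach threshold > 0
  idx <- rep.int(seq_len(n), lengths(kmer_sets))
  by_kmer <- split(idx, unlist(kmer_sets))
  cand <- unique(do.call(rbind, lapply(by_kmer, function(v) {
    if (length(v) < 2) return(NULL)
    t(utils::combn(v, 2))
  })))

  edges <- NULL
  if (!is.null(cand) && nrow(cand)) {
    sizes <- lengths(kmer_sets)
    keep <- vapply(seq_len(nrow(cand)), function(r) {
      i <- cand[r, 1]; j <- cand[r, 2]
      inter <- length(intersect(kmer_sets[[i]], kmer_sets[[j]]))
      inter / (sizes[i] + sizes[j] - inter) >= threshold
    }, logical(1))
    edges <- cand[keep, , drop = FALSE]
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  members <- split(gene_ids, comp)
  # number components by their smallest member gene_id
  members <- members[order(vapply(members, min, character(1)))]
  lapply(seq_along(members), function(i) {
    structure(list(pham_id = i,
                   member_gene_ids = sort(unname(members[[i]])),
                   size = length(members[[i]])),
              class = "pham")
  })
}

#' Summarize a pham partition
#'
#' @param phams List of `pham` objects forming a partition of the genes.
#' @return A list with `n_genes`, `n_phams`, `mean_pham_size` (0 for empty
#'   input) and `n_orphams` (phams of size 1).
#' @export
pham_summary <- function(phams) {
  if (length(phams) == 0) {
    return(list(n_genes = 0L, n_phams = 0L, mean_pham_size = 0,
                n_orphams = 0L))
  }
  all_ids <- unlist(lapply(phams, `[[`, "member_gene_ids"))
  if (anyDuplicated(all_ids)) {
    stop("phams overlap: gene(s) ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         " appear in more than one pham")
  }
  sizes <- vapply(phams, function(p) as.integer(p$size), integer(1))
  list(n_genes = sum(sizes), n_phams = length(phams),
       mean_pham_size = sum(sizes) / length(phams),
       n_orphams = sum(sizes == 1L))
}

#' Write a gene-to-pham assignment table
#'
#' @param phams List of `pham` objects.
#' @param path Output TSV path (`gene_id`, `pham_id`).
#' @export
write_pham_table <- function(phams, path) {
  df <- do.call(rbind, lapply(phams, function(p) {
    data.frame(gene_id = p$member_gene_ids, pham_id = p$pham_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(gene_id = character(), pham_id = integer())
  utils::write.table(df[order(df$gene_id), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
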