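#' Construct a phage genome record
#'
#' A `genome_record` bundles the identity, (optional) nucleotide sequence and
#' metadata of a single phage genome: genome length, GC content on the 0-100
#' scale, the physical genome-end type, and cluster/subcluster membership.
#'
#' @param genome_id Genome name (unique within a collection).
#' @param sequence Nucleotide sequence string (A/C/G/T/N), or `NA` when only
#'   metadata is known.
#' @param length_bp Genome length in bp; derived from `sequence` when present.
#' @param gc_percent GC content on the 0-100 scale; ambiguous bases are
#'   excluded from both numerator and denominator when computed from sequence.
#' @param host_genus,host_species,host_strain Host taxonomy strings.
#' @param end_type A list describing the genome end, as returned by
#'   [parse_end_type()]: `list(type = ..., n = ...)` where `type` is one of
#'   `"three_prime_ext"`, `"five_prime_ext"`, `"circularly_permuted"`,
#'   `"dtr"`, `"unknown"` and `n` is the extension/repeat length (or `NA`).
#' @param cluster_label Cluster label, or `"SINGLETON"`.
#' @param subcluster_label Subcluster label (e.g. `"CS2"`), or `NA`.
#' @param accession Sequence database accession, or `NA`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, sequence = NA_character_,
                          length_bp = NULL, gc_percent = NULL,
                          host_genus = NA_character_,
                          host_species = NA_character_,
                          host_strain = NA_character_,
                          end_type = list(type = "unknown", n = NA_integer_),
                          cluster_label = NA_character_,
                          subcluster_label = NA_character_,
                          accession = NA_character_) {
  if (!is.na(sequence)) {
    sequence <- toupper(sequence)
    bad <- gsub("[ACGTN]", "", sequence)
    if (nzchar(bad)) {
      stop("genome '", genome_id, "': non-IUPAC character(s) in sequence: ",
           substr(bad, 1, 10))
    }
    if (is.null(length_bp)) length_bp <- nchar(sequence)
    if (length_bp != nchar(sequence)) {
      stop("genome '", genome_id, "': length_bp does not match sequence length")
    }
    if (is.null(gc_percent)) gc_percent <- gc_percent_of(sequence)
  }
  if (!is.null(gc_percent) && !is.na(gc_percent) &&
      (gc_percent < 0 || gc_percent > 100)) {
    stop("genome '", genome_id, "': gc_percent outside [0, 100]")
  }
  structure(list(
    genome_id = as.character(genome_id),
    sequence = sequence,
    length_bp = as.integer(length_bp),
    gc_percent = if (is.null(gc_percent)) NA_real_ else as.numeric(gc_percent),
    host_genus = host_genus, host_species = host_species,
    host_strain = host_strain,
    end_type = end_type,
    cluster_label = cluster_label, subcluster_label = subcluster_label,
    accession = accession
  ), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$genome_id,
      sprintf("(%s bp, %.1f%% GC)", format(x$length_bp, big.mark = ","),
              x$gc_percent), "\n")
  if (!is.na(x$cluster_label)) {
    cat("  cluster:", x$cluster_label,
        if (!is.na(x$subcluster_label)) paste0("(", x$subcluster_label, ")"),
        "\n")
  }
  invisible(x)
}

#' GC content of a nucleotide string
#'
#' Computed as `100 * (G + C) / (A + C + G + T)`; ambiguous bases (N) are
#' excluded from numerator and denominator.
#'
#' @param sequence Nucleotide string.
#' @return GC percentage on the 0-100 scale.
#' @export
gc_percent_of <- function(sequence) {
  s <- Biostrings::DNAString(toupper(sequence))
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  100 * (f[["C"]] + f[["G"]]) / denom
}

#' Read phage genomes from a FASTA file
#'
#' @param path Path to a FASTA file of nucleotide sequences.
#' @return A list of [genome_record()] objects carrying sequence, derived
#'   length and derived GC content only.
#' @export
read_genome_fasta <- function(path) {
  # read as raw strings first: the DNA reader silently drops invalid
  # letters, and we want to reject them with the offending record named
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0)) {
    stop("empty sequence for record(s): ",
         paste(ids[Biostrings::width(set) == 0], collapse = ", "))
  }
  lapply(seq_along(set), function(i) {
    seq <- toupper(as.character(set[[i]]))
    bad <- gsub("[ACGTN]", "", seq)
    if (nzchar(bad)) {
      stop("non-IUPAC character(s) in record '", ids[i], "'")
    }
    genome_record(genome_id = ids[i], sequence = seq)
  })
}

#' Write genome records to FASTA
#'
#' @param genomes List of [genome_record()] objects with sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genomes, path) {
  seqs <- vapply(genomes, function(g) {
    if (is.na(g$sequence)) stop("genome '", g$genome_id, "' has no sequence")
    g$sequence
  }, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- vapply(genomes, `[[`, character(1), "genome_id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct an annotated-gene record
#'
#' @param gene_id,genome_id Identifiers.
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @param translation Amino-acid sequence (non-empty).
#' @param pham_id Assigned pham id, or `NA` before pham construction.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(gene_id, genome_id, start, end, strand, translation,
                        pham_id = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start) {
    stop("gene '", gene_id, "': invalid coordinates [", start, ", ", end, "]")
  }
  if (!strand %in% c("+", "-")) {
    stop("gene '", gene_id, "': unknown strand symbol '", strand, "'")
  }
  if (is.na(translation) || !nzchar(translation)) {
    stop("gene '", gene_id, "': empty translation")
  }
  structure(list(gene_id = as.character(gene_id),
                 genome_id = as.character(genome_id),
                 start = start, end = end, strand = strand,
                 translation = toupper(translation),
                 pham_id = as.integer(pham_id)),
            class = "gene_record")
}

#' Read a gene table (TSV or GFF3)
#'
#' The TSV dialect has columns `gene_id`, `genome_id`, `start`, `end`,
#' `strand`, `translation`. The GFF3 dialect uses 1-based inclusive
#' coordinates with the protein sequence in a `translation` attribute; the
#' seqid column identifies the genome and the `ID` attribute the gene.
#'
#' @param path Path to the gene table.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param genomes Optional list of [genome_record()]; when supplied, gene
#'   coordinates are validated against genome lengths.
#' @return A list of [gene_record()] objects.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"), genomes = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "genome_id", "start", "end", "strand", "translation")
    missing <- setdiff(need, names(tab))
    if (length(missing)) {
      stop("gene TSV missing column(s): ", paste(missing, collapse = ", "))
    }
    genes <- lapply(seq_len(nrow(tab)), function(i) {
      gene_record(tab$gene_id[i], tab$genome_id[i], tab$start[i], tab$end[i],
                  tab$strand[i], tab$translation[i])
    })
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    if (is.null(md$translation)) {
      stop("GFF3 gene table lacks a 'translation' attribute")
    }
    ids <- if (!is.null(md$ID)) as.character(md$ID) else
      paste0("gene", seq_along(gr))
    genes <- lapply(seq_along(gr), function(i) {
      gene_record(ids[i], as.character(GenomicRanges::seqnames(gr)[i]),
                  GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
                  as.character(GenomicRanges::strand(gr)[i]),
                  as.character(md$translation[i]))
    })
  }
  if (!is.null(genomes)) {
    lens <- stats::setNames(
      vapply(genomes, `[[`, integer(1), "length_bp"),
      vapply(genomes, `[[`, character(1), "genome_id"))
    for (g in genes) {
      if (g$genome_id %in% names(lens) && g$end > lens[[g$genome_id]]) {
        stop("gene '", g$gene_id, "' extends beyond genome '", g$genome_id,
             "' (", lens[[g$genome_id]], " bp)")
      }
    }
  }
  genes
}

#' Parse a printed genome-end description
#'
#' Recognizes the descriptions used in phage genome tables: single-stranded
#' extensions (`"3' 10-base ext."`, `"5' 16-base ext."`), circular
#' permutation (`"Cir. Perm"`), direct terminal repeats (`"191-bp DTR"`,
#' `"1,182-bp DTR"`), and `"?"` for unknown.
#'
#' @param x Character string.
#' @return `list(type = ..., n = ...)`; unparseable strings map to
#'   `type = "unknown"` with a warning.
#' @export
parse_end_type <- function(x) {
  x <- trimws(x)
  x2 <- chartr("′", "'", x)  # typographic prime
  if (x2 == "?" || !nzchar(x2)) {
    return(list(type = "unknown", n = NA_integer_))
  }
  if (grepl("^cir", x2, ignore.case = TRUE)) {
    return(list(type = "circularly_permuted", n = NA_integer_))
  }
  m <- regmatches(x2, regexec("^([0-9,]+)-bp DTR$", x2, ignore.case = TRUE))[[1]]
  if (length(m) == 2) {
    return(list(type = "dtr", n = as.integer(gsub(",", "", m[2]))))
  }
  m <- regmatches(x2, regexec("^([35])' ([0-9]+)-base ext", x2))[[1]]
  if (length(m) == 3) {
    type <- if (m[2] == "3") "three_prime_ext" else "five_prime_ext"
    return(list(type = type, n = as.integer(m[3])))
  }
  warning("unparseable genome-end description '", x, "'; recorded as unknown")
  list(type = "unknown", n = NA_integer_)
}

#' Split a printed cluster label into cluster and subcluster
#'
#' Trailing digits denote a subcluster: `"CS2"` has base cluster `"CS"` and
#' subcluster `"CS2"`; `"A15"` has base `"A"`. `"Singleton"` maps to the
#' reserved label `"SINGLETON"` with no subcluster.
#'
#' @param x Printed cluster string.
#' @return `list(cluster_label, subcluster_label)`.
#' @export
split_cluster_label <- function(x) {
  x <- trimws(x)
  if (tolower(x) == "singleton") {
    return(list(cluster_label = "SINGLETON", subcluster_label = NA_character_))
  }
  base <- sub("[0-9]+$", "", x)
  if (identical(base, x)) {
    list(cluster_label = x, subcluster_label = NA_character_)
  } else {
    list(cluster_label = base, subcluster_label = x)
  }
}

#' Read a genome metadata table
#'
#' Reads a TSV with columns `name`, `host_species`, `strain`, `cluster`,
#' `length_bp`, `gc_percent`, `end_type`, `accession` into metadata-only
#' genome records. The packaged fixture `table1_gordonia.tsv` (under
#' `inst/extdata`) is in this format.
#'
#' @param path Path to the metadata TSV.
#' @return A list of [genome_record()] objects without sequences.
#' @export
read_metadata_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  lapply(seq_len(nrow(tab)), function(i) {
    cl <- split_cluster_label(tab$cluster[i])
    sp <- strsplit(tab$host_species[i], " ", fixed = TRUE)[[1]]
    genome_record(
      genome_id = tab$name[i],
      length_bp = as.integer(gsub(",", "", tab$length_bp[i])),
      gc_percent = as.numeric(tab$gc_percent[i]),
      host_genus = if (grepl("^G\\.", sp[1]) || grepl("Gordonia", sp[1]))
        "Gordonia" else sp[1],
      host_species = tab$host_species[i],
      host_strain = as.character(tab$strain[i]),
      end_type = parse_end_type(tab$end_type[i]),
      cluster_label = cl$cluster_label,
      subcluster_label = cl$subcluster_label,
      accession = tab$accession[i])
  })
}

#' Read the predicted attB site table
#'
#' Reads a TSV with columns `site_id`, `trna`, `locus_tag`, `coord_start`,
#' `coord_end`, `phages` (comma-separated phage names). Rows printed with
#' descending coordinates (minus-strand sites) are stored as `(min, max)`
#' with `orientation = "reverse"`. The packaged fixture `table2_attB.tsv` is
#' in this format.
#'
#' @param path Path to the attB table.
#' @return A data frame with one row per site: `site_id`, `trna_label`
#'   (`"INTERGENIC"` for intergenic sites), `locus_tag`, `host_start`,
#'   `host_end`, `orientation`, and a list-column `phage_names`.
#' @export
read_att_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (anyDuplicated(tab$site_id)) stop("duplicate site_id in attB table")
  phage_names <- strsplit(tab$phages, ",", fixed = TRUE)
  if (any(lengths(phage_names) == 0)) stop("attB row with empty phage list")
  a <- as.integer(tab$coord_start); b <- as.integer(tab$coord_end)
  out <- data.frame(
    site_id = tab$site_id,
    trna_label = ifelse(tolower(tab$trna) == "intergenic", "INTERGENIC",
                        tab$trna),
    locus_tag = tab$locus_tag,
    host_start = pmin(a, b),
    host_end = pmax(a, b),
    orientation = ifelse(a <= b, "forward", "reverse"),
    stringsAsFactors = FALSE)
  out$phage_names <- lapply(phage_names, trimws)
  out
}

#' Write and read a symmetric labelled matrix as TSV
#'
#' The file has a header of genome labels and one labelled row per genome;
#' `read_matrix_tsv(write_matrix_tsv(M))` recovers `M` to 10 decimal places
#' with label order preserved.
#'
#' @param matrix Symmetric numeric matrix with zero diagonal and row/column
#'   names.
#' @param path File path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(matrix, path) {
  check_symmetric(matrix)
  df <- data.frame(genome = rownames(matrix),
                   format(matrix, digits = 12, scientific = FALSE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("genome", colnames(matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}

check_symmetric <- function(matrix, tol = 1e-9) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("matrix must be square")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix))) {
    stop("matrix must carry identical row and column labels")
  }
  if (max(abs(matrix - t(matrix))) > tol) stop("matrix is not symmetric")
  if (max(abs(diag(matrix))) > tol) stop("matrix diagonal must be zero")
  invisible(TRUE)
}

#' Export a distance matrix as a Nexus DISTANCES block
#'
#' Writes a `#NEXUS` file with TAXA and DISTANCES blocks
#' (`TRIANGLE=BOTH`, `LABELS=LEFT`, diagonal included) so that
#' gene-content distance matrices can be loaded into network/splits
#' software. Labels containing whitespace are single-quoted.
#'
#' @param matrix Symmetric labelled distance matrix with zero diagonal.
#' @param path Output path.
#' @export
write_nexus_distances <- function(matrix, path) {
  if (length(matrix) == 0 || nrow(matrix) == 0) stop("empty label set")
  check_symmetric(matrix)
  n <- nrow(matrix)
  labels <- rownames(matrix)
  quoted <- ifelse(grepl("\\s", labels),
                   paste0("'", gsub("'", "''", labels), "'"), labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(c("", "BEGIN TAXA;",
               paste0("  DIMENSIONS NTAX=", n, ";"),
               paste0("  TAXLABELS ", paste(quoted, collapse = " "), ";"),
               "END;", "", "BEGIN DISTANCES;",
               paste0("  DIMENSIONS NTAX=", n, ";"),
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS=LEFT;",
               "  MATRIX"), con)
  for (i in seq_len(n)) {
    writeLines(paste0("    ", quoted[i], " ",
                      paste(format(matrix[i, ], digits = 12, trim = TRUE),
                            collapse = " ")), con)
  }
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Path to a packaged data fixture
#'
#' @param name Fixture file name (e.g. `"table1_gordonia.tsv"`).
#' @return Absolute path to the installed fixture.
#' @export
phagegcd_fixture <- function(name) {
  p <- system.file("extdata", name, package = "phagegcd")
  if (!nzchar(p)) stop("no packaged fixture named '", name, "'")
  p
}
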