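# Seeded synthetic mosaic phage populations: pham content with planted
# cluster structure and a shared horizontal-transfer pool, protein families
# mutated from family ancestors, nucleotide genomes with planted consensus
# sites and att cores, and exported ground truth.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")

#' Configuration for a synthetic phage population
#'
#' The defaults describe a well-separated mosaic population: 4 clusters of
#' 5 genomes, each cluster with a private pool of 40 core phams retained
#' with probability 0.9 per genome, a shared accessory pool of 200 phams
#' each drawn with probability 0.02 (the horizontal-transfer knob), one
#' expected private orpham per genome, and protein families diverged from
#' a random ancestor at 5% per site.
#'
#' @param n_clusters Number of planted clusters.
#' @param genomes_per_cluster Genomes per cluster (scalar or vector of
#'   length `n_clusters`).
#' @param core_phams_per_cluster Size of each cluster's core pham pool.
#' @param core_retention Probability a genome keeps each core pham.
#' @param accessory_pool_size Size of the shared accessory pool.
#' @param hgt_rate Probability a genome draws each accessory pham.
#' @param orpham_rate Expected number of private single-gene phams per
#'   genome (Poisson).
#' @param protein_family_mutation Per-site substitution probability applied
#'   to each family member relative to the family ancestor.
#' @param genome_length_bp Nucleotide genome length for emitted sequences.
#' @param n_planted_motifs Number of consensus-site copies planted per
#'   genome (see [emit_genome_sequences()]).
#' @param motif_mismatch_counts Integer vector of substitution counts, one
#'   per planted motif copy (recycled); overrides `n_planted_motifs` when
#'   longer.
#' @param att_core_lengths Lengths (bp) of att cores copied between the
#'   first genome and the synthetic host.
#' @param host_length_bp Length of the synthetic host genome.
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical populations.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 4, genomes_per_cluster = 5,
                       core_phams_per_cluster = 40, core_retention = 0.9,
                       accessory_pool_size = 200, hgt_rate = 0.02,
                       orpham_rate = 1, protein_family_mutation = 0.05,
                       genome_length_bp = 20000, n_planted_motifs = 5,
                       motif_mismatch_counts = 0L,
                       att_core_lengths = 37L, host_length_bp = 50000,
                       seed = 1L) {
  probs <- c(core_retention, hgt_rate, protein_family_mutation)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_clusters, core_phams_per_cluster, accessory_pool_size,
              genome_length_bp, n_planted_motifs, host_length_bp,
              genomes_per_cluster)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (core_retention == 0 && hgt_rate == 0 && orpham_rate == 0) {
    stop("configuration implies empty genomes",
         " (no core retention, no accessory draws, no orphams)")
  }
  if (length(genomes_per_cluster) == 1) {
    genomes_per_cluster <- rep(genomes_per_cluster, n_clusters)
  }
  if (length(genomes_per_cluster) != n_clusters) {
    stop("genomes_per_cluster must have length 1 or n_clusters")
  }
  structure(list(
    n_clusters = as.integer(n_clusters),
    genomes_per_cluster = as.integer(genomes_per_cluster),
    core_phams_per_cluster = as.integer(core_phams_per_cluster),
    core_retention = core_retention,
    accessory_pool_size = as.integer(accessory_pool_size),
    hgt_rate = hgt_rate, orpham_rate = orpham_rate,
    protein_family_mutation = protein_family_mutation,
    genome_length_bp = as.integer(genome_length_bp),
    n_planted_motifs = as.integer(n_planted_motifs),
    motif_mismatch_counts = as.integer(motif_mismatch_counts),
    att_core_lengths = as.integer(att_core_lengths),
    host_length_bp = as.integer(host_length_bp),
    seed = as.integer(seed)), class = "sim_config")
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

mutate_protein <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(old) {
      sample(setdiff(AA20, old), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

substitute_bases <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  chars[pos] <- vapply(chars[pos], function(old) {
    sample(setdiff(DNA4, old), 1)
  }, character(1))
  paste(chars, collapse = "")
}

#' Simulate a mosaic phage population
#'
#' Each genome's pham set is the union of its cluster's core phams (each
#' kept with probability `core_retention`), accessory phams drawn from the
#' shared pool (each with probability `hgt_rate`) and Poisson-distributed
#' private orphams. Every pham used gets one random ancestor protein
#' (length 80-400 aa) and each member gene carries a copy mutated at
#' `protein_family_mutation` per site. Genomes are guaranteed non-empty: a
#' genome whose draws all fail keeps one core pham. Output is
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (list of [gene_record()]), `profiles`
#'   (named list genome_id -> true pham-id set), and `truth`, a list with
#'   `true_cluster_of` (named integer vector), `pham_of_gene` (named
#'   integer vector), and empty `motif_positions`/`att_core_loci` tables
#'   to be filled by [emit_genome_sequences()].
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  nc <- config$n_clusters
  core_ids <- lapply(seq_len(nc), function(c) {
    (c - 1) * config$core_phams_per_cluster +
      seq_len(config$core_phams_per_cluster)
  })
  acc_base <- nc * config$core_phams_per_cluster
  acc_ids <- acc_base + seq_len(config$accessory_pool_size)
  next_orpham <- acc_base + config$accessory_pool_size

  genomes <- character(0)
  true_cluster <- integer(0)
  profiles <- list()
  for (c in seq_len(nc)) {
    for (g in seq_len(config$genomes_per_cluster[c])) {
      gid <- sprintf("sim_c%02d_g%02d", c, g)
      core <- core_ids[[c]][stats::runif(length(core_ids[[c]])) <
                              config$core_retention]
      acc <- acc_ids[stats::runif(length(acc_ids)) < config$hgt_rate]
      n_orp <- stats::rpois(1, config$orpham_rate)
      orp <- if (n_orp > 0) next_orpham + seq_len(n_orp) else integer(0)
      next_orpham <- next_orpham + n_orp
      phams <- sort(c(core, acc, orp))
      if (length(phams) == 0) phams <- core_ids[[c]][1]
      genomes <- c(genomes, gid)
      true_cluster[gid] <- c
      profiles[[gid]] <- phams
    }
  }

  used <- sort(unique(unlist(profiles)))
  ancestors <- stats::setNames(vapply(used, function(p) {
    random_aa(sample(80:400, 1))
  }, character(1)), used)

  genes <- list()
  pham_of_gene <- integer(0)
  for (gid in genomes) {
    phams <- profiles[[gid]]
    pos <- 1L
    for (t in seq_along(phams)) {
      p <- phams[t]
      prot <- mutate_protein(ancestors[[as.character(p)]],
                             config$protein_family_mutation)
      gene_id <- sprintf("%s_gene%03d", gid, t)
      len_nt <- 3L * nchar(prot)
      genes[[gene_id]] <- gene_record(gene_id, gid, pos, pos + len_nt - 1,
                                      "+", prot)
      pham_of_gene[gene_id] <- p
      pos <- pos + len_nt + 50L
    }
  }

  list(genes = unname(genes), profiles = profiles,
       truth = list(true_cluster_of = true_cluster,
                    pham_of_gene = pham_of_gene,
                    motif_positions = empty_motif_truth(),
                    att_core_loci = empty_att_truth()))
}

empty_motif_truth <- function() {
  data.frame(genome_id = character(), start = integer(),
             strand = character(), n_sub = integer(),
             stringsAsFactors = FALSE)
}

empty_att_truth <- function() {
  data.frame(phage_id = character(), phage_start = integer(),
             host_start = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Emit nucleotide genomes with planted sites and a synthetic host
#'
#' Generates uniform-random nucleotide backgrounds of
#' `config$genome_length_bp` for every simulated genome, plants
#' non-overlapping copies of the consensus at random positions and strands
#' with the configured substitution counts, and copies one att core per
#' configured length from the first genome into a uniform-random synthetic
#' host genome. All plants are recorded in the returned truth tables.
#' Deterministic given `config$seed` (offset so sequence generation is
#' independent of the population draw).
#'
#' @param population Result of [simulate_population()].
#' @param config The same [sim_config()].
#' @param consensus Consensus to plant (default the KatherineG preset).
#' @return List with `genomes` (list of [genome_record()] with sequences),
#'   `host` (a [genome_record()]), and `truth` with `motif_positions` and
#'   `att_core_loci` filled in.
#' @export
emit_genome_sequences <- function(population, config,
                                  consensus = stoperator_presets[["KatherineG"]]) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1000003L)

  ids <- names(population$profiles)
  k <- nchar(consensus)
  n_sub <- config$motif_mismatch_counts
  n_motifs <- max(config$n_planted_motifs, length(n_sub))
  if (n_motifs > 0) {
    n_sub <- rep_len(n_sub, n_motifs)
  }
  need <- n_motifs * (k + 10)
  if (need > config$genome_length_bp) {
    stop("planted motifs exceed genome capacity: need ", need,
         " bp, genome is ", config$genome_length_bp, " bp")
  }
  if (length(config$att_core_lengths) &&
      max(config$att_core_lengths, 0) > config$genome_length_bp) {
    stop("att core longer than the genome")
  }

  motif_truth <- empty_motif_truth()
  genomes <- list()
  for (gid in ids) {
    seqchr <- random_dna(config$genome_length_bp)
    if (n_motifs > 0) {
      # non-overlapping plant positions on a (k+10)-spaced lattice
      slots <- seq(1, config$genome_length_bp - k + 1, by = k + 10)
      pos <- sort(sample(slots, n_motifs))
      strands <- sample(c("+", "-"), n_motifs, replace = TRUE)
      for (t in seq_len(n_motifs)) {
        site <- substitute_bases(consensus, n_sub[t])
        planted <- if (strands[t] == "+") site else revcomp(site)
        substr(seqchr, pos[t], pos[t] + k - 1) <- planted
        motif_truth <- rbind(motif_truth, data.frame(
          genome_id = gid, start = pos[t], strand = strands[t],
          n_sub = n_sub[t], stringsAsFactors = FALSE))
      }
    }
    genomes[[gid]] <- genome_record(gid, sequence = seqchr)
  }

  host_seq <- random_dna(config$host_length_bp)
  att_truth <- empty_att_truth()
  donor <- ids[1]
  lens <- config$att_core_lengths
  if (length(lens)) {
    # place cores in disjoint thirds of both sequences to keep them apart
    for (t in seq_along(lens)) {
      L <- lens[t]
      core <- random_dna(L)
      pspan <- floor(config$genome_length_bp / length(lens))
      hspan <- floor(config$host_length_bp / length(lens))
      pstart <- (t - 1) * pspan + sample(pspan - L, 1)
      hstart <- (t - 1) * hspan + sample(hspan - L, 1)
      pseq <- genomes[[donor]]$sequence
      substr(pseq, pstart, pstart + L - 1) <- core
      genomes[[donor]] <- genome_record(donor, sequence = pseq)
      substr(host_seq, hstart, hstart + L - 1) <- core
      att_truth <- rbind(att_truth, data.frame(
        phage_id = donor, phage_start = pstart, host_start = hstart,
        length = L, stringsAsFactors = FALSE))
    }
  }
  truth <- population$truth
  truth$motif_positions <- motif_truth
  truth$att_core_loci <- att_truth
  list(genomes = unname(genomes), host = genome_record("sim_host",
                                                       sequence = host_seq),
       truth = truth)
}

#' Export simulation ground truth as a TSV bundle
#'
#' Writes `cluster_truth.tsv`, `pham_truth.tsv`, `motif_truth.tsv` and
#' `att_truth.tsv` under `dir`; [read_truth()] recovers the truth object
#' exactly.
#'
#' @param truth Truth list as produced by [simulate_population()] /
#'   [emit_genome_sequences()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  nm <- function(x) if (is.null(names(x))) character(0) else names(x)
  w(data.frame(genome_id = nm(truth$true_cluster_of),
               cluster = unname(truth$true_cluster_of)), "cluster_truth.tsv")
  w(data.frame(gene_id = nm(truth$pham_of_gene),
               pham_id = unname(truth$pham_of_gene)), "pham_truth.tsv")
  w(truth$motif_positions, "motif_truth.tsv")
  w(truth$att_core_loci, "att_truth.tsv")
  invisible(dir)
}

#' @rdname export_truth
#' @export
read_truth <- function(dir) {
  r <- function(name) {
    utils::read.delim(file.path(dir, name), stringsAsFactors = FALSE)
  }
  cl <- r("cluster_truth.tsv"); ph <- r("pham_truth.tsv")
  list(true_cluster_of = stats::setNames(as.integer(cl$cluster),
                                         cl$genome_id),
       pham_of_gene = stats::setNames(as.integer(ph$pham_id), ph$gene_id),
       motif_positions = r("motif_truth.tsv"),
       att_core_loci = r("att_truth.tsv"))
}
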