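consensus_kg <- stoperator_presets[["KatherineG"]]

plant <- function(background, site, at, strand = "+") {
  s <- if (strand == "+") site else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  substr(background, at, at + nchar(s) - 1) <- s
  background
}

mutate_site <- function(site, n) {
  v <- strsplit(site, "")[[1]]
  pos <- sample(length(v), n)
  v[pos] <- vapply(v[pos], function(o) {
    sample(setdiff(c("A", "C", "G", "T"), o), 1)
  }, character(1))
  paste(v, collapse = "")
}

test_that("exact planted consensus copies are found on both strands", {
  set.seed(2)
  g <- plant(random_dna_str(2000), consensus_kg, 100)
  hits <- scan_consensus(g, consensus_kg, max_mismatch = 0)
  expect_true(any(hits$start == 100 & hits$strand == "+" &
                  hits$n_mismatches == 0))
  expect_true(all(hits$matched_seq[hits$n_mismatches == 0] == consensus_kg))

  # reverse-complement plant reports a minus-strand hit at the same
  # leftmost coordinate
  g2 <- plant(random_dna_str(2000), consensus_kg, 700, strand = "-")
  hits2 <- scan_consensus(g2, consensus_kg, max_mismatch = 0)
  expect_true(any(hits2$start == 700 & hits2$strand == "-"))

  # 3 substitutions exceed the allowance
  g3 <- plant(random_dna_str(2000), mutate_site(consensus_kg, 3), 500)
  hits3 <- scan_consensus(g3, consensus_kg, max_mismatch = 2)
  expect_false(any(hits3$start == 500))

  expect_error(scan_consensus(g, "GGNGAT"), "A/C/G/T")
  expect_error(scan_consensus(g, "ACGTA"), "at least 6")
  expect_error(scan_consensus(g, "ACGTACGT", max_mismatch = 8), "smaller")
})

test_that("scan equals the exhaustive Hamming oracle on random sequence", {
  set.seed(6)
  for (rep in 1:2) {
    g <- random_dna_str(10000)
    # plant a few degraded copies so hits exist at several mismatch levels
    for (at in c(500, 2500, 7000)) {
      g <- plant(g, mutate_site(consensus_kg, rep - 1), at,
                 strand = sample(c("+", "-"), 1))
    }
    got <- scan_consensus(g, consensus_kg, max_mismatch = 2)
    want <- oracle_hamming_scan(g, consensus_kg, 2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$start, want$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$n_mismatches, want$n_mismatches)
    }
  }
})

test_that("reverse-complementing the genome mirrors hit coordinates", {
  set.seed(8)
  g <- plant(plant(random_dna_str(3000), consensus_kg, 101),
             consensus_kg, 1500, strand = "-")
  k <- nchar(consensus_kg)
  L <- nchar(g)
  fwd <- scan_consensus(g, consensus_kg, max_mismatch = 1)
  grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  rev <- scan_consensus(grc, consensus_kg, max_mismatch = 1)
  flip <- function(h) {
    data.frame(start = L - h$start - k + 2,
               strand = ifelse(h$strand == "+", "-", "+"),
               n_mismatches = h$n_mismatches)
  }
  a <- flip(fwd); a <- a[order(a$start, a$strand), ]
  b <- rev[order(rev$start, rev$strand), c("start", "strand", "n_mismatches")]
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
})

test_that("planted-motif recall is total at <= 2 substitutions, zero at 3", {
  set.seed(14)
  for (n_sub in 0:3) {
    g <- random_dna_str(8000)
    positions <- seq(200, 7200, by = 1000)
    for (at in positions) g <- plant(g, mutate_site(consensus_kg, n_sub), at)
    hits <- scan_consensus(g, consensus_kg, max_mismatch = 2)
    recall <- mean(positions %in% hits$start[hits$strand == "+"])
    expect_equal(recall, if (n_sub <= 2) 1 else 0)
  }
})

test_that("background false-positive rate is consistent with the binomial model", {
  # P(window within 2 mismatches of a fixed 13-mer) under uniform bases,
  # doubled for the two strands
  k <- nchar(consensus_kg)
  p1 <- sum(choose(k, 0:2) * (1 / 4)^(k - 0:2) * (3 / 4)^(0:2))
  n <- 200000
  set.seed(21)
  g <- random_dna_str(n)
  hits <- scan_consensus(g, consensus_kg, max_mismatch = 2)
  expected <- 2 * (n - k + 1) * p1
  sd <- sqrt(2 * (n - k + 1) * p1 * (1 - p1))
  expect_lte(abs(nrow(hits) - expected), 3 * sd + 1)
})

test_that("intergenic annotation uses the any-overlap rule", {
  genes <- list(gene_record("g1", "ph", 101, 400, "+", "MKTAYI"),
                gene_record("g2", "ph", 601, 900, "-", "MKTAYI"))
  hits <- data.frame(genome_id = "ph", start = c(200, 450, 389, 88, 95),
                     strand = "+",
                     matched_seq = "GGGGATTGTCAAG", n_mismatches = 0L,
                     intergenic = NA)
  ann <- intergenic_filter(hits, genes)
  # inside g1; in the gap; straddling g1's end by 1 base; ending 1 bp
  # before g1 starts; straddling g1's start
  expect_equal(ann$intergenic, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  kept <- intergenic_filter(hits, genes, remove_genic = TRUE)
  expect_equal(sort(kept$start), c(88, 450))
  bad <- hits; bad$genome_id <- "other"
  expect_error(intergenic_filter(bad, genes), "does not cover")
})

test_that("att cores report planted shared segments and respect the floor", {
  set.seed(33)
  core37 <- random_dna_str(37)
  phage <- plant(random_dna_str(3000), core37, 1200)
  host <- plant(random_dna_str(4000), core37, 2500)
  cores <- find_att_cores(phage, host)
  expect_equal(nrow(cores), 1)
  expect_equal(cores$length, 37)
  expect_equal(cores$core_seq, core37)
  expect_equal(c(cores$phage_start, cores$phage_end), c(1200, 1236))
  expect_equal(c(cores$host_start, cores$host_end), c(2500, 2536))
  expect_identical(cores$orientation, "same")
  expect_false(cores$long_core)

  # a 19-bp shared segment is below the 20-bp floor; flanking bases are
  # forced to differ so the match cannot extend by chance
  core19 <- random_dna_str(19)
  s1 <- plant(random_dna_str(2000), core19, 500)
  s2 <- plant(random_dna_str(2000), core19, 900)
  substr(s1, 499, 499) <- "A"; substr(s2, 899, 899) <- "C"
  substr(s1, 519, 519) <- "A"; substr(s2, 919, 919) <- "C"
  expect_equal(nrow(find_att_cores(s1, s2)), 0)

  # cores longer than max_len are flagged, not truncated
  core60 <- random_dna_str(60)
  long <- find_att_cores(plant(random_dna_str(2000), core60, 500),
                         plant(random_dna_str(2000), core60, 900))
  expect_equal(long$length, 60)
  expect_true(long$long_core)

  expect_error(find_att_cores("ACGT", host), "shorter")
  expect_error(find_att_cores(phage, host, min_len = 8), "at least 12")
})

test_that("att cores match the dynamic-programming oracle on both strands", {
  set.seed(36)
  core24 <- random_dna_str(24)
  core31 <- random_dna_str(31)
  phage <- plant(plant(random_dna_str(1500), core24, 200), core31, 1000)
  host <- plant(plant(random_dna_str(1800), core24, 700), core31, 80)
  got <- find_att_cores(phage, host)
  want <- oracle_common_substrings(phage, host, 20)
  got_fwd <- got[got$orientation == "same", ]
  expect_equal(nrow(got_fwd), nrow(want))
  o1 <- order(got_fwd$phage_start)
  o2 <- order(want$start1)
  expect_equal(got_fwd$phage_start[o1], want$start1[o2])
  expect_equal(got_fwd$host_start[o1], want$start2[o2])
  expect_equal(got_fwd$length[o1], want$length[o2])

  # reverse-orientation plant is reported with phage coordinates on the
  # plus strand and host-strand core sequence
  rc31 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core31)))
  phage_rc <- plant(random_dna_str(1500), rc31, 400)
  host2 <- plant(random_dna_str(1500), core31, 600)
  rev <- find_att_cores(phage_rc, host2)
  expect_equal(nrow(rev), 1)
  expect_identical(rev$orientation, "reverse")
  expect_equal(rev$core_seq, core31)
  expect_equal(c(rev$phage_start, rev$phage_end), c(400, 430))
  expect_equal(c(rev$host_start, rev$host_end), c(600, 630))
})

test_that("att core discovery is role-symmetric up to coordinate exchange", {
  set.seed(39)
  core <- random_dna_str(28)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core)))
  s1 <- plant(plant(random_dna_str(1200), core, 100), rc, 800)
  s2 <- plant(random_dna_str(1400), core, 500)
  ab <- find_att_cores(s1, s2)
  ba <- find_att_cores(s2, s1)
  expect_equal(nrow(ab), nrow(ba))
  key_ab <- paste(ab$phage_start, ab$host_start, ab$length, ab$orientation)
  key_ba <- paste(ba$host_start, ba$phage_start, ba$length, ba$orientation)
  expect_setequal(key_ab, key_ba)
  expect_setequal(ab$length, ba$length)
})

test_that("tRNA overlap requires at least one shared base", {
  features <- data.frame(
    locus_tag = c("T0001", "T0002", "CDS01"),
    type = c("tRNA", "tRNA", "CDS"),
    start = c(1000, 5000, 2000), end = c(1075, 5075, 3000))
  cores <- data.frame(core_seq = "X", length = 30,
                      phage_start = 1, phage_end = 30,
                      host_start = c(1050, 2500, 969, 1076),
                      host_end = c(1079, 2529, 999, 1105),
                      orientation = "same", long_core = FALSE,
                      trna_overlap = NA, trna_locus = NA_character_)
  ann <- annotate_trna_overlap(cores, features)
  # overlapping T0001; inside a CDS (not tRNA); ending 1 bp before the
  # tRNA start; starting 1 bp after the tRNA end
  expect_equal(ann$trna_overlap, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ann$trna_locus, c("T0001", NA, NA, NA))
})

test_that("attB fixture sites annotate against a matching feature table", {
  att <- read_att_table(phagegcd_fixture("table2_attB.tsv"))
  # build host features from the fixture's own tRNA rows
  trna_rows <- att[att$trna_label != "INTERGENIC", ]
  features <- data.frame(locus_tag = trna_rows$locus_tag, type = "tRNA",
                         start = trna_rows$host_start,
                         end = trna_rows$host_end)
  cores <- data.frame(core_seq = "X", length = att$host_end - att$host_start + 1,
                      phage_start = 1, phage_end = 2,
                      host_start = att$host_start, host_end = att$host_end,
                      orientation = "same", long_core = FALSE,
                      trna_overlap = NA, trna_locus = NA_character_)
  ann <- annotate_trna_overlap(cores, features)
  expect_equal(sum(ann$trna_overlap), 10)
  expect_equal(sum(!ann$trna_overlap), 3)
})
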