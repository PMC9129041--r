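test_that("CDS splicing concatenates exons and respects strand", {
  # exon1 = 1..9, intron = 10..15, exon2 = 16..30
  contig <- paste0("ATGAAAGGG", "GTAAGT", "CCCTTTTAATGACCC")
  paths <- write_toy_genome(contig, toy_two_exon_features("+"))
  gb <- load_genome(paths$fasta, paths$gff)
  rec <- gene_records(gb)
  expect_equal(rec$cds, paste0(substr(contig, 1, 9), substr(contig, 16, 30)))
  expect_equal(rec$introns[[1]], substr(contig, 10, 15))

  # same annotation on the minus strand: cds is the reverse complement of
  # the descending-coordinate exon concatenation
  paths2 <- write_toy_genome(contig, toy_two_exon_features("-"))
  rec2 <- gene_records(load_genome(paths2$fasta, paths2$gff))
  fwd <- paste0(substr(contig, 1, 9), substr(contig, 16, 30))
  expect_equal(rec2$cds, stopflux:::revcomp(fwd))
})

test_that("extraction is strand-symmetric under contig reverse complement", {
  set.seed(11)
  ref <- make_reference(sim_config(seed = 11, n_genes = 6,
                                   mean_cds_length = 300))
  rec <- gene_records(ref$bundle)

  contig <- ref$bundle$contigs[["chr1"]]
  L <- nchar(contig)
  f <- ref$bundle$features
  mirrored <- structure(list(
    contigs = c(chr1 = stopflux:::revcomp(contig)),
    features = dplyr::mutate(f,
                             start0 = L - .data$end + 1L,
                             end = L - .data$start + 1L,
                             start = .data$start0,
                             strand = ifelse(.data$strand == "+", "-", "+"))
  ), class = "genome_bundle")
  rec2 <- gene_records(mirrored)
  rec2 <- rec2[match(rec$gene_id, rec2$gene_id), ]
  expect_equal(rec2$cds, rec$cds)
  expect_equal(rec2$utr5, rec$utr5)
  expect_equal(rec2$utr3, rec$utr3)
  expect_equal(rec2$introns, rec$introns)
})

test_that("synthetic bundles round-trip through FASTA/GFF3 byte-identically", {
  cfg <- sim_config(seed = 7, n_genes = 10, mean_cds_length = 300)
  sim <- sim_bundle(cfg, n_mutations = 500)
  d <- tempfile()
  write_bundle(sim, d, write_trios = FALSE)
  gb <- load_genome(file.path(d, "reference.fa"), file.path(d, "annotation.gff3"))
  expect_identical(unname(gb$contigs["chr1"]), unname(sim$bundle$contigs["chr1"]))
  rec <- gene_records(gb)
  rec <- rec[match(sim$genes$gene_id, rec$gene_id), ]
  expect_identical(rec$cds, sim$genes$cds)
  expect_identical(rec$stop, sim$genes$stop)
  # construction guarantees the QC filters pass
  expect_equal(nrow(qc_filter(rec)), nrow(rec))
})

test_that("qc_filter enforces length, premature stops and valid stop codons", {
  expect_equal(nrow(qc_filter(tibble::tibble(cds = "ATGTAATGA"))), 0) # internal TAA
  kept <- qc_filter(tibble::tibble(cds = "ATGAAATGA"))
  expect_equal(nrow(kept), 1)
  expect_equal(substring(kept$cds, 7, 9), "TGA")

  set.seed(42)
  good <- replicate(90, stopflux:::.random_cds(90, 0.5, sample(c("TAA", "TGA", "TAG"), 1)))
  bad <- c(
    replicate(4, paste0(stopflux:::.random_cds(87, 0.5, "TAA"), "AC")),  # length
    replicate(3, paste0("ATGTAA", substring(stopflux:::.random_cds(90, 0.5, "TAA"), 7))), # premature
    replicate(3, paste0(substring(stopflux:::.random_cds(90, 0.5, "TAA"), 1, 87), "TGG")) # bad stop
  )
  recs <- tibble::tibble(cds = sample(c(good, bad)))
  out <- suppressMessages(qc_filter(recs))
  expect_equal(nrow(out), 90)
  rej <- attr(out, "rejections")
  expect_equal(sum(rej$n), 10)
})

test_that("gc3 and intronic_gc compute planted compositions", {
  expect_equal(gc3("ATGGCGTAA"), 1.0)   # thirds of ATG, GCG; stop excluded
  expect_equal(gc3("ATGGCATAA"), 0.5)  # thirds G, A
  expect_equal(intronic_gc(list("ATATATAT")), 0)
  expect_true(is.na(intronic_gc(list(character(0)))))

  set.seed(5)
  n <- 20000
  intron <- stopflux:::.random_seq(n, 0.62)
  se <- sqrt(0.62 * 0.38 / n)
  expect_lt(abs(intronic_gc(list(intron)) - 0.62), 3 * se)
})

test_that("trinuc_profile counts windows as hand-enumerated", {
  p <- trinuc_profile("TAATAA", frame_free = TRUE)
  expect_equal(unname(p$counts[c("TAA", "AAT", "ATA")]), c(2L, 1L, 1L))
  expect_equal(p$total, 4L)  # L - 2 windows
  pin <- trinuc_profile("TAATAA", frame_free = FALSE)
  expect_equal(unname(pin$counts["TAA"]), 2L)
  expect_equal(pin$total, 2L)

  # frequencies sum to 1; N-containing windows are skipped
  pn <- trinuc_profile("TANTAA")
  expect_equal(pn$total, 4L - 3L)
  expect_equal(sum(p$frequencies), 1, tolerance = 1e-9)

  empty <- trinuc_profile("")
  expect_true(empty$empty)
})

test_that("trinuc frequencies of i.i.d. sequence match the product expectation", {
  set.seed(9)
  s <- stopflux:::.random_seq(3e5, 0.4)
  p <- trinuc_profile(s)
  base_p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  exp_freq <- vapply(stopflux:::TRINUCS, function(tr) {
    prod(base_p[strsplit(tr, "")[[1]]])
  }, numeric(1))
  se <- sqrt(exp_freq * (1 - exp_freq) / p$total)
  expect_true(all(abs(p$frequencies - exp_freq) < 5 * se))
})

test_that("stop_usage returns relative frequencies and rejects empty input", {
  u <- stop_usage(c(TAA = 1, TGA = 1, TAG = 1))
  expect_equal(u$usage, rep(1 / 3, 3))
  u2 <- stop_usage(c(TAA = 0, TGA = 3, TAG = 1))
  expect_equal(u2$usage, c(0, 0.75, 0.25))
  expect_error(stop_usage(c(TAA = 0, TGA = 0, TAG = 0)), "no stop codons")
})

test_that("decile_bins partitions into near-equal bins without loss", {
  rec <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), x = rnorm(100))
  out <- decile_bins(rec, "x", bins = 10)
  expect_true(all(table(out$.bin) == 10))
  expect_setequal(out$gene_id, rec$gene_id)
  # unequal case: sizes differ by at most one
  out2 <- decile_bins(rec[1:97, ], "x", bins = 10)
  expect_lte(diff(range(table(out2$.bin))), 1)
  expect_error(decile_bins(rec[1:7, ], "x", bins = 10), "fewer records")
})

test_that("half_split balances flux events across the GC halves", {
  set.seed(21)
  rec <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                        gc = sort(runif(200)),
                        events = 0L)
  rec$events[sample.int(200, 40)] <- 1L
  out <- half_split(rec, "gc", "events")
  tab <- tapply(out$events, out$.half, sum)
  expect_equal(unname(tab["low"]), 20)
  expect_equal(unname(tab["high"]), 20)
  expect_lte(attr(out, "event_diff"), 1)
})

test_that("assign_recombination averages SNP rates and overlap rates", {
  map <- tibble::tibble(contig = "chr1",
                        start = c(0L, 100L, 200L),
                        end = c(100L, 200L, 300L),
                        rate = c(1, 3, 5))
  rec <- tibble::tibble(gene_id = "g1", contig = "chr1", start = 10L, end = 90L)
  out <- assign_recombination(rec, map)
  expect_equal(out$recomb_rate, 1)

  snps <- tibble::tibble(contig = "chr1", pos = c(50L, 150L))
  rec2 <- tibble::tibble(gene_id = "g1", contig = "chr1", start = 10L, end = 190L)
  out2 <- assign_recombination(rec2, map, snps)
  expect_equal(out2$recomb_rate, 2)  # mean of 1 and 3

  # length-weighted overlap equals brute-force per-base averaging
  set.seed(8)
  starts <- seq(0L, 900L, by = 100L)
  map2 <- tibble::tibble(contig = "chr1", start = starts, end = starts + 100L,
                         rate = runif(10, 0, 5))
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:20),
                          contig = "chr1",
                          start = sample.int(800, 20),
                          end = 0L)
  genes$end <- genes$start + sample.int(150, 20)
  out3 <- assign_recombination(genes, map2)
  per_base <- vapply(seq_len(20), function(i) {
    bases <- (genes$start[i] - 1L):(genes$end[i] - 1L)  # 0-based
    r <- map2$rate[findInterval(bases, map2$start)]
    r[bases >= max(map2$end)] <- NA
    mean(r, na.rm = TRUE)
  }, numeric(1))
  expect_equal(out3$recomb_rate, per_base, tolerance = 1e-9)

  # no overlap -> NA
  far <- tibble::tibble(gene_id = "g", contig = "chr1", start = 5000L, end = 5100L)
  expect_true(is.na(assign_recombination(far, map)$recomb_rate))
})
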