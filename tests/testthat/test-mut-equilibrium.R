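test_that("read_mutations validates against the reference and computes local GC", {
  contig <- c(chrA = paste0(strrep("A", 50), "CATG", strrep("T", 50)))
  tsv <- tempfile()
  writeLines(c("Chr\tPos\tRef\tAlt",
               "chrA\t51\tC\tT",
               "chrA\t52\tA\tG",
               "chrA\t53\tT\tC",
               "chrA\t54\tG\tA",
               "chrA\t10\tA\tC"), tsv)
  mu <- read_mutations(tsv, contig)
  expect_equal(nrow(mu), 5)
  expect_equal(attr(mu, "n_ref_mismatch"), 0)
  # window clipped at contig ends: local GC of the whole 104 bp contig
  expect_equal(mu$local_gc[1], 2 / 104)

  # one mismatching ref allele is dropped and logged
  writeLines(c("chrA\t51\tC\tT", "chrA\t52\tT\tG", "chrA\t53\tT\tC",
               paste0("chrA\t", 1:47, "\tA\tG")), tsv)
  expect_message(mu2 <- read_mutations(tsv, contig), "mismatch")
  expect_equal(nrow(mu2), 49)
  expect_equal(attr(mu2, "n_ref_mismatch"), 1)

  # systematic mismatch aborts: assembly mismatch
  writeLines(c(paste0("chrA\t", 1:20, "\tG\tT"),
               paste0("chrA\t", 60:79, "\tT\tC")), tsv)
  expect_error(read_mutations(tsv, contig), "assembly mismatch")
})

test_that("mono matrix rates are counts per exposure with Poisson intervals", {
  contig <- c(chr = paste(rep(c("A", "C", "G", "T"), 250), collapse = ""))
  set.seed(2)
  pos <- which(strsplit(contig, "")[[1]] == "A")[1:10]
  mu <- tibble::tibble(contig = "chr", pos = pos, ref = "A", alt = "G",
                       local_gc = 0.5)
  mm <- build_mono_matrix(mu, contig, exposure = "genome")
  expect_equal(mm$rates["A", "G"], 10 / 250)
  expect_equal(mm$rates["C", "T"], 0)
  expect_equal(mm$ci_lo["C", "T"], 0)  # zero count: CI lower bound 0
  ci <- stats::poisson.test(10)$conf.int
  expect_equal(mm$ci_lo["A", "G"], ci[1] / 250)
  expect_equal(mm$ci_hi["A", "G"], ci[2] / 250)
})

test_that("solve_stationary matches closed forms and power iteration", {
  # symmetric 4x4 -> uniform
  sym <- matrix(0.2, 4, 4, dimnames = list(stopflux:::BASES, stopflux:::BASES))
  diag(sym) <- 0
  expect_equal(unname(solve_stationary(sym)), rep(0.25, 4), tolerance = 1e-12)

  # 2-state closed form (v/(u+v), u/(u+v))
  two <- matrix(c(0, 0.3, 0.1, 0), 2, byrow = TRUE)
  expect_equal(solve_stationary(two), c(0.1 / 0.4, 0.3 / 0.4), tolerance = 1e-12)

  # random strictly positive matrices match the iteration oracle
  set.seed(17)
  for (k in c(4, 16)) {
    for (rep in 1:5) {
      m <- random_rate_matrix(k)
      pi_lin <- solve_stationary(m)
      pi_pow <- power_iteration_stationary(m)
      expect_lt(max(abs(pi_lin - pi_pow)), 1e-10)
      # every gain = loss balance holds
      q <- m; diag(q) <- 0
      gains <- as.numeric(pi_lin %*% q)
      losses <- pi_lin * rowSums(q)
      expect_lt(max(abs(gains - losses)), 1e-12)
    }
  }

  # scale invariance: only rate ratios matter
  m <- random_rate_matrix(4)
  expect_equal(solve_stationary(m), solve_stationary(m * 37), tolerance = 1e-12)

  # reducible chain errors naming the absorbing class
  red <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  red["X", "Y"] <- 1; red["Y", "X"] <- 1  # Z unreachable and absorbing
  expect_error(solve_stationary(red), "reducible")
})

test_that("stop equilibrium is uniform under symmetric rates and exact", {
  rates <- matrix(0, 4, 4, dimnames = list(stopflux:::BASES, stopflux:::BASES))
  rates["A", "G"] <- 0.003
  rates["G", "A"] <- 0.003
  eq <- stop_equilibrium(rates)
  expect_equal(c(eq$taa, eq$tga, eq$tag), rep(1 / 3, 3), tolerance = 1e-12)
  expect_lt(max(eq$residuals), 1e-12)
})

test_that("stop equilibrium solves the balance system for asymmetric rates", {
  rates <- matrix(0, 4, 4, dimnames = list(stopflux:::BASES, stopflux:::BASES))
  rates["A", "G"] <- 0.002
  rates["G", "A"] <- 0.004
  eq <- stop_equilibrium(rates)
  expect_lt(max(eq$residuals), 1e-12)

  # independent oracle: full 3x3 linear solve of the balance system
  f <- matrix(0, 3, 3, dimnames = list(stopflux:::STOPS, stopflux:::STOPS))
  f["TAA", "TGA"] <- f["TAA", "TAG"] <- 0.002
  f["TGA", "TAA"] <- f["TAG", "TAA"] <- 0.004
  f["TGA", "TAG"] <- f["TAG", "TGA"] <- 2 * 0.002 * 0.004
  oracle <- solve_stationary(f)
  expect_equal(c(eq$taa, eq$tga, eq$tag), unname(oracle), tolerance = 1e-10)

  # elimination-choice invariance
  for (e in stopflux:::STOPS) {
    eqe <- stop_equilibrium(rates, eliminate = e)
    expect_equal(c(eqe$taa, eqe$tga, eqe$tag), c(eq$taa, eq$tga, eq$tag),
                 tolerance = 1e-12)
  }

  expect_error(stop_equilibrium(rates * 0), "zero")
})

test_that("dinucleotide transitions trace both flanks with boundary handling", {
  contig <- c(chr = "ACATG")
  mu <- tibble::tibble(contig = "chr", pos = 3L, ref = "A", alt = "G",
                       local_gc = 0.4)
  dm <- build_dinuc_matrix(mu, contig, exposure = "genome")
  expect_equal(dm$counts["CA", "CG"], 1)
  expect_equal(dm$counts["AT", "GT"], 1)
  expect_equal(sum(dm$counts), 2)

  # mutation at a contig start only counts the right-hand dinucleotide
  mu2 <- tibble::tibble(contig = "chr", pos = 1L, ref = "A", alt = "T",
                        local_gc = 0.4)
  dm2 <- build_dinuc_matrix(mu2, contig, exposure = "genome")
  expect_equal(dm2$counts["AC", "TC"], 1)
  expect_equal(sum(dm2$counts), 1)

  # single-side sensitivity mode
  dm3 <- build_dinuc_matrix(mu, contig, exposure = "genome", both_sides = FALSE)
  expect_equal(sum(dm3$counts), 1)
  expect_equal(dm3$counts["AT", "GT"], 1)
})

test_that("CpG-elevated mutation processes are recovered from sampled tables", {
  set.seed(23)
  ref <- c(chr = stopflux:::.random_seq(2e5, 0.5))
  rates <- default_mutation_rates()
  n <- 40000
  # sample from a context-dependent process: C->T at CpG 10x the base rate
  codes <- stopflux:::encode_seq(ref)
  is_c <- which(codes == 2L)
  next_g <- codes[pmin(is_c + 1L, length(codes))] == 3L
  w <- rep(1, length(is_c)); w[next_g] <- 10
  pick <- is_c[sample.int(length(is_c), n, replace = TRUE, prob = w)]
  mu <- tibble::tibble(contig = "chr", pos = pick, ref = "C", alt = "T",
                       local_gc = 0.5)
  dm <- build_dinuc_matrix(mu, ref, exposure = "genome")
  ratio <- dm$rates["CG", "TG"] / dm$rates["CA", "TA"]
  se <- ratio * sqrt(1 / dm$counts["CG", "TG"] + 1 / dm$counts["CA", "TA"])
  expect_lt(abs(ratio - 10), 3 * se)
})

test_that("binned equilibria degenerate to the global solution at bins = 1", {
  set.seed(31)
  ref <- c(chr = stopflux:::.random_seq(1e5, 0.45))
  mu <- sample_denovo(ref, default_mutation_rates(), 2000, seed = 31)
  mu <- dplyr::mutate(mu, local_gc = runif(dplyr::n()))  # synthetic window GC
  be <- binned_equilibria(mu, ref, bins = 1, kind = "mono",
                          window = 1e5)
  mm <- build_mono_matrix(mu, ref, window = 1e5)
  expect_equal(be$gc_star, mono_equilibrium(mm)$gcstar, tolerance = 1e-12)
  expect_equal(be$tga_star, stop_equilibrium(mm)$tga, tolerance = 1e-12)
  expect_false(be$flagged)
})

test_that("binned equilibria split mutations into equal-count bins", {
  set.seed(37)
  ref <- c(chr = stopflux:::.random_seq(3e5, 0.5))
  mu <- sample_denovo(ref, default_mutation_rates(), 5000, seed = 37)
  mu$local_gc <- runif(nrow(mu))
  be <- binned_equilibria(mu, ref, bins = 5, kind = "mono", window = 4000)
  expect_equal(be$n_mutations, rep(1000, 5))
  expect_true(all(diff(be$gc_lo) > 0))
})

test_that("dinucleotide binned equilibria give coherent stop shares", {
  set.seed(53)
  ref <- c(chr = stopflux:::.random_seq(2e5, 0.5))
  mu <- sample_denovo(ref, default_mutation_rates(), 4000, seed = 53)
  mu$local_gc <- runif(nrow(mu))
  be <- binned_equilibria(mu, ref, bins = 2, kind = "dinuc", window = 20000)
  expect_false(any(be$flagged))
  expect_true(all(be$gc_star > 0 & be$gc_star < 1))
  expect_equal(be$taa_star + be$tga_star + be$tag_star, rep(1, 2),
               tolerance = 1e-9)
  # GC->AT biased process: equilibrium favours TAA over TAG
  expect_true(all(be$taa_star > be$tag_star))
})

test_that("GC* recovery: sampled mutations reproduce the generating equilibrium", {
  set.seed(41)
  ref <- c(chr = stopflux:::.random_seq(2e5, 0.5))
  rates <- default_mutation_rates()
  truth <- solve_stationary(rates)
  gc_true <- unname(truth["G"] + truth["C"])
  mu <- sample_denovo(ref, rates, 30000, seed = 41)
  mu$local_gc <- 0.5
  mm <- build_mono_matrix(mu, ref, exposure = "genome")
  est <- mono_equilibrium(mm)$gcstar
  # bootstrap SE over mutation resampling
  boots <- vapply(1:60, function(b) {
    mb <- mu[sample.int(nrow(mu), replace = TRUE), ]
    mono_equilibrium(build_mono_matrix(mb, ref, exposure = "genome"))$gcstar
  }, numeric(1))
  expect_lt(abs(est - gc_true), 3 * sd(boots))
})
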