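toy_genes <- function(anc, t1, t2) {
  tibble::tibble(ancestral = anc, tip1 = t1, tip2 = t2)
}

test_that("count_stop_flux scores both ingroup lineages per incidence", {
  fc <- count_stop_flux(toy_genes("TAA", "TGA", "TAA"))
  expect_equal(unname(fc$incidences["TAA"]), 2)
  expect_equal(fc$transitions$count[fc$transitions$derived == "TGA"], 1L)

  fc2 <- count_stop_flux(toy_genes("TGA", "TGA", "TGA"))
  expect_equal(unname(fc2$incidences["TGA"]), 2)
  expect_equal(nrow(fc2$transitions), 0)

  # non-stop tips are tabulated separately and kept out of stop rates
  fc3 <- count_stop_flux(toy_genes("TAA", "TCA", "TAA"))
  expect_equal(fc3$transitions$derived, "nonstop")
  r <- flux_rates(fc3)
  expect_equal(r$rate[r$ancestral == "TAA" & r$derived == "TGA"], 0)

  # unresolved genes are skipped with a message
  expect_message(fc4 <- count_stop_flux(
    toy_genes(c("TAA", "unresolved"), c("TAA", "TAA"), c("TAA", "TAA"))),
    "skipped")
  expect_equal(fc4$n_skipped, 1L)
})

test_that("count_stop_flux is invariant to gene order and ingroup swap", {
  set.seed(10)
  g <- toy_genes(sample(stopflux:::STOPS, 50, replace = TRUE),
                 sample(c(stopflux:::STOPS, "TCA"), 50, replace = TRUE),
                 sample(stopflux:::STOPS, 50, replace = TRUE))
  a <- count_stop_flux(g)
  b <- count_stop_flux(g[sample.int(50), ])
  cc <- count_stop_flux(dplyr::rename(g, tip1 = "tip2", tip2 = "tip1"))
  expect_equal(a$incidences, b$incidences)
  expect_equal(a$transitions, b$transitions)
  expect_equal(a$transitions, cc$transitions)
})

test_that("pTGA follows 1/(1+s) and its edge cases", {
  # symmetric rates: 1 TAA->TGA per 100 TAA incidences and vice versa
  g <- toy_genes(c(rep("TAA", 50), rep("TGA", 50)),
                 c("TGA", rep("TAA", 49), "TAA", rep("TGA", 49)),
                 c(rep("TAA", 50), rep("TGA", 50)))
  s <- compute_ptga(count_stop_flux(g))
  expect_equal(s$ptga, 0.5)

  # rate(TAA->TGA) = 0.02, rate(TGA->TAA) = 0.01 -> s = 0.5, pTGA = 2/3
  g2 <- toy_genes(c(rep("TAA", 100), rep("TGA", 100)),
                  c(rep("TGA", 4), rep("TAA", 96), rep("TAA", 2), rep("TGA", 98)),
                  c(rep("TAA", 100), rep("TGA", 100)))
  s2 <- compute_ptga(count_stop_flux(g2))
  expect_equal(s2$s, 0.5)
  expect_equal(s2$ptga, 2 / 3)

  # absorbing TAA: zero TAA->TGA rate with nonzero reverse -> 0 with warning
  g3 <- toy_genes(c(rep("TAA", 10), rep("TGA", 10)),
                  c(rep("TAA", 10), "TAA", rep("TGA", 9)),
                  c(rep("TAA", 10), rep("TGA", 10)))
  expect_warning(s3 <- compute_ptga(count_stop_flux(g3)), "absorbing")
  expect_equal(s3$ptga, 0)

  # both rates zero -> undefined
  g4 <- toy_genes(c("TAA", "TGA"), c("TAA", "TGA"), c("TAA", "TGA"))
  expect_error(compute_ptga(count_stop_flux(g4)), "undefined")
})

test_that("pTGA equals the stationary TGA share of the two-state chain", {
  set.seed(3)
  for (rep in 1:5) {
    r_at <- runif(1, 0.005, 0.05)
    r_ta <- runif(1, 0.005, 0.05)
    # power-iterate the two-state chain {TAA, TGA}
    P <- matrix(c(1 - r_at, r_at, r_ta, 1 - r_ta), 2, byrow = TRUE)
    v <- c(0.5, 0.5)
    for (i in 1:20000) v <- v %*% P
    n <- 4000
    g <- toy_genes(
      c(rep("TAA", n), rep("TGA", n)),
      c(rep("TGA", round(2 * n * r_at)), rep("TAA", n - round(2 * n * r_at)),
        rep("TAA", round(2 * n * r_ta)), rep("TGA", n - round(2 * n * r_ta))),
      c(rep("TAA", n), rep("TGA", n)))
    s <- compute_ptga(count_stop_flux(g))
    expect_lt(abs(s$ptga - v[2] / sum(v)), 1e-2)  # chain mixes to 1/(1+s)
    # exact identity with the analytic stationary distribution
    expect_lt(abs(s$ptga - s$rates$rate[s$rates$ancestral == "TAA" &
                                          s$rates$derived == "TGA"] /
                    (s$rates$rate[s$rates$ancestral == "TAA" &
                                    s$rates$derived == "TGA"] +
                       s$rates$rate[s$rates$ancestral == "TGA" &
                                      s$rates$derived == "TAA"])), 1e-12)
  }
})

test_that("ptga_deviation is (O-E)/E with a positive-E guard", {
  expect_equal(ptga_deviation(0.5, 0.5)$deviation, 0)
  expect_equal(ptga_deviation(0.6, 0.5)$deviation, 0.2)
  expect_error(ptga_deviation(0.5, 0), "positive")
})

test_that("bootstrap_sd is deterministic, zero for invariant genes", {
  g <- toy_genes(c(rep("TAA", 30), rep("TGA", 30)),
                 c(rep("TGA", 3), rep("TAA", 27), rep("TAA", 3), rep("TGA", 27)),
                 c(rep("TAA", 30), rep("TGA", 30)))
  g$part <- "all"
  b1 <- bootstrap_sd(g, "part", reps = 500, seed = 7)
  b2 <- bootstrap_sd(g, "part", reps = 500, seed = 7)
  expect_identical(b1$boot_sd, b2$boot_sd)
  expect_gt(b1$boot_sd, 0)

  # no variation between genes: every resample gives the same pTGA
  gsame <- toy_genes(rep(c("TAA", "TGA"), each = 20),
                     rep(c("TGA", "TAA"), each = 20),
                     rep(c("TGA", "TAA"), each = 20))
  gsame$part <- "all"
  expect_equal(bootstrap_sd(gsame, "part", reps = 200, seed = 1)$boot_sd, 0)
})

test_that("bootstrap sd is stable in reps (Monte-Carlo consistency)", {
  set.seed(99)
  g <- toy_genes(sample(c("TAA", "TGA"), 400, TRUE),
                 sample(c("TAA", "TGA"), 400, TRUE, prob = c(0.9, 0.1)),
                 sample(c("TAA", "TGA"), 400, TRUE, prob = c(0.9, 0.1)))
  g$part <- "all"
  s1 <- bootstrap_sd(g, "part", reps = 2000, seed = 3)$boot_sd
  s2 <- bootstrap_sd(g, "part", reps = 4000, seed = 4)$boot_sd
  expect_lt(abs(s1 - s2) / s1, 0.15)
})

test_that("twofold flux ratios match hand counts and symmetry", {
  # hand-built toy: 2 CAA->CAG among 4 CAA, 1 CAG->CAA among 2 CAG
  codons <- tibble::tibble(
    ancestral = c(rep("CAA", 4), rep("CAG", 2), rep("AAA", 6)),
    derived = c("CAG", "CAG", "CAA", "CAA", "CAA", "CAG", rep("AAA", 6)),
    recomb_rate = 1
  )
  out <- twofold_flux_ratio(codons, bins = 1)
  gln <- out[out$aa == "Gln", ]
  expect_equal(gln$gc_increasing, 0.5)
  expect_equal(gln$gc_decreasing, 0.5)
  expect_equal(gln$ratio, 1)

  # symmetric substitution gives pooled ratio ~ 1 in every bin
  set.seed(12)
  n <- 30000
  anc <- sample(c(stopflux:::TWOFOLD_PAIRS$low, stopflux:::TWOFOLD_PAIRS$high),
                n, replace = TRUE)
  partner <- c(setNames(stopflux:::TWOFOLD_PAIRS$high, stopflux:::TWOFOLD_PAIRS$low),
               setNames(stopflux:::TWOFOLD_PAIRS$low, stopflux:::TWOFOLD_PAIRS$high))
  flip <- runif(n) < 0.05
  der <- ifelse(flip, partner[anc], anc)
  sym <- tibble::tibble(ancestral = anc, derived = unname(der),
                        recomb_rate = runif(n))
  pooled <- twofold_flux_ratio(sym, bins = 5)
  pooled <- pooled[pooled$aa == "pooled", ]
  expect_equal(nrow(pooled), 5)
  expect_true(all(abs(pooled$ratio - 1) < 0.35))
})

test_that("a planted GC-coupled flux gradient shows up across recombination bins", {
  set.seed(77)
  n <- 40000
  rr <- runif(n)
  anc <- sample(c("CAA", "CAG"), n, replace = TRUE)
  up_p <- 0.02 * (1 + 3 * rr)   # GC-increasing flux grows with recombination
  down_p <- 0.02
  der <- anc
  up <- anc == "CAA" & runif(n) < up_p
  down <- anc == "CAG" & runif(n) < down_p
  der[up] <- "CAG"; der[down] <- "CAA"
  out <- twofold_flux_ratio(tibble::tibble(ancestral = anc, derived = der,
                                           recomb_rate = rr), bins = 10)
  pooled <- out[out$aa == "pooled", ]
  expect_gt(cor(pooled$bin, pooled$ratio, method = "spearman"), 0)
})
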