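#' Genome-wide per-incidence TAA/TGA flux rates
#'
#' Pools all genes and returns the per-incidence rate of TAA to TGA and of
#' TGA to TAA, the rates that parameterise the null simulator.
#'
#' @param flux A `flux_count` over the undivided gene set.
#' @return Named numeric: `taa_tga`, `tga_taa`.
#' @export
genomic_rates <- function(flux) {
  r <- flux_rates(flux)
  inc_taa <- flux$incidences["TAA"]
  inc_tga <- flux$incidences["TGA"]
  if (is.na(inc_taa) || inc_taa == 0 || is.na(inc_tga) || inc_tga == 0) {
    stop("zero TAA or TGA incidence; genomic rates undefined", call. = FALSE)
  }
  c(taa_tga = r$rate[r$ancestral == "TAA" & r$derived == "TGA"],
    tga_taa = r$rate[r$ancestral == "TGA" & r$derived == "TAA"])
}

#' Simulate the null pTGA distribution of a gene group
#'
#' Under the null, every ancestral-TAA incidence in the group fluxes to TGA
#' with the genomic TAA->TGA probability and every ancestral-TGA incidence
#' fluxes to TAA with the genomic TGA->TAA probability. Null event counts
#' divided by ancestral incidences give null rates, hence a null pTGA per
#' replicate. Replicates with undefined pTGA (no TAA->TGA events) are
#' redrawn, keeping the replicate count exact; the number redrawn is
#' recorded in the `"n_redrawn"` attribute.
#'
#' @param group Either a character vector of ancestral stops (each gene
#'   contributing two lineage incidences) or a named numeric
#'   `c(TAA = ..., TGA = ...)` of ancestral incidences.
#' @param rates Named numeric from [genomic_rates()].
#' @param reps Number of null replicates (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of `reps` null pTGA values.
#' @export
simulate_null_ptga <- function(group, rates, reps = 1000, seed = 1) {
  if (is.character(group)) {
    n_taa <- 2 * sum(group == "TAA")
    n_tga <- 2 * sum(group == "TGA")
  } else {
    n_taa <- group[["TAA"]]
    n_tga <- group[["TGA"]]
  }
  if (n_taa < 1 || n_tga < 1) {
    stop("group must contain both TAA and TGA ancestral stops", call. = FALSE)
  }
  if (n_taa * rates[["taa_tga"]] < 1) {
    warning("expected TAA->TGA events per replicate < 1; null badly resolved")
  }
  set.seed(derive_seed(seed, 1L))
  vals <- numeric(reps)
  filled <- 0L
  n_redrawn <- 0L
  while (filled < reps) {
    todo <- reps - filled
    ev_at <- rbinom(todo, n_taa, rates[["taa_tga"]])
    ev_ta <- rbinom(todo, n_tga, rates[["tga_taa"]])
    ptga <- 1 / (1 + (ev_ta / n_tga) / (ev_at / n_taa))
    ok <- ev_at > 0
    n_redrawn <- n_redrawn + sum(!ok)
    keep <- which(ok)
    vals[filled + seq_along(keep)] <- ptga[keep]
    filled <- filled + length(keep)
  }
  attr(vals, "n_redrawn") <- n_redrawn
  vals
}

#' Monte-Carlo p-value for an observed pTGA deviation
#'
#' Draws `m` random pairs (one null pTGA from each group's distribution,
#' with replacement), forms the null deviation `(a - b) / b` per pair, and
#' reports `p = n / m` with `n` the number of null deviations at least as
#' large as the observed one (ties counted, one-sided by default). Pairs
#' whose group-B draw is zero are redrawn and counted.
#'
#' @param dist_a,dist_b Null pTGA distributions of the focal (A) and
#'   reference (B) groups ([simulate_null_ptga()]).
#' @param observed Observed deviation `(O - E) / E`.
#' @param m Number of random pairs (default 10000).
#' @param seed Integer seed.
#' @param two_sided Compare `|deviation|` instead of the signed value.
#' @return A `deviation_test`: list with `observed`, `p`, `n`, `m`,
#'   `null_deviations`, `n_redrawn`, `two_sided`, `seed`. When `n = 0` the
#'   printed p-value is the resolution bound `< 1/m`.
#' @export
deviation_pvalue <- function(dist_a, dist_b, observed, m = 10000, seed = 1,
                             two_sided = FALSE) {
  if (!length(dist_a) || !length(dist_b)) {
    stop("both null distributions must be non-empty", call. = FALSE)
  }
  set.seed(derive_seed(seed, 2L))
  devs <- numeric(m)
  filled <- 0L
  n_redrawn <- 0L
  while (filled < m) {
    todo <- m - filled
    a <- dist_a[sample.int(length(dist_a), todo, replace = TRUE)]
    b <- dist_b[sample.int(length(dist_b), todo, replace = TRUE)]
    ok <- b != 0
    n_redrawn <- n_redrawn + sum(!ok)
    d <- (a[ok] - b[ok]) / b[ok]
    devs[filled + seq_along(d)] <- d
    filled <- filled + length(d)
  }
  n <- if (two_sided) sum(abs(devs) >= abs(observed)) else sum(devs >= observed)
  structure(list(observed = observed, p = n / m, n = n, m = m,
                 null_deviations = devs, n_redrawn = n_redrawn,
                 two_sided = two_sided, seed = seed),
            class = "deviation_test")
}

#' @export
print.deviation_test <- function(x, ...) {
  p_txt <- if (x$n == 0) paste0("< ", format(1 / x$m)) else format(x$p)
  cat("<deviation_test> observed = ", signif(x$observed, 4),
      ", p = ", p_txt, " (n = ", x$n, ", m = ", x$m,
      if (x$two_sided) ", two-sided" else ", one-sided", ")\n", sep = "")
  invisible(x)
}

#' @export
glance.deviation_test <- function(x, ...) {
  tibble(observed = x$observed, p = x$p, p_upper = max(x$p, 1 / x$m),
         n = x$n, m = x$m, two_sided = x$two_sided)
}

#' @export
autoplot.deviation_test <- function(object, ...) {
  df <- tibble(deviation = object$null_deviations)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deviation)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(x = "null pTGA deviation (a-b)/b", y = "pairs",
                  title = sprintf("observed deviation %.3f, p %s",
                                  object$observed,
                                  if (object$n == 0) paste0("< ", 1 / object$m)
                                  else format(object$p)))
}
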