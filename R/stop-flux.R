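#' Count stop-codon flux from ancestral to derived states
#'
#' Each of the two ingroup lineages contributes one incidence of the
#' (resolved) ancestral stop; a lineage whose focal tip codon differs from
#' the ancestor contributes one transition. Tips that are not stop codons
#' are tabulated under the derived class `"nonstop"` and never enter
#' stop-to-stop rate numerators. Genes whose ancestral stop is unresolved
#' are skipped and counted.
#'
#' @param genes Tibble with columns `ancestral` (TAA/TGA/TAG or
#'   `"unresolved"`), `tip1`, `tip2` (the two ingroup focal codons).
#' @return A `flux_count`: list with `incidences` (named numeric over
#'   ancestral stops), `transitions` (tibble `ancestral`, `derived`,
#'   `count`), `n_genes`, `n_skipped`.
#' @export
count_stop_flux <- function(genes) {
  resolved <- genes$ancestral %in% STOPS
  n_skipped <- sum(!resolved)
  if (n_skipped > 0) {
    message(n_skipped, " gene(s) with unresolved ancestral stop skipped")
  }
  g <- genes[resolved, , drop = FALSE]
  inc <- 2 * table(factor(g$ancestral, levels = STOPS))
  incidences <- setNames(as.numeric(inc), STOPS)

  long <- tibble(
    ancestral = rep(g$ancestral, 2L),
    derived = c(g$tip1, g$tip2)
  )
  long$derived[!(long$derived %in% STOPS)] <- "nonstop"
  trans <- long |>
    dplyr::filter(.data$derived != .data$ancestral) |>
    dplyr::count(.data$ancestral, .data$derived, name = "count") |>
    dplyr::arrange(.data$ancestral, .data$derived)

  structure(list(incidences = incidences, transitions = trans,
                 n_genes = nrow(g), n_skipped = n_skipped),
            class = "flux_count")
}

#' @export
print.flux_count <- function(x, ...) {
  cat("<flux_count> ", x$n_genes, " genes (", x$n_skipped, " skipped); ",
      "incidences TAA/TGA/TAG = ",
      paste(x$incidences, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Per-incidence transition rates of a flux count
#'
#' @param flux A `flux_count`.
#' @return Tibble `ancestral`, `derived`, `incidences`, `count`, `rate`
#'   covering all six stop-to-stop transitions (zero counts included) plus
#'   any stop-to-nonstop rows observed.
#' @export
flux_rates <- function(flux) {
  grid <- tidyr::expand_grid(ancestral = STOPS, derived = STOPS) |>
    dplyr::filter(.data$ancestral != .data$derived)
  extra <- dplyr::distinct(flux$transitions[flux$transitions$derived == "nonstop",
                                            c("ancestral", "derived")])
  grid <- dplyr::bind_rows(grid, extra)
  out <- dplyr::left_join(grid, flux$transitions, by = c("ancestral", "derived"))
  out$count[is.na(out$count)] <- 0
  out$incidences <- unname(flux$incidences[out$ancestral])
  out$rate <- ifelse(out$incidences > 0, out$count / out$incidences, NA_real_)
  dplyr::select(out, "ancestral", "derived", "incidences", "count", "rate")
}

#' @export
tidy.flux_count <- function(x, ...) flux_rates(x)

#' Equilibrium TGA share implied by TAA/TGA flux
#'
#' Computes the per-incidence rates of TAA to TGA and TGA to TAA (fluxes
#' involving TAG are excluded), their ratio `s = rate(TGA->TAA) /
#' rate(TAA->TGA)`, and the predicted equilibrium TGA share
#' `pTGA = 1 / (1 + s)` — the stationary TGA fraction of the two-state
#' TAA/TGA chain.
#'
#' @param flux A `flux_count`.
#' @return A `flux_summary`: list with `rates` (tibble), `s`, `ptga`,
#'   `boot_sd` (NA until [bootstrap_sd()] is run).
#' @export
compute_ptga <- function(flux) {
  r <- flux_rates(flux)
  r_at <- r$rate[r$ancestral == "TAA" & r$derived == "TGA"]
  r_ta <- r$rate[r$ancestral == "TGA" & r$derived == "TAA"]
  if (!length(r_at) || !length(r_ta) ||
      is.na(r_at) || is.na(r_ta)) {
    stop("TAA and TGA incidences are required to compute pTGA", call. = FALSE)
  }
  if (r_at == 0 && r_ta == 0) {
    stop("both TAA->TGA and TGA->TAA rates are zero; pTGA undefined",
         call. = FALSE)
  }
  if (r_at == 0) {
    warning("TAA->TGA rate is zero; pTGA = 0 (TAA absorbing)")
    s <- Inf
    ptga <- 0
  } else {
    s <- r_ta / r_at
    ptga <- 1 / (1 + s)
  }
  structure(list(rates = r, s = s, ptga = ptga, boot_sd = NA_real_),
            class = "flux_summary")
}

#' @export
print.flux_summary <- function(x, ...) {
  cat("<flux_summary> pTGA = ", signif(x$ptga, 4),
      " (s = ", signif(x$s, 4), ")",
      if (!is.na(x$boot_sd)) paste0(", bootstrap sd = ", signif(x$boot_sd, 3)),
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.flux_summary <- function(x, ...) {
  tibble(s = x$s, ptga = x$ptga, boot_sd = x$boot_sd)
}

#' Deviation of one pTGA from a reference pTGA
#'
#' `(O - E) / E` where `O` is the focal partition's pTGA (e.g. GC-rich
#' genes) and `E` the reference's (GC-poor genes).
#'
#' @param focal,reference `flux_summary` objects or plain pTGA numbers.
#' @return Tibble with `observed`, `expected`, `deviation`.
#' @export
ptga_deviation <- function(focal, reference) {
  O <- if (inherits(focal, "flux_summary")) focal$ptga else focal
  E <- if (inherits(reference, "flux_summary")) reference$ptga else reference
  if (!is.finite(E) || E <= 0) {
    stop("reference pTGA must be positive to form (O-E)/E", call. = FALSE)
  }
  tibble(observed = O, expected = E, deviation = (O - E) / E)
}

## Per-gene contribution table used by the bootstrap: each resample only
## needs these four sums.
.gene_flux_contrib <- function(genes) {
  g <- genes[genes$ancestral %in% c("TAA", "TGA"), , drop = FALSE]
  cbind(
    inc_taa = 2 * (g$ancestral == "TAA"),
    inc_tga = 2 * (g$ancestral == "TGA"),
    ev_at = (g$ancestral == "TAA") *
      ((g$tip1 == "TGA") + (g$tip2 == "TGA")),
    ev_ta = (g$ancestral == "TGA") *
      ((g$tip1 == "TAA") + (g$tip2 == "TAA"))
  )
}

.ptga_from_sums <- function(s) {
  # s: matrix with columns inc_taa, inc_tga, ev_at, ev_ta
  r_at <- s[, "ev_at"] / s[, "inc_taa"]
  r_ta <- s[, "ev_ta"] / s[, "inc_tga"]
  ptga <- 1 / (1 + r_ta / r_at)
  ptga[is.finite(r_ta) & r_at == 0 & r_ta > 0] <- 0
  ptga[s[, "inc_taa"] == 0 | s[, "inc_tga"] == 0 |
         (r_at == 0 & r_ta == 0)] <- NA_real_
  ptga
}

#' Bootstrap standard deviation of pTGA within partitions
#'
#' Resamples genes with replacement within each partition and recomputes
#' pTGA per resample; resamples where pTGA is undefined (no TAA->TGA
#' events, or a stop class absent) are skipped and counted.
#'
#' @param genes Tibble with `ancestral`, `tip1`, `tip2` and a partition
#'   column.
#' @param partition Name of the partition column (use a constant column for
#'   a single partition).
#' @param reps Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return Tibble `partition`, `ptga`, `boot_sd`, `n_genes`, `n_invalid`.
#' @export
bootstrap_sd <- function(genes, partition, reps = 10000, seed = 1) {
  stopifnot(reps >= 1)
  parts <- unique(genes[[partition]])
  out <- vector("list", length(parts))
  for (pi in seq_along(parts)) {
    g <- genes[genes[[partition]] == parts[pi] & genes$ancestral %in% STOPS, ,
               drop = FALSE]
    contrib <- .gene_flux_contrib(g)
    n <- nrow(contrib)
    if (n == 0) stop("partition '", parts[pi], "' has no usable genes", call. = FALSE)
    point <- .ptga_from_sums(rbind(colSums(contrib)))
    set.seed(derive_seed(seed, pi))
    vals <- numeric(reps)
    done <- 0L
    while (done < reps) {
      block <- min(2000L, reps - done)
      # resample gene multiplicities directly: counts ~ Multinomial(n, 1/n)
      mult <- stats::rmultinom(block, n, rep(1 / n, n))
      sums <- t(mult) %*% contrib
      colnames(sums) <- colnames(contrib)
      vals[done + seq_len(block)] <- .ptga_from_sums(sums)
      done <- done + block
    }
    n_invalid <- sum(is.na(vals))
    if (n_invalid > reps / 2) {
      stop("partition '", parts[pi], "': >50% of bootstrap resamples had ",
           "undefined pTGA; partition too sparse", call. = FALSE)
    }
    out[[pi]] <- tibble(partition = parts[pi], ptga = as.numeric(point),
                        boot_sd = sd(vals[!is.na(vals)]),
                        n_genes = n, n_invalid = n_invalid)
  }
  dplyr::bind_rows(out)
}

## The 12 two-fold degenerate synonymous codon pairs (third-position
## transitions). `low` is the A/T-ending codon, `high` the G/C-ending one,
## so low -> high increases GC and high -> low decreases it.
TWOFOLD_PAIRS <- tibble::tibble(
  aa = c("Phe", "Tyr", "His", "Gln", "Asn", "Lys", "Asp", "Glu", "Cys",
         "Leu", "Ser", "Arg"),
  low = c("TTT", "TAT", "CAT", "CAA", "AAT", "AAA", "GAT", "GAA", "TGT",
          "TTA", "AGT", "AGA"),
  high = c("TTC", "TAC", "CAC", "CAG", "AAC", "AAG", "GAC", "GAG", "TGC",
           "TTG", "AGC", "AGG")
)

#' GC-increasing versus GC-decreasing flux at two-fold degenerate sites
#'
#' For each recombination bin and each of the 12 two-fold degenerate
#' synonymous codon pairs, computes the per-incidence rate of third-position
#' GC-increasing transitions (..A to ..G, ..T to ..C) and of the reverse,
#' plus a pooled row per bin aggregating counts across amino acids.
#'
#' @param codons Tibble with one row per (gene, lineage, codon site):
#'   columns `ancestral`, `derived` (codon strings) and `recomb_rate`.
#' @param bins Number of recombination-rate bins (default 10).
#' @return Tibble `bin`, `aa`, `incidences_low`, `incidences_high`,
#'   `gc_increasing`, `gc_decreasing`, `ratio` (`NA` where the decreasing
#'   rate is zero); `aa == "pooled"` rows aggregate each bin.
#' @export
twofold_flux_ratio <- function(codons, bins = 10) {
  codons <- codons[codons$ancestral %in% c(TWOFOLD_PAIRS$low, TWOFOLD_PAIRS$high), ,
                   drop = FALSE]
  if (!nrow(codons)) stop("no two-fold degenerate ancestral codons", call. = FALSE)
  codons <- decile_bins(codons, "recomb_rate", bins = bins)
  pair_of <- c(setNames(TWOFOLD_PAIRS$aa, TWOFOLD_PAIRS$low),
               setNames(TWOFOLD_PAIRS$aa, TWOFOLD_PAIRS$high))
  partner <- c(setNames(TWOFOLD_PAIRS$high, TWOFOLD_PAIRS$low),
               setNames(TWOFOLD_PAIRS$low, TWOFOLD_PAIRS$high))
  is_low <- codons$ancestral %in% TWOFOLD_PAIRS$low

  per <- tibble(
    bin = codons$.bin,
    aa = pair_of[codons$ancestral],
    inc_low = as.numeric(is_low),
    inc_high = as.numeric(!is_low),
    up = as.numeric(is_low & codons$derived == partner[codons$ancestral]),
    down = as.numeric(!is_low & codons$derived == partner[codons$ancestral])
  )
  summarise_rates <- function(d) {
    d |>
      dplyr::summarise(
        incidences_low = sum(.data$inc_low),
        incidences_high = sum(.data$inc_high),
        gc_increasing = sum(.data$up) / sum(.data$inc_low),
        gc_decreasing = sum(.data$down) / sum(.data$inc_high),
        .groups = "drop"
      ) |>
      dplyr::mutate(ratio = dplyr::if_else(
        is.finite(.data$gc_decreasing) & .data$gc_decreasing > 0,
        .data$gc_increasing / .data$gc_decreasing, NA_real_))
  }
  by_aa <- per |> dplyr::group_by(.data$bin, .data$aa) |> summarise_rates()
  pooled <- per |> dplyr::group_by(.data$bin) |> summarise_rates() |>
    dplyr::mutate(aa = "pooled", .after = "bin")
  dplyr::bind_rows(by_aa, pooled) |> dplyr::arrange(.data$bin, .data$aa)
}
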