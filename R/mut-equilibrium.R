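#' Read a de novo mutation table against a reference
#'
#' TSV columns: chromosome, position (1-based), reference allele, alternate
#' allele (header tolerated). Non-SNV rows are dropped with a count. Rows
#' whose reference allele disagrees with the reference sequence are dropped
#' and logged; more than 1% disagreement aborts (assembly mismatch). Local
#' GC is computed over a centred 10 kb window clipped at contig ends.
#'
#' @param path Path to the TSV.
#' @param reference A `genome_bundle` or named character vector of contig
#'   sequences.
#' @param window Local-GC window width in bp (default 10000).
#' @return Tibble `contig`, `pos`, `ref`, `alt`, `local_gc` with attributes
#'   `n_ref_mismatch` and `n_non_snv`.
#' @export
read_mutations <- function(path, reference, window = 10000) {
  contigs <- if (inherits(reference, "genome_bundle")) reference$contigs else reference
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "character",
                                          "character"))
  names(tab) <- c("contig", "pos", "ref", "alt")
  tab$ref <- toupper(tab$ref); tab$alt <- toupper(tab$alt)

  snv <- nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
    tab$ref %in% BASES & tab$alt %in% BASES & tab$ref != tab$alt
  n_non_snv <- sum(!snv)
  tab <- tab[snv, , drop = FALSE]

  bad_contig <- setdiff(unique(tab$contig), names(contigs))
  if (length(bad_contig)) {
    stop("mutation contig '", bad_contig[1], "' absent from reference",
         call. = FALSE)
  }
  obs <- substring(contigs[tab$contig], tab$pos, tab$pos)
  mismatch <- obs != tab$ref
  # tolerate isolated mismatches in small tables; a systematic excess
  # (>1% and at least 10 rows) indicates the wrong assembly
  if (mean(mismatch) > 0.01 && sum(mismatch) >= 10) {
    stop(sum(mismatch), "/", nrow(tab), " reference-allele mismatches ",
         "(>1%): assembly mismatch", call. = FALSE)
  }
  if (any(mismatch)) {
    message(sum(mismatch), " mutation(s) dropped: reference allele mismatch")
  }
  tab <- tab[!mismatch, , drop = FALSE]

  half <- window %/% 2L
  clen <- nchar(contigs)[tab$contig]
  lo <- pmax(tab$pos - half, 1L)
  hi <- pmin(tab$pos + half, clen)
  tab$local_gc <- vapply(seq_len(nrow(tab)), function(i) {
    gc_fraction(substring(contigs[tab$contig[i]], lo[i], hi[i]))
  }, numeric(1))

  out <- as_tibble(tab)
  attr(out, "n_ref_mismatch") <- sum(mismatch)
  attr(out, "n_non_snv") <- n_non_snv
  out
}

## Merge the centred windows of a set of positions into disjoint intervals
## (1-based inclusive) per contig.
.merged_windows <- function(mutations, contigs, window) {
  half <- window %/% 2L
  out <- list()
  for (ctg in unique(mutations$contig)) {
    pos <- sort(mutations$pos[mutations$contig == ctg])
    lo <- pmax(pos - half, 1L)
    hi <- pmin(pos + half, nchar(contigs[[ctg]]))
    keep_lo <- lo[1]; merged <- NULL; cur_hi <- hi[1]
    for (i in seq_along(pos)[-1]) {
      if (lo[i] <= cur_hi + 1L) {
        cur_hi <- max(cur_hi, hi[i])
      } else {
        merged <- rbind(merged, c(keep_lo, cur_hi))
        keep_lo <- lo[i]; cur_hi <- hi[i]
      }
    }
    merged <- rbind(merged, c(keep_lo, cur_hi))
    out[[ctg]] <- merged
  }
  out
}

.exposure_counts <- function(contigs, intervals, order = 1L) {
  k <- 4L^order
  counts <- numeric(k)
  names(counts) <- if (order == 1L) BASES else DINUCS
  for (ctg in names(intervals)) {
    for (r in seq_len(nrow(intervals[[ctg]]))) {
      v <- encode_seq(substring(contigs[[ctg]], intervals[[ctg]][r, 1],
                                intervals[[ctg]][r, 2]))
      if (order == 1L) {
        counts <- counts + tabulate(v[!is.na(v)], nbins = 4L)
      } else {
        L <- length(v)
        if (L < 2L) next
        idx <- (v[1:(L - 1L)] - 1L) * 4L + v[2:L]
        counts <- counts + tabulate(idx[!is.na(idx)], nbins = 16L)
      }
    }
  }
  counts
}

.poisson_ci <- function(count) {
  ci <- stats::poisson.test(count)$conf.int
  c(ci[1], ci[2])
}

.mut_matrix <- function(kind, counts, exposure, n_mutations) {
  rates <- counts / ifelse(exposure > 0, exposure, NA_real_)
  k <- nrow(counts)
  ci_lo <- ci_hi <- matrix(NA_real_, k, k, dimnames = dimnames(counts))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || is.na(rates[i, j])) next
    ci <- .poisson_ci(counts[i, j])
    ci_lo[i, j] <- ci[1] / exposure[i]
    ci_hi[i, j] <- ci[2] / exposure[i]
  }
  structure(list(kind = kind, counts = counts, exposure = exposure,
                 rates = rates, ci_lo = ci_lo, ci_hi = ci_hi,
                 n_mutations = n_mutations),
            class = "mut_matrix")
}

#' Mononucleotide mutation-rate matrix
#'
#' Rates are observed changes per incidence of the ancestral nucleotide in
#' the exposure region; 95% confidence intervals are exact Poisson
#' intervals on the count, scaled by exposure. The default exposure region
#' is the union of the mutations' centred 10 kb windows, so rates and local
#' composition are measured on the same sequence; `exposure = "genome"`
#' uses the whole reference instead.
#'
#' @param mutations Tibble from [read_mutations()].
#' @param reference A `genome_bundle` or named character vector.
#' @param exposure `"windows"` (default) or `"genome"`.
#' @param window Window width for `"windows"` exposure.
#' @return A `mut_matrix` (kind `"mono"`): counts, exposure, rates and CI
#'   bounds, all 4 x 4 with empty diagonal.
#' @export
build_mono_matrix <- function(mutations, reference,
                              exposure = c("windows", "genome"),
                              window = 10000) {
  exposure <- match.arg(exposure)
  contigs <- if (inherits(reference, "genome_bundle")) reference$contigs else reference
  counts <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  tb <- table(factor(mutations$ref, BASES), factor(mutations$alt, BASES))
  counts[] <- as.numeric(tb)
  exp_counts <- if (exposure == "genome") {
    .exposure_counts(contigs, lapply(contigs, function(s) cbind(1L, nchar(s))),
                     order = 1L)
  } else {
    .exposure_counts(contigs, .merged_windows(mutations, contigs, window),
                     order = 1L)
  }
  if (any(exp_counts == 0)) {
    stop("exposure region lacks nucleotide(s): ",
         paste(BASES[exp_counts == 0], collapse = ", "), call. = FALSE)
  }
  .mut_matrix("mono", counts, exp_counts, nrow(mutations))
}

#' Dinucleotide mutation-rate matrix
#'
#' A point mutation at position i contributes the two overlapping
#' dinucleotide transitions `(i-1, i)` and `(i, i+1)`; at a contig end only
#' the existing side is counted. Set `both_sides = FALSE` to count only the
#' right-hand dinucleotide (sensitivity mode). Exposure is the dinucleotide
#' occurrence count over the exposure region.
#'
#' @inheritParams build_mono_matrix
#' @param both_sides Count both overlapping dinucleotides (default) or only
#'   the right-hand one.
#' @return A `mut_matrix` (kind `"dinuc"`), 16 x 16; only transitions
#'   between dinucleotides differing at exactly one position can be
#'   non-zero.
#' @export
build_dinuc_matrix <- function(mutations, reference,
                               exposure = c("windows", "genome"),
                               window = 10000, both_sides = TRUE) {
  exposure <- match.arg(exposure)
  contigs <- if (inherits(reference, "genome_bundle")) reference$contigs else reference
  counts <- matrix(0, 16, 16, dimnames = list(DINUCS, DINUCS))
  clen <- nchar(contigs)[mutations$contig]
  left <- substring(contigs[mutations$contig], mutations$pos - 1L, mutations$pos - 1L)
  right <- substring(contigs[mutations$contig], mutations$pos + 1L, mutations$pos + 1L)
  add_pairs <- function(from, to) {
    ok <- from %in% DINUCS & to %in% DINUCS
    tb <- table(factor(from[ok], DINUCS), factor(to[ok], DINUCS))
    counts + as.matrix(tb)
  }
  if (both_sides) {
    has_left <- mutations$pos > 1L
    counts <- add_pairs(paste0(left[has_left], mutations$ref[has_left]),
                        paste0(left[has_left], mutations$alt[has_left]))
  }
  has_right <- mutations$pos < clen
  counts <- add_pairs(paste0(mutations$ref[has_right], right[has_right]),
                      paste0(mutations$alt[has_right], right[has_right]))
  exp_counts <- if (exposure == "genome") {
    .exposure_counts(contigs, lapply(contigs, function(s) cbind(1L, nchar(s))),
                     order = 2L)
  } else {
    .exposure_counts(contigs, .merged_windows(mutations, contigs, window),
                     order = 2L)
  }
  observed_from <- rowSums(counts) > 0
  if (any(observed_from & exp_counts == 0)) {
    stop("observed transitions from dinucleotide(s) absent from the ",
         "exposure region: ",
         paste(DINUCS[observed_from & exp_counts == 0], collapse = ", "),
         call. = FALSE)
  }
  .mut_matrix("dinuc", counts, exp_counts, nrow(mutations))
}

#' @export
print.mut_matrix <- function(x, ...) {
  cat("<mut_matrix> ", x$kind, ", ", x$n_mutations, " mutations, ",
      sum(x$counts), " counted transitions\n", sep = "")
  invisible(x)
}

#' @export
tidy.mut_matrix <- function(x, ...) {
  k <- nrow(x$counts)
  nm <- rownames(x$counts)
  grid <- tidyr::expand_grid(from = nm, to = nm) |>
    dplyr::filter(.data$from != .data$to)
  grid |>
    dplyr::mutate(
      count = x$counts[cbind(.data$from, .data$to)],
      exposure = x$exposure[.data$from],
      rate = x$rates[cbind(.data$from, .data$to)],
      ci_lo = x$ci_lo[cbind(.data$from, .data$to)],
      ci_hi = x$ci_hi[cbind(.data$from, .data$to)]
    )
}

## Reachability closure of a boolean adjacency matrix.
.reachable <- function(adj) {
  k <- nrow(adj)
  reach <- adj | diag(TRUE, k)
  for (step in seq_len(ceiling(log2(k)) + 1L)) {
    reach <- (reach %*% reach) > 0
  }
  reach
}

#' Stationary distribution of a rate matrix
#'
#' Solves the global-balance system (gain equals loss for every state) with
#' the sum-to-one constraint by a linear solve. The result equals the
#' long-run distribution of the embedded per-generation chain.
#'
#' @param rates Square matrix of off-diagonal transition rates (the
#'   diagonal is ignored), e.g. the `rates` slot of a `mut_matrix`.
#' @return Named numeric simplex over the states.
#' @export
solve_stationary <- function(rates) {
  if (inherits(rates, "mut_matrix")) rates <- rates$rates
  q <- as.matrix(rates)
  q[is.na(q)] <- 0
  diag(q) <- 0
  k <- nrow(q)
  reach <- .reachable(q > 0)
  if (!all(reach & t(reach))) {
    mutual <- reach & t(reach)
    classes <- unique(apply(mutual, 1, function(r) paste(which(r), collapse = ",")))
    absorbing <- classes[vapply(classes, function(cl) {
      idx <- as.integer(strsplit(cl, ",")[[1]])
      all(!reach[idx, -idx, drop = FALSE])
    }, logical(1))]
    nm <- rownames(q) %||% as.character(seq_len(k))
    lab <- vapply(absorbing, function(cl) {
      paste(nm[as.integer(strsplit(cl, ",")[[1]])], collapse = "+")
    }, character(1))
    stop("rate matrix is reducible; absorbing class: ",
         paste(lab, collapse = "; "), call. = FALSE)
  }
  diag(q) <- -rowSums(q)
  A <- rbind(t(q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  setNames(as.numeric(pi), rownames(rates))
}

#' Mononucleotide mutational equilibrium
#'
#' Stationary nucleotide frequencies N* of the 4 x 4 mutation-rate matrix,
#' the implied equilibrium GC content GC* = N*(G) + N*(C), and the
#' two-class reduction: `m = rate(GC->AT) / rate(AT->GC)` (per-incidence
#' rates pooled within each class) with `P_n = 1 / (1 + m)`.
#'
#' @param matrix A mono `mut_matrix`.
#' @return A list with `nstar` (named 4-simplex), `gcstar`, `m`, `pn`.
#' @export
mono_equilibrium <- function(matrix) {
  stopifnot(inherits(matrix, "mut_matrix"), matrix$kind == "mono")
  nstar <- solve_stationary(matrix$rates)
  cts <- matrix$counts; expo <- matrix$exposure
  gc_at <- sum(cts[c("G", "C"), c("A", "T")]) / sum(expo[c("G", "C")])
  at_gc <- sum(cts[c("A", "T"), c("G", "C")]) / sum(expo[c("A", "T")])
  m <- gc_at / at_gc
  list(nstar = nstar, gcstar = unname(nstar["G"] + nstar["C"]),
       m = m, pn = 1 / (1 + m))
}

#' Stop-codon mutational equilibrium
#'
#' Predicts equilibrium TAA/TGA/TAG frequencies from a mononucleotide
#' mutation matrix using substitution controls for the six stop-to-stop
#' fluxes: TAA->TGA and TAA->TAG take the A->G rate, TGA->TAA and TAG->TAA
#' the G->A rate, and TGA->TAG and TAG->TGA take `2 * A->G * G->A`
#' (double-step exchanges). Stop-to-sense flux is ignored. The three
#' balance equations (gain = loss per stop) are solved after replacing one
#' stop frequency by one minus the sum of the other two; the result is
#' invariant to which stop is eliminated.
#'
#' @param matrix A mono `mut_matrix`, or a 4 x 4 rates matrix with
#'   dimnames A/C/G/T.
#' @param eliminate Which stop frequency to replace by the sum constraint.
#' @return A `stop_equilibrium`: list with `taa`, `tga`, `tag`, `fluxes`
#'   (tibble `from`, `to`, `rate`), `residuals` (balance-equation
#'   residuals), `eliminated`.
#' @export
stop_equilibrium <- function(matrix, eliminate = c("TAG", "TAA", "TGA")) {
  eliminate <- match.arg(eliminate)
  rates <- if (inherits(matrix, "mut_matrix")) matrix$rates else matrix
  r_ag <- rates["A", "G"]
  r_ga <- rates["G", "A"]
  if (is.na(r_ag) || r_ag == 0) stop("A->G rate is zero", call. = FALSE)
  if (is.na(r_ga) || r_ga == 0) stop("G->A rate is zero", call. = FALSE)

  f <- matrix(0, 3, 3, dimnames = list(STOPS, STOPS))
  f["TAA", "TGA"] <- r_ag
  f["TAA", "TAG"] <- r_ag
  f["TGA", "TAA"] <- r_ga
  f["TAG", "TAA"] <- r_ga
  f["TGA", "TAG"] <- 2 * r_ag * r_ga
  f["TAG", "TGA"] <- 2 * r_ag * r_ga

  keep <- setdiff(STOPS, eliminate)
  loss <- rowSums(f)
  # balance for each retained stop i, with p[eliminate] = 1 - sum(p[keep])
  A <- matrix(0, 2, 2, dimnames = list(keep, keep))
  b <- numeric(2)
  for (r in 1:2) {
    i <- keep[r]
    A[r, i] <- loss[i] + f[eliminate, i]
    j <- setdiff(keep, i)
    A[r, j] <- -f[j, i] + f[eliminate, i]
    b[r] <- f[eliminate, i]
  }
  p_keep <- solve(A, b)
  p <- setNames(numeric(3), STOPS)
  p[keep] <- p_keep
  p[eliminate] <- 1 - sum(p_keep)

  residuals <- vapply(STOPS, function(i) {
    abs(p[i] * loss[i] - sum(p[setdiff(STOPS, i)] * f[setdiff(STOPS, i), i]))
  }, numeric(1))

  fluxes <- tidyr::expand_grid(from = STOPS, to = STOPS) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::mutate(rate = f[cbind(.data$from, .data$to)])

  structure(list(taa = unname(p["TAA"]), tga = unname(p["TGA"]),
                 tag = unname(p["TAG"]), fluxes = fluxes,
                 residuals = residuals, eliminated = eliminate),
            class = "stop_equilibrium")
}

#' @export
print.stop_equilibrium <- function(x, ...) {
  cat("<stop_equilibrium> TAA* = ", signif(x$taa, 4),
      ", TGA* = ", signif(x$tga, 4), ", TAG* = ", signif(x$tag, 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.stop_equilibrium <- function(x, ...) {
  tibble(stop = STOPS, frequency = c(x$taa, x$tga, x$tag))
}

#' Mutational equilibria within local-GC bins
#'
#' Orders mutations by the GC content of their surrounding window, splits
#' them into equal-count bins, and recomputes GC* and the stop-codon
#' equilibria within each bin with bin-specific exposure. With
#' `kind = "dinuc"` GC* comes from the 16-state stationary distribution and
#' the stop shares from the first-order Markov chain implied by the
#' dinucleotide equilibrium (closed form, or simulation when
#' `closed_form = FALSE`).
#'
#' @param mutations Tibble from [read_mutations()] (needs `local_gc`).
#' @param reference A `genome_bundle` or named character vector.
#' @param bins Number of equal-count bins (default 10).
#' @param kind `"mono"` or `"dinuc"`.
#' @param window Exposure window width.
#' @param closed_form Use the closed-form chain trinucleotide probabilities
#'   for the dinucleotide stop shares (default) instead of simulation.
#' @param n_sim,sim_length,seed Simulation size when `closed_form = FALSE`.
#' @return Tibble `bin`, `gc_lo`, `gc_hi`, `n_mutations`, `gc_star`,
#'   `taa_star`, `tga_star`, `tag_star`, `flagged` (TRUE when a bin's
#'   chain was reducible and its equilibrium is absent).
#' @export
binned_equilibria <- function(mutations, reference, bins = 10,
                              kind = c("mono", "dinuc"), window = 10000,
                              closed_form = TRUE, n_sim = 2000,
                              sim_length = 300, seed = 1) {
  kind <- match.arg(kind)
  if (nrow(mutations) < bins * 100) {
    stop("need at least ", bins * 100, " mutations for ", bins, " bins",
         call. = FALSE)
  }
  mutations$.row <- seq_len(nrow(mutations))
  binned <- decile_bins(dplyr::rename(mutations, gene_id = ".row"),
                        "local_gc", bins = bins)
  out <- vector("list", bins)
  for (b in seq_len(bins)) {
    mb <- binned[binned$.bin == b, , drop = FALSE]
    row <- tibble(bin = b, gc_lo = min(mb$local_gc), gc_hi = max(mb$local_gc),
                  n_mutations = nrow(mb), gc_star = NA_real_,
                  taa_star = NA_real_, tga_star = NA_real_,
                  tag_star = NA_real_, flagged = FALSE)
    res <- tryCatch({
      if (kind == "mono") {
        mat <- build_mono_matrix(mb, reference, window = window)
        eq <- mono_equilibrium(mat)
        se <- stop_equilibrium(mat)
        list(gc = eq$gcstar, taa = se$taa, tga = se$tga, tag = se$tag)
      } else {
        mat <- build_dinuc_matrix(mb, reference, window = window)
        dstar <- solve_stationary(mat$rates)
        gc_star <- sum(dstar * vapply(DINUCS, function(d) {
          sum(strsplit(d, "")[[1]] %in% c("G", "C")) / 2
        }, numeric(1)))
        model <- markov_from_dinuc(dstar)
        tf <- if (closed_form) {
          trinuc_expected(model)
        } else {
          sim <- simulate_sequences(model, n = n_sim, length = sim_length,
                                    seed = derive_seed(seed, b))
          null_trinuc_frequencies(sim)$frequencies
        }
        st <- tf[STOPS] / sum(tf[STOPS])
        list(gc = gc_star, taa = unname(st["TAA"]), tga = unname(st["TGA"]),
             tag = unname(st["TAG"]))
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      row$flagged <- TRUE
    } else {
      row$gc_star <- res$gc; row$taa_star <- res$taa
      row$tga_star <- res$tga; row$tag_star <- res$tag
    }
    out[[b]] <- row
  }
  dplyr::bind_rows(out)
}

#' @export
#' @rdname binned_equilibria
#' @param x Output of `binned_equilibria()`.
plot_binned_equilibria <- function(x) {
  long <- tidyr::pivot_longer(x, c("gc_star", "tga_star"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = x$bin) +
    ggplot2::labs(x = "local-GC bin (low to high)", y = "equilibrium frequency",
                  colour = NULL)
}
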