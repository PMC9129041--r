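#' GC class of a trinucleotide
#'
#' The percent G+C of the three positions, labelled 0/33/66/100; there are
#' exactly 8, 24, 24 and 8 trinucleotides in the four classes.
#'
#' @param trinuc Character vector of trinucleotides.
#' @return Integer vector with values in `{0, 33, 66, 100}`.
#' @export
gc_class <- function(trinuc) {
  k <- vapply(strsplit(toupper(trinuc), ""), function(v) {
    sum(v %in% c("G", "C"))
  }, integer(1))
  c(0L, 33L, 66L, 100L)[k + 1L]
}

#' Per-trinucleotide deviation from a mutational expectation
#'
#' `(O - E) / E` per trinucleotide, the deviation of observed fixed
#' frequencies from the mutational-equilibrium null. Trinucleotides with a
#' zero expectation get `NA` and are logged.
#'
#' @param observed,expected `trinuc_profile` objects or named numeric
#'   frequency vectors over the 64 trinucleotides.
#' @return Tibble `trinuc`, `observed`, `expected`, `deviation`.
#' @export
deviation_D <- function(observed, expected) {
  o <- if (inherits(observed, "trinuc_profile")) observed$frequencies else observed[TRINUCS]
  e <- if (inherits(expected, "trinuc_profile")) expected$frequencies else expected[TRINUCS]
  dev <- ifelse(e > 0, (o - e) / e, NA_real_)
  if (any(e == 0, na.rm = TRUE)) {
    message(sum(e == 0, na.rm = TRUE),
            " trinucleotide(s) with zero expectation: deviation absent")
  }
  tibble(trinuc = TRINUCS, observed = as.numeric(o), expected = as.numeric(e),
         deviation = as.numeric(dev))
}

#' GC-coupled fixation boost
#'
#' The literal second-order deviation `(d1 - d2) / d2` comparing the
#' GC-rich deviation `d1` with the GC-poor deviation `d2`. The formula
#' flips orientation when `d2 < 0`, so the plain difference `d1 - d2` and
#' the `|d2|`-denominator variant are always co-reported by
#' [boost_table()]; this function returns the literal value only. When
#' `d2 = 0` the boost is 0 if `d1 = 0` and absent (with a warning)
#' otherwise.
#'
#' @param d1,d2 Numeric deviations (vectorised).
#' @return Numeric vector.
#' @export
boost <- function(d1, d2) {
  out <- (d1 - d2) / d2
  zero <- !is.na(d2) & d2 == 0
  if (any(zero & d1 != 0, na.rm = TRUE)) {
    warning("boost undefined where d2 = 0 and d1 != 0")
  }
  out[zero] <- ifelse(d1[zero] == 0, 0, NA_real_)
  out
}

#' Full per-trinucleotide boost table
#'
#' Joins the GC-rich (`d1`) and GC-poor (`d2`) deviation tables, computes
#' the literal boost, the plain difference and the `|d2|`-denominator
#' variant, assigns GC classes and ranks trinucleotides by boost within
#' each class (rank 1 = lowest).
#'
#' @param d1,d2 Tibbles from [deviation_D()] for the GC-rich and GC-poor
#'   sequence sets.
#' @param seq_class Optional sequence-class label (CDS, 5'UTR, 3'UTR,
#'   intron, ncRNA, CRE).
#' @return Tibble `trinuc`, `seq_class`, `d1`, `d2`, `diff`, `boost`,
#'   `boost_abs`, `gc_class`, `rank`.
#' @export
boost_table <- function(d1, d2, seq_class = NA_character_) {
  d2_matched <- d2$deviation[match(d1$trinuc, d2$trinuc)]
  out <- tibble(
    trinuc = d1$trinuc,
    seq_class = seq_class,
    d1 = d1$deviation,
    d2 = d2_matched
  )
  out$diff <- out$d1 - out$d2
  out$boost <- boost(out$d1, out$d2)
  out$boost_abs <- ifelse(!is.na(out$d2) & out$d2 != 0,
                          out$diff / abs(out$d2), out$boost)
  out$gc_class <- gc_class(out$trinuc)
  out <- out |>
    dplyr::group_by(.data$gc_class) |>
    dplyr::mutate(rank = rank(.data$boost, na.last = "keep")) |>
    dplyr::ungroup()
  out
}

#' Rank correlations of boost between sequence classes
#'
#' Within each GC class, trinucleotides are ranked by boost separately per
#' sequence class (ties mid-ranked) and the rank vectors of every pair of
#' sequence classes are compared by Pearson correlation over
#' pairwise-complete trinucleotides. Coding sequence is excluded by
#' default, where selection on the encoded protein confounds the fixation
#' signal.
#'
#' @param boosts Tibble with columns `trinuc`, `seq_class`, `boost`
#'   (rows for several sequence classes, e.g. stacked [boost_table()]
#'   outputs).
#' @param exclude Sequence classes to drop (default `"CDS"`).
#' @return Tibble `gc_class`, `class_a`, `class_b`, `r`, `n`.
#' @export
class_rank_correlation <- function(boosts, exclude = "CDS") {
  boosts <- boosts[!(boosts$seq_class %in% exclude), , drop = FALSE]
  boosts$gc_class <- gc_class(boosts$trinuc)
  classes <- sort(unique(boosts$seq_class))
  if (length(classes) < 2) stop("need at least two sequence classes", call. = FALSE)
  out <- list()
  for (g in sort(unique(boosts$gc_class))) {
    bg <- boosts[boosts$gc_class == g, , drop = FALSE]
    wide <- tidyr::pivot_wider(bg[, c("trinuc", "seq_class", "boost")],
                               names_from = "seq_class", values_from = "boost")
    for (i in seq_along(classes)) for (j in seq_along(classes)) {
      if (i >= j) next
      a <- wide[[classes[i]]]; b <- wide[[classes[j]]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3) next
      r <- cor(rank(a[ok]), rank(b[ok]), method = "pearson")
      out[[length(out) + 1L]] <- tibble(gc_class = g, class_a = classes[i],
                                        class_b = classes[j], r = r,
                                        n = sum(ok))
    }
  }
  dplyr::bind_rows(out)
}

.revcomp_trinuc <- function(trinuc) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(trinuc, ""), function(v) {
    paste(comp[rev(v)], collapse = "")
  }, character(1))
}

#' Permutation test of sense/antisense boost similarity
#'
#' Statistic: mean absolute boost difference over the 32 reverse-complement
#' trinucleotide pairs. The null re-pairs trinucleotides at random within
#' their GC class (reverse complementation preserves GC class, so the
#' constraint keeps the composition comparison fair); `p` is the fraction
#' of permutations with a statistic at most the observed one, i.e. small p
#' means the true pairs are unusually similar.
#'
#' @param boosts Named numeric of boosts over the 64 trinucleotides, or a
#'   [boost_table()] tibble (its `boost` column is used).
#' @param permutations Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `perm_test`: list with `observed`, `null`, `p`,
#'   `permutations`, and an `audit` tibble recording the GC class of every
#'   permuted pairing (all within-class by construction).
#' @export
sense_antisense_test <- function(boosts, permutations = 1000, seed = 1) {
  if (is.data.frame(boosts)) {
    boosts <- setNames(boosts$boost, boosts$trinuc)
  }
  boosts <- boosts[TRINUCS]
  rc <- .revcomp_trinuc(TRINUCS)
  pair_first <- TRINUCS[TRINUCS < rc]    # one representative per pair
  if (any(is.na(boosts[pair_first]) | is.na(boosts[rc[match(pair_first, TRINUCS)]]))) {
    stop("boost must be defined for both members of every pair", call. = FALSE)
  }
  observed <- mean(abs(boosts[pair_first] - boosts[.revcomp_trinuc(pair_first)]))

  cls <- gc_class(TRINUCS)
  set.seed(derive_seed(seed, 1L))
  null <- numeric(permutations)
  audit <- NULL
  for (p in seq_len(permutations)) {
    diffs <- numeric(0)
    pairs_cls <- integer(0)
    for (g in unique(cls)) {
      members <- TRINUCS[cls == g]
      perm <- sample(members)
      a <- perm[seq(1, length(perm), by = 2)]
      b <- perm[seq(2, length(perm), by = 2)]
      diffs <- c(diffs, abs(boosts[a] - boosts[b]))
      pairs_cls <- c(pairs_cls, rep(g, length(a)))
    }
    null[p] <- mean(diffs)
    if (p == 1L) audit <- tibble(pair = seq_along(pairs_cls), gc_class = pairs_cls)
  }
  structure(list(observed = observed, null = null,
                 p = mean(null <= observed), permutations = permutations,
                 audit = audit),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  p_txt <- if (all(x$null > x$observed)) paste0("<= ", format(1 / x$permutations))
  else format(x$p)
  cat("<perm_test> observed = ", signif(x$observed, 4), ", p ", p_txt,
      " (", x$permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' Focal-stop enrichment over downstream positions
#'
#' For each stop codon, usage at the termination codon (its relative
#' frequency among the three stops across the gene set) is divided by its
#' mean usage over downstream in-frame codon positions +1 to
#' `+positions` in the 3' UTR. Usage at a downstream position is computed
#' only over genes carrying one of the three stop trinucleotides at that
#' position; positions with no stop trinucleotide in any gene are skipped.
#'
#' @param genes Gene records with `stop` and `utr3` columns.
#' @param positions Number of downstream in-frame codon positions
#'   (default 6).
#' @return Tibble `stop`, `usage_focal`, `usage_downstream`, `enrichment`.
#' @export
stop_enrichment <- function(genes, positions = 6) {
  focal <- stop_usage(genes)
  down <- matrix(NA_real_, nrow = positions, ncol = 3,
                 dimnames = list(NULL, STOPS))
  any_stop <- FALSE
  for (p in seq_len(positions)) {
    codon <- toupper(substring(genes$utr3, 3L * (p - 1L) + 1L, 3L * p))
    codon <- codon[codon %in% STOPS]
    if (!length(codon)) next
    any_stop <- TRUE
    tab <- table(factor(codon, STOPS))
    down[p, ] <- as.numeric(tab) / sum(tab)
  }
  if (!any_stop) {
    stop("no stop trinucleotides at any downstream position", call. = FALSE)
  }
  usage_down <- colMeans(down, na.rm = TRUE)
  tibble(stop = STOPS,
         usage_focal = focal$usage[match(STOPS, focal$stop)],
         usage_downstream = as.numeric(usage_down),
         enrichment = focal$usage[match(STOPS, focal$stop)] / as.numeric(usage_down))
}

#' Partition genes into low- and high-expression sets
#'
#' LEGs are the lowest `quantile` fraction of genes by protein abundance
#' and HEGs the highest; ties are broken by gene id for determinism.
#'
#' @param genes Gene records with `abundance` and `gene_id`.
#' @param quantile Tail fraction (default 0.25).
#' @return `genes` (rows with abundance only) with a `tier` column in
#'   `{"LEG", "mid", "HEG"}`.
#' @export
expression_partition <- function(genes, quantile = 0.25) {
  g <- genes[!is.na(genes$abundance), , drop = FALSE]
  n <- nrow(g)
  if (n < 8) stop("need at least 8 genes with abundance", call. = FALSE)
  k <- floor(n * quantile)
  o <- order(g$abundance, g$gene_id)
  tier <- rep("mid", n)
  tier[o[seq_len(k)]] <- "LEG"
  tier[o[seq(n - k + 1L, n)]] <- "HEG"
  g$tier <- tier
  g
}

#' Boxplot of boost by trinucleotide GC class
#'
#' @param boosts A [boost_table()] tibble (one or more sequence classes).
#' @return A ggplot.
#' @export
plot_boost <- function(boosts) {
  ggplot2::ggplot(boosts,
                  ggplot2::aes(x = factor(.data$gc_class), y = .data$boost)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "trinucleotide GC class (%)",
                  y = "GC-coupled fixation boost (D1-D2)/D2") +
    (if (length(unique(boosts$seq_class)) > 1)
      ggplot2::facet_wrap(~seq_class) else NULL)
}

#' Stop usage across intronic-GC bins
#'
#' @param records Gene records with `stop` and `intronic_gc`.
#' @param bins Number of GC bins (default 10).
#' @return A ggplot of relative TAA/TGA/TAG usage per bin.
#' @export
plot_stop_usage_bins <- function(records, bins = 10) {
  records <- records[!is.na(records$intronic_gc), , drop = FALSE]
  binned <- decile_bins(records, "intronic_gc", bins = bins)
  usage <- binned |>
    dplyr::group_by(.data$.bin) |>
    dplyr::group_modify(~stop_usage(.x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(usage, ggplot2::aes(x = .data$.bin, y = .data$usage,
                                      colour = .data$stop)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(bins)) +
    ggplot2::labs(x = "intronic-GC bin (low to high)",
                  y = "relative stop usage", colour = NULL)
}
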