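#' Construct a nucleotide substitution model for a 3-taxon star tree
#'
#' The tree is the single unrooted 3-taxon topology: one internal node with
#' three pendant branches (ingroup1, ingroup2, outgroup). Under JC69 base
#' frequencies are uniform and kappa is 1; under HKY85 both are free.
#'
#' @param kind `"JC69"` or `"HKY85"`.
#' @param kappa Transition/transversion rate ratio (HKY85).
#' @param pi Base frequencies in A, C, G, T order, summing to 1.
#' @param branch_lengths Three expected substitutions/site, internal node to
#'   ingroup1, ingroup2, outgroup.
#' @return A `sub_model` object.
#' @export
substitution_model <- function(kind = c("HKY85", "JC69"), kappa = 1,
                               pi = rep(0.25, 4), branch_lengths = c(0.1, 0.1, 0.1)) {
  kind <- match.arg(kind)
  if (kind == "JC69") {
    kappa <- 1
    pi <- rep(0.25, 4)
  }
  stopifnot(length(pi) == 4, abs(sum(pi) - 1) < 1e-8, all(pi > 0),
            length(branch_lengths) == 3, all(branch_lengths >= 0), kappa > 0)
  structure(list(kind = kind, kappa = kappa, pi = setNames(pi, BASES),
                 branch_lengths = branch_lengths, loglik = NA_real_,
                 n_columns = NA_integer_),
            class = "sub_model")
}

## HKY85 rate matrix, scaled to one expected substitution per unit time.
.model_Q <- function(model) {
  pi <- model$pi
  k <- model$kappa
  q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- (BASES[i] == "A" && BASES[j] == "G") ||
      (BASES[i] == "G" && BASES[j] == "A") ||
      (BASES[i] == "C" && BASES[j] == "T") ||
      (BASES[i] == "T" && BASES[j] == "C")
    q[i, j] <- if (transition) k * pi[j] else pi[j]
  }
  diag(q) <- -rowSums(q)
  scale <- -sum(pi * diag(q))
  q / scale
}

.branch_P <- function(model) {
  q <- .model_Q(model)
  lapply(model$branch_lengths, function(t) as.matrix(Matrix::expm(q * t)))
}

.aln_codes <- function(alignment) {
  if (is.data.frame(alignment)) {
    alignment <- c(alignment$ingroup1[1], alignment$ingroup2[1], alignment$outgroup[1])
  }
  alignment <- unlist(alignment, use.names = FALSE)
  stopifnot(length(alignment) == 3,
            length(unique(nchar(alignment))) == 1L)
  lapply(alignment, encode_seq)   # gap and N both become NA
}

## Pattern counts over ungapped columns, index (x1-1)*16 + (x2-1)*4 + x3.
.pattern_counts <- function(alignments) {
  counts <- numeric(64)
  for (a in alignments) {
    x <- .aln_codes(a)
    ok <- !is.na(x[[1]]) & !is.na(x[[2]]) & !is.na(x[[3]])
    if (!any(ok)) next
    idx <- (x[[1]][ok] - 1L) * 16L + (x[[2]][ok] - 1L) * 4L + x[[3]][ok]
    counts <- counts + tabulate(idx, nbins = 64L)
  }
  counts
}

.pattern_loglik <- function(counts, model) {
  P <- .branch_P(model)
  i <- seq_len(64) - 1L
  a1 <- i %/% 16L + 1L
  a2 <- (i %/% 4L) %% 4L + 1L
  a3 <- i %% 4L + 1L
  lik <- numeric(64)
  for (anc in 1:4) {
    lik <- lik + model$pi[anc] * P[[1]][anc, a1] * P[[2]][anc, a2] * P[[3]][anc, a3]
  }
  sum(counts * log(pmax(lik, 1e-300)))
}

#' Fit a trio substitution model by maximum likelihood
#'
#' Base frequencies are the empirical tip frequencies; branch lengths (and
#' kappa for HKY85) are optimised by cyclic bounded one-dimensional ascent
#' of the pruning likelihood over ungapped columns. The likelihood is
#' non-decreasing across sweeps.
#'
#' @param alignments A list of trio alignments (each a character vector of 3
#'   equal-length aligned sequences: ingroup1, ingroup2, outgroup) or a
#'   tibble with those three columns.
#' @param kind `"HKY85"` (default) or `"JC69"`.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return A fitted `sub_model` with `loglik` and `n_columns` filled in.
#' @export
fit_model <- function(alignments, kind = c("HKY85", "JC69"), tol = 1e-8) {
  kind <- match.arg(kind)
  if (is.data.frame(alignments)) {
    alignments <- purrr::pmap(
      list(alignments$ingroup1, alignments$ingroup2, alignments$outgroup), c)
  }
  if (length(alignments) == 0) stop("no alignments supplied", call. = FALSE)
  counts <- .pattern_counts(alignments)
  n <- sum(counts)
  if (n == 0) stop("all alignment columns are gapped or ambiguous", call. = FALSE)

  if (kind == "JC69") {
    pi <- rep(0.25, 4)
  } else {
    base_counts <- numeric(4)
    i <- seq_len(64) - 1L
    for (x in list(i %/% 16L + 1L, (i %/% 4L) %% 4L + 1L, i %% 4L + 1L)) {
      base_counts <- base_counts + tapply(counts, x, sum)
    }
    pi <- as.numeric(base_counts / sum(base_counts))
    pi <- pmax(pi, 1e-6); pi <- pi / sum(pi)
  }
  model <- substitution_model(kind, kappa = 2, pi = pi,
                              branch_lengths = c(0.1, 0.1, 0.1))

  ll <- .pattern_loglik(counts, model)
  for (sweep in seq_len(100)) {
    for (b in 1:3) {
      opt <- optimize(function(t) {
        m <- model; m$branch_lengths[b] <- t
        .pattern_loglik(counts, m)
      }, interval = c(0, 3), maximum = TRUE, tol = 1e-6)
      model$branch_lengths[b] <- opt$maximum
    }
    if (kind == "HKY85") {
      opt <- optimize(function(k) {
        m <- model; m$kappa <- k
        .pattern_loglik(counts, m)
      }, interval = c(0.05, 50), maximum = TRUE, tol = 1e-6)
      model$kappa <- opt$maximum
    }
    new_ll <- .pattern_loglik(counts, model)
    if (new_ll - ll < tol) { ll <- new_ll; break }
    ll <- new_ll
  }
  # optimize() never probes the boundary itself; snap near-zero lengths
  model$branch_lengths[model$branch_lengths < 1e-6] <- 0
  model$loglik <- .pattern_loglik(counts, model)
  model$n_columns <- n
  model
}

#' @export
print.sub_model <- function(x, ...) {
  cat("<sub_model> ", x$kind, ", kappa = ", signif(x$kappa, 4),
      ", t = (", paste(signif(x$branch_lengths, 4), collapse = ", "),
      "), logL = ", signif(x$loglik, 8), "\n", sep = "")
  invisible(x)
}

#' @export
glance.sub_model <- function(x, ...) {
  tibble(kind = x$kind, kappa = x$kappa,
         t_ingroup1 = x$branch_lengths[1], t_ingroup2 = x$branch_lengths[2],
         t_outgroup = x$branch_lengths[3], logLik = x$loglik,
         n_columns = x$n_columns)
}

#' @export
tidy.sub_model <- function(x, ...) {
  tibble(term = c("kappa", "t_ingroup1", "t_ingroup2", "t_outgroup",
                  paste0("pi_", BASES)),
         estimate = c(x$kappa, x$branch_lengths, unname(x$pi)))
}

#' Marginal ancestral reconstruction at the internal node
#'
#' For each column, the posterior over the internal-node nucleotide is
#' proportional to `pi(x) * P(x -> tip1 | t1) * P(x -> tip2 | t2) *
#' P(x -> tip3 | t3)`. Tips that are gap or N at a column contribute no
#' likelihood term (the posterior comes from the remaining tips). MAP ties
#' are broken by the fixed nucleotide order A < C < G < T.
#'
#' @param alignment Character vector of 3 aligned sequences (ingroup1,
#'   ingroup2, outgroup).
#' @param model A `sub_model` (fitted or hand-specified).
#' @return An `asr_reconstruction`: list with `posterior` (columns x 4
#'   matrix, rows summing to 1), `map` (integer codes) and `map_seq`
#'   (string).
#' @export
asr_marginal <- function(alignment, model) {
  x <- .aln_codes(alignment)
  L <- length(x[[1]])
  P <- .branch_P(model)
  post <- matrix(rep(model$pi, each = L), nrow = L, ncol = 4,
                 dimnames = list(NULL, BASES))
  for (tip in 1:3) {
    xi <- x[[tip]]
    ok <- !is.na(xi)
    if (!any(ok)) next
    for (a in 1:4) {
      post[ok, a] <- post[ok, a] * P[[tip]][a, xi[ok]]
    }
  }
  post <- post / rowSums(post)
  map <- max.col(post, ties.method = "first")
  structure(list(posterior = post, map = map, map_seq = decode_seq(map),
                 model = model),
            class = "asr_reconstruction")
}

#' @export
print.asr_reconstruction <- function(x, ...) {
  cat("<asr_reconstruction> ", nrow(x$posterior), " columns\n", sep = "")
  invisible(x)
}

#' @export
tidy.asr_reconstruction <- function(x, ...) {
  out <- as_tibble(x$posterior)
  names(out) <- paste0("p_", BASES)
  dplyr::bind_cols(tibble(site = seq_len(nrow(x$posterior)),
                          state = BASES[x$map]), out)
}

#' Ancestral stop codon at the internal node
#'
#' Concatenates the MAP nucleotides at the three stop columns. The call is
#' `"unresolved"` when the resulting codon is not one of TAA/TGA/TAG, or
#' when any stop column carries a gap in two or more of the three aligned
#' sequences.
#'
#' @param reconstruction An `asr_reconstruction`.
#' @param stop_columns Integer vector of the 3 alignment columns holding the
#'   focal stop codon.
#' @param alignment Optional: the 3 aligned sequences, used for the gap
#'   rule; omit to skip it.
#' @return A string: `"TAA"`, `"TGA"`, `"TAG"` or `"unresolved"`.
#' @export
ancestral_stop <- function(reconstruction, stop_columns, alignment = NULL) {
  stopifnot(length(stop_columns) == 3)
  if (!is.null(alignment)) {
    if (is.data.frame(alignment)) {
      alignment <- c(alignment$ingroup1[1], alignment$ingroup2[1],
                     alignment$outgroup[1])
    }
    chars <- vapply(alignment, function(s) substring(s, stop_columns, stop_columns),
                    character(3))
    n_gap <- rowSums(chars == "-")
    if (any(n_gap >= 2)) return("unresolved")
  }
  codon <- paste(BASES[reconstruction$map[stop_columns]], collapse = "")
  if (codon %in% STOPS) codon else "unresolved"
}

#' Import an ancestral-state table
#'
#' Reads a TSV in the IQ-TREE `.state` dialect (columns `Node`, `Site`,
#' `State`, `p_A`, `p_C`, `p_G`, `p_T`) and returns the reconstruction for
#' one node. Posterior rows off unity by at most `1e-6` are renormalised;
#' anything worse, or a malformed row, is an error naming the line.
#'
#' @param path Path to the TSV.
#' @param node Node identifier to extract; may be omitted when the table
#'   holds a single node.
#' @return An `asr_reconstruction`.
#' @export
import_state_table <- function(path, node = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Node", "Site", "State", "p_A", "p_C", "p_G", "p_T")
  if (!all(need %in% names(tab))) {
    stop("state table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(node)) {
    nodes <- unique(tab$Node)
    if (length(nodes) != 1L) {
      stop("table holds ", length(nodes), " nodes; specify `node`", call. = FALSE)
    }
    node <- nodes
  }
  tab <- tab[tab$Node == node, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for node '", node, "'", call. = FALSE)
  p <- as.matrix(tab[, c("p_A", "p_C", "p_G", "p_T")])
  bad <- which(!complete.cases(p) | !is.finite(tab$Site))
  if (length(bad)) {
    stop("malformed state-table row at line ", bad[1] + 1L, call. = FALSE)
  }
  rs <- rowSums(p)
  off <- which(abs(rs - 1) > 1e-6 + 1e-12)
  if (length(off)) {
    stop("posterior row at line ", off[1] + 1L, " sums to ",
         signif(rs[off[1]], 8), call. = FALSE)
  }
  o <- order(tab$Site)
  p <- p[o, , drop = FALSE] / rs[o]
  colnames(p) <- BASES
  map <- max.col(p, ties.method = "first")
  structure(list(posterior = p, map = map, map_seq = decode_seq(map),
                 model = NULL),
            class = "asr_reconstruction")
}

#' Export an ancestral reconstruction as a state table
#'
#' Writes the IQ-TREE-style TSV consumed by [import_state_table()].
#'
#' @param reconstruction An `asr_reconstruction`.
#' @param path Output path.
#' @param node Node label to write (default `"Node1"`).
#' @return `path`, invisibly.
#' @export
export_state_table <- function(reconstruction, path, node = "Node1") {
  p <- reconstruction$posterior
  tab <- data.frame(Node = node, Site = seq_len(nrow(p)),
                    State = BASES[reconstruction$map],
                    p_A = p[, 1], p_C = p[, 2], p_G = p[, 3], p_T = p[, 4])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
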