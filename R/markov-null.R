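#' First-order Markov model from dinucleotide equilibrium frequencies
#'
#' The conditional distribution of the next nucleotide given the previous
#' one is the row-normalised dinucleotide simplex:
#' `P(b | a) = F(ab) / sum_b' F(ab')`. The initial dinucleotide is drawn
#' from `F` itself.
#'
#' @param dinuc Named 16-simplex over dinucleotides (e.g.
#'   [solve_stationary()] of a dinucleotide `mut_matrix`).
#' @return A `markov_model`: list with `initial` (16-simplex),
#'   `conditional` (4 x 4 row-stochastic matrix), `order`.
#' @export
markov_from_dinuc <- function(dinuc) {
  stopifnot(length(dinuc) == 16, all(dinuc >= 0))
  dinuc <- dinuc / sum(dinuc)
  names(dinuc) <- names(dinuc) %||% DINUCS
  dinuc <- dinuc[DINUCS]
  fmat <- matrix(dinuc, 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
  marg <- rowSums(fmat)
  if (any(marg == 0)) {
    stop("nucleotide(s) with zero marginal frequency: ",
         paste(BASES[marg == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(initial = dinuc, conditional = fmat / marg, order = 2L),
            class = "markov_model")
}

#' First-order Markov model from mononucleotide equilibrium frequencies
#'
#' Successive nucleotides are independent draws from the mononucleotide
#' simplex (the mono-mode null).
#'
#' @param mono Named 4-simplex over nucleotides.
#' @return A `markov_model`.
#' @export
markov_from_mono <- function(mono) {
  stopifnot(length(mono) == 4, all(mono > 0))
  mono <- mono / sum(mono)
  names(mono) <- names(mono) %||% BASES
  mono <- mono[BASES]
  init <- as.vector(outer(mono, mono))
  names(init) <- as.vector(outer(BASES, BASES, paste0))
  init <- init[DINUCS]
  cond <- matrix(mono, 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
  structure(list(initial = init, conditional = cond, order = 1L),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> order-", x$order, " chain\n", sep = "")
  invisible(x)
}

#' Simulate a set of null sequences from a Markov model
#'
#' The first dinucleotide of each simulant is drawn from the model's
#' initial distribution and the chain is extended one nucleotide at a time
#' from the conditional distribution. Each sequence uses its own random
#' stream derived from the root seed, so enlarging `n` leaves earlier
#' sequences unchanged.
#'
#' @param model A `markov_model`.
#' @param n Number of sequences (default 10000).
#' @param length Sequence length in nucleotides (>= 3); typically the mean
#'   CDS length of the gene set under study.
#' @param seed Integer root seed.
#' @return A `null_seq_set`: list with `codes` (n x length integer
#'   matrix), `model`, `seed`.
#' @export
simulate_sequences <- function(model, n = 10000, length, seed = 1) {
  stopifnot(length >= 3, n >= 1)
  # per-sequence uniform streams, consumed column-wise below
  u <- matrix(0, n, length)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    u[i, ] <- runif(length)
  }
  codes <- matrix(0L, n, length)
  cum_init <- cumsum(model$initial)
  first <- findInterval(u[, 1], cum_init, left.open = TRUE) + 1L
  codes[, 1] <- (first - 1L) %/% 4L + 1L
  codes[, 2] <- (first - 1L) %% 4L + 1L
  for (j in 3:length) {
    codes[, j] <- sample_transition(codes[, j - 1L], model$conditional,
                                    u = u[, j])
  }
  structure(list(codes = codes, model = model, seed = seed),
            class = "null_seq_set")
}

#' @export
print.null_seq_set <- function(x, ...) {
  cat("<null_seq_set> ", nrow(x$codes), " sequences of length ",
      ncol(x$codes), "\n", sep = "")
  invisible(x)
}

#' Sequences of a null set as character strings
#' @param set A `null_seq_set`.
#' @return Character vector.
#' @export
null_sequences <- function(set) {
  apply(set$codes, 1L, decode_seq)
}

#' Aggregate frame-free trinucleotide frequencies of a null sequence set
#'
#' @param set A `null_seq_set`.
#' @return A `trinuc_profile` aggregated over all simulants.
#' @export
null_trinuc_frequencies <- function(set) {
  stopifnot(nrow(set$codes) >= 1)
  trinuc_profile_matrix(set$codes)
}

#' Closed-form trinucleotide probabilities of a first-order chain
#'
#' `p(abc) = F(ab) * P(c | b)`: the exact stationary trinucleotide
#' distribution of the chain, usable in place of simulation.
#'
#' @param model A `markov_model`.
#' @return Named numeric over the 64 trinucleotides, summing to 1.
#' @export
trinuc_expected <- function(model) {
  p <- setNames(numeric(64), TRINUCS)
  for (i in seq_len(64)) {
    a <- (i - 1L) %/% 16L + 1L
    b <- ((i - 1L) %/% 4L) %% 4L + 1L
    cc <- (i - 1L) %% 4L + 1L
    p[i] <- model$initial[(a - 1L) * 4L + b] * model$conditional[b, cc]
  }
  p / sum(p)
}

#' Equilibrium stop-codon shares of a null model or sequence set
#'
#' Relative frequencies of TAA/TGA/TAG among the three stop trinucleotides:
#' `TGA* = F(TGA) / (F(TAA) + F(TGA) + F(TAG))` and likewise for the other
#' two.
#'
#' @param x A `null_seq_set`, a `trinuc_profile`, or a `markov_model`
#'   (closed form).
#' @return Tibble `stop`, `frequency`, `star` (shares summing to 1).
#' @export
tga_star <- function(x) {
  f <- if (inherits(x, "null_seq_set")) {
    null_trinuc_frequencies(x)$frequencies
  } else if (inherits(x, "trinuc_profile")) {
    x$frequencies
  } else if (inherits(x, "markov_model")) {
    trinuc_expected(x)
  } else {
    stop("unsupported input", call. = FALSE)
  }
  s <- f[STOPS]
  tibble(stop = STOPS, frequency = as.numeric(s),
         star = as.numeric(s / sum(s)))
}
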