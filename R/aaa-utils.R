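## Internal sequence utilities. Nucleotides are encoded 1..4 in the fixed
## order A < C < G < T throughout; ambiguity codes become NA.

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TGA", "TAG")

.dinuc_names <- function() {
  as.vector(t(outer(BASES, BASES, paste0)))
}

.trinuc_names <- function() {
  g <- expand.grid(c3 = BASES, c2 = BASES, c1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$c1, g$c2, g$c3)
}

DINUCS  <- .dinuc_names()   # index (a-1)*4  + b
TRINUCS <- .trinuc_names()  # index (a-1)*16 + (b-1)*4 + c

encode_seq <- function(x) {
  stopifnot(length(x) == 1L)
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
}

decode_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- BASES[codes[ok]]
  paste(out, collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

gc_fraction <- function(x) {
  codes <- encode_seq(x)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) return(NA_real_)
  mean(codes == 2L | codes == 3L)
}

## Deterministic child seeds below 2^31 so independent stages of a pipeline
## can share one root seed without sharing a stream.
derive_seed <- function(seed, i) {
  # products stay below 2^53, exact in doubles; reduce before coercing
  as.integer(((as.numeric(seed) %% 2147483629) * 48271 + i) %% 2147483629)
}

## Sample one categorical draw per element of `state` (integer codes) from
## the rows of a k x k probability matrix, vectorised over elements.
sample_transition <- function(state, prob, u = NULL) {
  k <- ncol(prob)
  cum <- t(apply(prob, 1L, cumsum))
  if (is.null(u)) u <- runif(length(state))
  nxt <- rep(1L, length(state))
  for (j in seq_len(k - 1L)) {
    nxt <- nxt + (u > cum[cbind(state, j)])
  }
  nxt
}

## Row-stochastic one-step matrix exp(Q * t) for an off-diagonal rate matrix.
transition_matrix <- function(rates, t = 1) {
  q <- as.matrix(rates)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  as.matrix(Matrix::expm(q * t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
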