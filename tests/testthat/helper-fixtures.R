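# Shared fixtures, all built in code.

write_toy_genome <- function(contig, features, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", contig), fa)
  attr_col <- paste0(
    ifelse(is.na(features$id), "", paste0("ID=", features$id)),
    ifelse(is.na(features$parent), "", paste0(";Parent=", features$parent))
  )
  attr_col <- sub("^;", "", attr_col)
  attr_col[attr_col == ""] <- "."
  gff <- file.path(dir, "toy.gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "toy", features$type, features$start,
                     features$end, ".", features$strand, ".", attr_col,
                     sep = "\t")),
             gff)
  list(fasta = fa, gff = gff)
}

# Two-exon gene annotation over an explicit contig; CDS covers both exons.
toy_two_exon_features <- function(strand = "+") {
  tibble::tibble(
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS"),
    start = c(1L, 1L, 1L, 16L, 1L, 16L),
    end = c(30L, 30L, 9L, 30L, 9L, 30L),
    strand = strand,
    id = c("g1", "t1", "t1.e1", "t1.e2", "t1.c1", "t1.c2"),
    parent = c(NA, "g1", "t1", "t1", "t1", "t1")
  )
}

random_rate_matrix <- function(k, min = 0.01, max = 1) {
  m <- matrix(runif(k * k, min, max), k, k)
  diag(m) <- 0
  if (k == 4) dimnames(m) <- list(stopflux:::BASES, stopflux:::BASES)
  if (k == 16) dimnames(m) <- list(stopflux:::DINUCS, stopflux:::DINUCS)
  m
}

# Long-run power-iteration oracle for stationary distributions.
power_iteration_stationary <- function(rates, tol = 1e-14, max_iter = 1e6) {
  q <- as.matrix(rates)
  diag(q) <- 0
  step <- 0.1 / max(rowSums(q))
  P <- q * step
  diag(P) <- 1 - step * rowSums(q)
  pi <- rep(1 / nrow(q), nrow(q))
  for (i in seq_len(max_iter)) {
    nxt <- as.numeric(pi %*% P)
    if (max(abs(nxt - pi)) < tol) return(nxt)
    pi <- nxt
  }
  pi
}

# Brute-force marginal ASR over the 4 internal states.
enumerate_asr <- function(alignment, model) {
  x <- lapply(alignment, function(s) {
    match(strsplit(toupper(s), "")[[1]], stopflux:::BASES)
  })
  P <- stopflux:::.branch_P(model)
  L <- length(x[[1]])
  post <- matrix(0, L, 4)
  for (l in seq_len(L)) {
    for (a in 1:4) {
      lik <- model$pi[a]
      for (tip in 1:3) {
        if (!is.na(x[[tip]][l])) lik <- lik * P[[tip]][a, x[[tip]][l]]
      }
      post[l, a] <- lik
    }
    post[l, ] <- post[l, ] / sum(post[l, ])
  }
  post
}

random_trio_alignment <- function(L = 100) {
  vapply(1:3, function(i) {
    paste(sample(stopflux:::BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}
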