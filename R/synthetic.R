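#' Default mononucleotide mutation-rate matrix
#'
#' A human-like, GC-to-AT-biased spectrum (transitions elevated, C->T and
#' G->A strongest), expressed as rates per incidence of the ancestral base
#' per unit time. Only rate ratios matter for equilibria.
#'
#' @return 4 x 4 numeric matrix with zero diagonal, dimnames A/C/G/T.
#' @export
default_mutation_rates <- function() {
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  m["A", ] <- c(0, 0.05, 0.15, 0.05)
  m["C", ] <- c(0.08, 0, 0.05, 0.25)
  m["G", ] <- c(0.25, 0.05, 0, 0.08)
  m["T", ] <- c(0.05, 0.15, 0.05, 0)
  m
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator: genome layout, the ground-truth
#' mutation process, trio branch lengths, the AT-to-GC fixation bias `B`
#' (`B = 1` is neutral; GC-increasing changes are favoured by `B` and
#' GC-decreasing ones disfavoured by `1/B`, acting at fixation, not
#' mutation), the recombination/GC coupling, stop-codon preferences and
#' abundance distribution.
#'
#' @param seed Integer root seed.
#' @param n_genes Number of genes.
#' @param isochore_gc Target GC fractions of the isochore blocks, cycled
#'   across blocks.
#' @param genes_per_block Genes placed in each block.
#' @param block_length Optional fixed block length (bp); genes that do not
#'   fit raise an error. `NULL` sizes blocks to their contents.
#' @param mean_cds_length Mean CDS length (bp, multiple of 3 enforced).
#' @param utr5_length,utr3_length,intron_length,gap_length Fixed lengths of
#'   the non-CDS parts (bp).
#' @param mutation_rates 4 x 4 ground-truth mutation-rate matrix.
#' @param branch_lengths Three branch lengths (ingroup1, ingroup2,
#'   outgroup) in expected substitutions/site.
#' @param B Fixation bias for AT-to-GC changes (> 0).
#' @param stop_switch_rate Per-lineage probability scale of stop-codon
#'   switches in trio evolution.
#' @param stop_switch Optional explicit 3 x 3 matrix of per-lineage
#'   stop-switch probabilities (rows/columns TAA, TGA, TAG; off-diagonal
#'   entries used, diagonal recomputed), overriding the probabilities
#'   derived from `stop_switch_rate` and `B`.
#' @param stop_freq Planted focal-stop distribution (TAA, TGA, TAG).
#' @param stop_preference Optional list with elements `LEG` and `HEG`
#'   (each a 3-simplex over stops) planting an expression-linked stop
#'   preference in the bottom/top abundance quartiles.
#' @param recomb_coupling Correlation knob in `[0, 1]` between window GC
#'   and recombination rate.
#' @param abundance_meanlog,abundance_sdlog Log-normal protein-abundance
#'   parameters (ppm).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 200,
                       isochore_gc = c(0.35, 0.45, 0.55, 0.65),
                       genes_per_block = 25, block_length = NULL,
                       mean_cds_length = 900, utr5_length = 120,
                       utr3_length = 240, intron_length = 400,
                       gap_length = 300,
                       mutation_rates = default_mutation_rates(),
                       branch_lengths = c(0.05, 0.05, 0.10),
                       B = 1, stop_switch_rate = 0.02, stop_switch = NULL,
                       stop_freq = c(TAA = 0.5, TGA = 0.3, TAG = 0.2),
                       stop_preference = NULL,
                       recomb_coupling = 0.5,
                       abundance_meanlog = 3, abundance_sdlog = 1.5) {
  stopifnot(B > 0, all(isochore_gc > 0 & isochore_gc < 1),
            mean_cds_length >= 150, all(branch_lengths >= 0),
            recomb_coupling >= 0, recomb_coupling <= 1)
  structure(
    list(seed = seed, n_genes = n_genes, isochore_gc = isochore_gc,
         genes_per_block = genes_per_block, block_length = block_length,
         mean_cds_length = mean_cds_length, utr5_length = utr5_length,
         utr3_length = utr3_length, intron_length = intron_length,
         gap_length = gap_length, mutation_rates = mutation_rates,
         branch_lengths = branch_lengths, B = B,
         stop_switch_rate = stop_switch_rate, stop_switch = stop_switch,
         stop_freq = stop_freq,
         stop_preference = stop_preference,
         recomb_coupling = recomb_coupling,
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog),
    class = "sim_config")
}

## i.i.d. nucleotide string at a target GC fraction
.random_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

SENSE_CODONS <- setdiff(TRINUCS, STOPS)

## Random CDS: ATG + sense codons at target GC + a planted stop
.random_cds <- function(len, gc, stop) {
  stopifnot(len %% 3 == 0, len >= 9)
  p_base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codon_p <- vapply(SENSE_CODONS, function(cd) {
    prod(p_base[match(strsplit(cd, "")[[1]], BASES)])
  }, numeric(1))
  codon_p <- codon_p / sum(codon_p)
  n_sense <- len / 3 - 2L
  body <- sample(SENSE_CODONS, n_sense, replace = TRUE, prob = codon_p)
  paste0("ATG", paste(body, collapse = ""), stop)
}

#' Generate an isochore-structured reference genome with genes
#'
#' Builds one contig of consecutive isochore blocks (i.i.d. bases at each
#' block's target GC), placing genes with 5'UTR, two CDS exons separated by
#' an intron, and 3'UTR; strands alternate. Focal stops are planted from
#' `stop_freq`, or from `stop_preference` tiers when protein abundances say
#' so. The construction guarantees every gene passes QC.
#'
#' @param config A [sim_config()].
#' @return A list: `bundle` (a `genome_bundle`), `genes` (truth tibble with
#'   per-gene block GC, planted stop, CDS, abundance, tier), `config`.
#' @export
make_reference <- function(config) {
  set.seed(derive_seed(config$seed, 101L))
  n <- config$n_genes

  abundance <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  tier <- rep("mid", n)
  qs <- quantile(abundance, c(0.25, 0.75))
  tier[abundance <= qs[1]] <- "LEG"
  tier[abundance >= qs[2]] <- "HEG"
  stops <- character(n)
  for (i in seq_len(n)) {
    pf <- config$stop_freq
    if (!is.null(config$stop_preference)) {
      if (tier[i] == "LEG" && !is.null(config$stop_preference$LEG)) {
        pf <- config$stop_preference$LEG
      } else if (tier[i] == "HEG" && !is.null(config$stop_preference$HEG)) {
        pf <- config$stop_preference$HEG
      }
    }
    stops[i] <- sample(STOPS, 1, prob = pf[STOPS])
  }

  n_blocks <- ceiling(n / config$genes_per_block)
  block_gc <- config$isochore_gc[(seq_len(n_blocks) - 1L) %%
                                   length(config$isochore_gc) + 1L]
  gene_block <- rep(seq_len(n_blocks), each = config$genes_per_block)[seq_len(n)]

  pieces <- character(0)
  feats <- list()
  genes_truth <- list()
  pos <- 0L
  for (b in seq_len(n_blocks)) {
    gc <- block_gc[b]
    idx <- which(gene_block == b)
    block_start <- pos + 1L
    for (i in idx) {
      strand <- if (i %% 2L == 1L) "+" else "-"
      cds_len <- 3L * max(50L, round(rnorm(1, config$mean_cds_length / 3,
                                           config$mean_cds_length / 12)))
      cds <- .random_cds(cds_len, gc, stops[i])
      utr5 <- .random_seq(config$utr5_length, gc)
      utr3 <- .random_seq(config$utr3_length, gc)
      intron <- .random_seq(config$intron_length, gc)
      gap <- .random_seq(config$gap_length, gc)
      l1 <- 3L * (cds_len %/% 6L)             # CDS split point, codon boundary
      cds1 <- substring(cds, 1L, l1)
      cds2 <- substring(cds, l1 + 1L)

      layout <- paste0(utr5, cds1, intron, cds2, utr3)
      Lg <- nchar(layout)
      genomic <- if (strand == "+") layout else revcomp(layout)
      footprint <- config$gap_length + Lg
      if (!is.null(config$block_length) && footprint > config$block_length) {
        stop("gene ", i, " (", footprint, " bp) longer than block (",
             config$block_length, " bp)", call. = FALSE)
      }
      pieces <- c(pieces, gap, genomic)
      locus_start <- pos + config$gap_length + 1L

      u5 <- config$utr5_length
      # spans in mRNA-layout offsets (1-based)
      spans <- list(
        five_prime_UTR = c(1L, u5),
        cds_a = c(u5 + 1L, u5 + l1),
        intron = c(u5 + l1 + 1L, u5 + l1 + config$intron_length),
        cds_b = c(u5 + l1 + config$intron_length + 1L,
                  u5 + config$intron_length + cds_len),
        three_prime_UTR = c(u5 + config$intron_length + cds_len + 1L, Lg)
      )
      spans$exon_a <- c(spans$five_prime_UTR[1], spans$cds_a[2])
      spans$exon_b <- c(spans$cds_b[1], spans$three_prime_UTR[2])
      to_contig <- function(sp) {
        if (strand == "+") locus_start + sp - 1L
        else c(locus_start + Lg - sp[2], locus_start + Lg - sp[1])
      }
      gid <- sprintf("gene%05d", i)
      tid <- sprintf("tx%05d", i)
      add <- function(type, sp, id = NA_character_, parent = NA_character_) {
        cc <- to_contig(sp)
        tibble(contig = "chr1", type = type, start = cc[1], end = cc[2],
               strand = strand, id = id, parent = parent,
               canonical = if (type %in% c("mRNA")) "1" else NA_character_)
      }
      gene_span <- to_contig(c(1L, Lg))
      feats[[length(feats) + 1L]] <- dplyr::bind_rows(
        tibble(contig = "chr1", type = "gene", start = gene_span[1],
               end = gene_span[2], strand = strand, id = gid,
               parent = NA_character_, canonical = NA_character_),
        add("mRNA", c(1L, Lg), id = tid, parent = gid),
        add("exon", spans$exon_a, id = paste0(tid, ".e1"), parent = tid),
        add("exon", spans$exon_b, id = paste0(tid, ".e2"), parent = tid),
        add("CDS", spans$cds_a, id = paste0(tid, ".c1"), parent = tid),
        add("CDS", spans$cds_b, id = paste0(tid, ".c2"), parent = tid),
        add("five_prime_UTR", spans$five_prime_UTR, id = paste0(tid, ".u5"),
            parent = tid),
        add("three_prime_UTR", spans$three_prime_UTR, id = paste0(tid, ".u3"),
            parent = tid)
      )
      genes_truth[[length(genes_truth) + 1L]] <- tibble(
        gene_id = gid, transcript_id = tid, block = b, block_gc = gc,
        strand = strand, stop = stops[i], cds = cds, abundance = abundance[i],
        tier = tier[i]
      )
      pos <- pos + config$gap_length + Lg
    }
    if (!is.null(config$block_length)) {
      used <- pos - block_start + 1L
      if (used < config$block_length) {
        fill <- .random_seq(config$block_length - used, gc)
        pieces <- c(pieces, fill)
        pos <- pos + nchar(fill)
      }
    }
  }
  tailgap <- .random_seq(config$gap_length, block_gc[n_blocks])
  contig <- paste(c(pieces, tailgap), collapse = "")

  bundle <- structure(
    list(contigs = c(chr1 = contig),
         features = dplyr::bind_rows(feats)),
    class = "genome_bundle")
  list(bundle = bundle, genes = dplyr::bind_rows(genes_truth), config = config)
}

## Fixation-biased effective rates: every proposal is accepted with a base
## probability of 0.5, scaled by B for AT->GC changes and by 1/B for
## GC->AT changes (capped at 1), so B = 1 is neutral and the up/down
## fixation ratio is B^2 for B <= 2.
.effective_rates <- function(rates, B) {
  acc <- matrix(0.5, 4, 4, dimnames = dimnames(rates))
  up <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  down <- rbind(c("G", "A"), c("G", "T"), c("C", "A"), c("C", "T"))
  acc[up] <- pmin(1, 0.5 * B)
  acc[down] <- pmin(1, 0.5 / B)
  rates * acc
}

## Scale a rate matrix so one unit of time is ~one expected substitution
## per site under uniform composition.
.scaled_Q <- function(rates) {
  q <- rates
  diag(q) <- 0
  mean_rate <- mean(rowSums(q))
  q / mean_rate
}

#' Evolve a nucleotide sequence under the mutation process
#'
#' Applies the (optionally fixation-biased) substitution process for a
#' branch of length `t` expected substitutions per site, sampling each
#' site's final state from the exact finite-time transition matrix.
#'
#' @param seq Nucleotide string.
#' @param rates 4 x 4 mutation-rate matrix.
#' @param t Branch length (expected substitutions/site at B = 1).
#' @param B AT-to-GC fixation bias (default 1, neutral).
#' @param seed Optional integer seed.
#' @return The evolved string.
#' @export
evolve_sequence <- function(seq, rates, t, B = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- encode_seq(seq)
  P <- transition_matrix(.scaled_Q(.effective_rates(rates, B)), t)
  ok <- !is.na(codes)
  codes[ok] <- sample_transition(codes[ok], P)
  decode_seq(codes)
}

## Stop-codon switch probabilities per lineage, with the fixation bias
## applied to GC-increasing switches.
.stop_switch_probs <- function(r, B) {
  p <- matrix(0, 3, 3, dimnames = list(STOPS, STOPS))
  p["TAA", "TGA"] <- min(0.45, r * B)
  p["TAA", "TAG"] <- min(0.45, r * B)
  p["TGA", "TAA"] <- min(0.45, r / B)
  p["TAG", "TAA"] <- min(0.45, r / B)
  p["TGA", "TAG"] <- min(0.05, r^2)
  p["TAG", "TGA"] <- min(0.05, r^2)
  diag(p) <- 1 - rowSums(p)
  p
}

#' Evolve trio alignments from ancestral coding sequences
#'
#' Each gene's ancestral CDS (internal-node state) evolves independently
#' along the three branches: background sites under the finite-time
#' transition matrix of the (bias-folded) mutation process, the focal stop
#' codon as a unit under per-lineage switch probabilities derived from
#' `stop_switch_rate` and `B`. Alignments are ungapped (identity
#' alignment), isolating flux inference from aligner error. Realized stop
#' switches are logged per lineage as truth.
#'
#' @param genes Truth tibble from [make_reference()] (needs `gene_id`,
#'   `cds`, `stop`), or any tibble with those columns.
#' @param config A [sim_config()]; `B` may also be a per-gene vector via
#'   the `B` argument.
#' @param B Optional per-gene fixation-bias vector overriding `config$B`.
#' @return Tibble: `gene_id`, `ancestral_stop`, `ingroup1`, `ingroup2`,
#'   `outgroup` (aligned, equal length), `stop_col1` (first of the 3 stop
#'   columns), `tip1_stop`, `tip2_stop`, `outgroup_stop`.
#' @export
evolve_trios <- function(genes, config, B = NULL) {
  n <- nrow(genes)
  Bvec <- if (is.null(B)) rep(config$B, n) else rep_len(B, n)
  t3 <- config$branch_lengths
  P_cache <- list()
  get_P <- function(b, t) {
    key <- paste0(signif(b, 10), "_", signif(t, 10))
    if (is.null(P_cache[[key]])) {
      P_cache[[key]] <<- transition_matrix(
        .scaled_Q(.effective_rates(config$mutation_rates, b)), t)
    }
    P_cache[[key]]
  }
  tips_mat <- matrix(NA_character_, n, 3)
  stops_mat <- matrix(NA_character_, n, 3)
  anc_stops <- character(n)
  stop_col1 <- integer(n)
  S_cache <- list()
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, 2000L + i))
    cds <- genes$cds[i]
    L <- nchar(cds)
    anc_codes <- encode_seq(cds)
    body_idx <- seq_len(L - 3L)
    anc_stop <- substring(cds, L - 2L, L)
    skey <- as.character(Bvec[i])
    if (is.null(S_cache[[skey]])) {
      S_cache[[skey]] <- if (!is.null(config$stop_switch)) {
        S <- config$stop_switch
        diag(S) <- 0
        diag(S) <- 1 - rowSums(S)
        S
      } else {
        .stop_switch_probs(config$stop_switch_rate, Bvec[i])
      }
    }
    S <- S_cache[[skey]]
    for (br in 1:3) {
      codes <- anc_codes
      if (t3[br] > 0) {
        P <- get_P(Bvec[i], t3[br])
        codes[body_idx] <- sample_transition(anc_codes[body_idx], P)
        new_stop <- sample(STOPS, 1, prob = S[anc_stop, ])
      } else {
        new_stop <- anc_stop
      }
      stops_mat[i, br] <- new_stop
      codes[(L - 2L):L] <- match(strsplit(new_stop, "")[[1]], BASES)
      tips_mat[i, br] <- decode_seq(codes)
    }
    anc_stops[i] <- anc_stop
    stop_col1[i] <- L - 2L
  }
  tibble(
    gene_id = genes$gene_id, ancestral_stop = anc_stops,
    ingroup1 = tips_mat[, 1], ingroup2 = tips_mat[, 2],
    outgroup = tips_mat[, 3], stop_col1 = stop_col1,
    tip1_stop = stops_mat[, 1], tip2_stop = stops_mat[, 2],
    outgroup_stop = stops_mat[, 3]
  )
}

#' Sample a de novo mutation table from a known matrix
#'
#' Sites are drawn proportionally to the total mutation rate of their
#' reference base; the alternate allele is drawn proportionally to the
#' base's matrix row. Positions may repeat (independent events).
#'
#' @param reference A `genome_bundle` or named character vector of contigs.
#' @param rates 4 x 4 ground-truth mutation-rate matrix.
#' @param n Number of mutations.
#' @param seed Integer seed.
#' @return Tibble `contig`, `pos`, `ref`, `alt`.
#' @export
sample_denovo <- function(reference, rates, n, seed = 1) {
  contigs <- if (inherits(reference, "genome_bundle")) reference$contigs else reference
  set.seed(derive_seed(seed, 301L))
  lens <- nchar(contigs)
  codes <- unlist(lapply(contigs, encode_seq), use.names = FALSE)
  valid <- which(!is.na(codes))
  w <- rowSums(rates)[codes[valid]]
  pick <- valid[sample.int(length(valid), n, replace = TRUE, prob = w)]
  ref_code <- codes[pick]
  alt_code <- integer(n)
  for (b in 1:4) {
    sel <- ref_code == b
    if (!any(sel)) next
    alt_code[sel] <- sample.int(4, sum(sel), replace = TRUE, prob = rates[b, ])
  }
  offsets <- cumsum(c(0, lens))[seq_along(contigs)]
  ctg_idx <- findInterval(pick, offsets + 1L)
  tibble(contig = names(contigs)[ctg_idx],
         pos = pick - offsets[ctg_idx],
         ref = BASES[ref_code], alt = BASES[alt_code]) |>
    dplyr::arrange(.data$contig, .data$pos)
}

#' Generate a GC-coupled recombination map
#'
#' Per-10 kb window rates are log-normal; the latent log-rate mixes the
#' standardised window GC with independent noise so that the correlation of
#' log-rate and GC approximately equals `coupling`.
#'
#' @param reference A `genome_bundle` or named character vector.
#' @param coupling Coupling knob in `[0, 1]`.
#' @param seed Integer seed.
#' @param window Window width (default 10000 bp).
#' @param meanlog,sdlog Log-normal parameters of the marginal rate (cM/Mb).
#' @return Tibble `contig`, `start`, `end` (0-based half-open), `rate`.
#' @export
make_recomb_map <- function(reference, coupling, seed = 1, window = 10000,
                            meanlog = 0.3, sdlog = 0.7) {
  contigs <- if (inherits(reference, "genome_bundle")) reference$contigs else reference
  set.seed(derive_seed(seed, 401L))
  out <- list()
  for (ctg in names(contigs)) {
    L <- nchar(contigs[[ctg]])
    starts <- seq(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    gc <- vapply(seq_along(starts), function(i) {
      gc_fraction(substring(contigs[[ctg]], starts[i] + 1L, ends[i]))
    }, numeric(1))
    z <- if (length(gc) > 1 && sd(gc) > 0) (gc - mean(gc)) / sd(gc) else rep(0, length(gc))
    latent <- coupling * z + sqrt(1 - coupling^2) * rnorm(length(gc))
    out[[ctg]] <- tibble(contig = ctg, start = starts, end = ends,
                         rate = exp(meanlog + sdlog * latent))
  }
  dplyr::bind_rows(out)
}

#' Generate a complete synthetic input bundle
#'
#' Runs the whole generator: reference + annotation, trio alignments,
#' de novo mutation table, recombination map and abundances, with a truth
#' list sufficient to recompute every expected estimate.
#'
#' @param config A [sim_config()].
#' @param n_mutations Number of de novo mutations to sample.
#' @return A `sim_bundle` list: `bundle`, `genes` (truth tibble), `trios`,
#'   `mutations`, `recomb_map`, `config`.
#' @export
sim_bundle <- function(config, n_mutations = 20000) {
  ref <- make_reference(config)
  trios <- evolve_trios(ref$genes, config)
  muts <- sample_denovo(ref$bundle, config$mutation_rates, n_mutations,
                        seed = config$seed)
  rmap <- make_recomb_map(ref$bundle, config$recomb_coupling,
                          seed = config$seed)
  structure(list(bundle = ref$bundle, genes = ref$genes, trios = trios,
                 mutations = muts, recomb_map = rmap, config = config),
            class = "sim_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits reference FASTA, GFF3 annotation, per-gene aligned trio FASTA
#' files, mutation/recombination/abundance TSVs and a truth JSON with the
#' generating parameters and per-gene event log.
#'
#' @param sim A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @param write_trios Write per-gene trio alignments (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(sim, dir, write_trios = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(sim$bundle$contigs)
  Biostrings::writeXStringSet(seqs, file.path(dir, "reference.fa"), width = 80)

  f <- sim$bundle$features
  attr_col <- paste0(
    ifelse(is.na(f$id), "", paste0("ID=", f$id)),
    ifelse(is.na(f$parent), "", paste0(";Parent=", f$parent)),
    ifelse(is.na(f$canonical), "", ";canonical=1")
  )
  attr_col <- sub("^;", "", attr_col)
  attr_col[attr_col == ""] <- "."
  gff <- paste(f$contig, "stopflux", f$type, f$start, f$end, ".", f$strand,
               ".", attr_col, sep = "\t")
  writeLines(c("##gff-version 3", gff), file.path(dir, "annotation.gff3"))

  if (write_trios && !is.null(sim$trios)) {
    tdir <- file.path(dir, "trios")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_len(nrow(sim$trios))) {
      aln <- Biostrings::DNAStringSet(c(
        ingroup1 = sim$trios$ingroup1[i],
        ingroup2 = sim$trios$ingroup2[i],
        outgroup = sim$trios$outgroup[i]))
      Biostrings::writeXStringSet(
        aln, file.path(tdir, paste0(sim$trios$gene_id[i], ".fa")), width = 80)
    }
  }

  utils::write.table(sim$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$recomb_map, file.path(dir, "recomb.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes[, c("gene_id", "abundance")],
                     file.path(dir, "abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    config = sim$config[setdiff(names(sim$config), "mutation_rates")],
    mutation_rates = as.data.frame(sim$config$mutation_rates),
    genes = sim$genes[, setdiff(names(sim$genes), "cds")],
    events = if (!is.null(sim$trios)) {
      sim$trios[, c("gene_id", "ancestral_stop", "tip1_stop", "tip2_stop")]
    }
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
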