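#' Load a genome and its annotation
#'
#' Reads a (possibly wrapped) multi-record FASTA and a GFF3 annotation into
#' an in-memory bundle. Contig names are truncated at the first whitespace.
#' Coordinates stay 1-based inclusive as in GFF3; extraction converts to
#' 0-based half-open internally.
#'
#' @param fasta_path Path to a FASTA file.
#' @param gff_path Path to a GFF3 file.
#' @return A `genome_bundle`: list with `contigs` (named character vector of
#'   nucleotide strings) and `features` (tibble with columns `contig`,
#'   `type`, `start`, `end`, `strand`, `id`, `parent`, `canonical`).
#' @export
load_genome <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  contigs <- setNames(toupper(as.character(seqs)), names(seqs))

  gr <- rtracklayer::import.gff3(gff_path)
  md <- S4Vectors::mcols(gr)
  parent <- md$Parent
  parent <- if (is.null(parent)) NA_character_ else {
    vapply(as.list(parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  }
  canonical <- md$canonical
  features <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(md$ID %||% NA_character_),
    parent = parent,
    canonical = if (is.null(canonical)) NA_character_ else as.character(canonical)
  )

  missing_contig <- setdiff(unique(features$contig), names(contigs))
  if (length(missing_contig)) {
    bad <- features$id[features$contig %in% missing_contig][1]
    stop("feature '", bad, "' refers to contig '", missing_contig[1],
         "' absent from the FASTA", call. = FALSE)
  }
  too_long <- features$end > nchar(contigs)[features$contig]
  if (any(too_long)) {
    stop("feature '", features$id[which(too_long)[1]],
         "' extends beyond its contig", call. = FALSE)
  }

  structure(list(contigs = contigs, features = features),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("<genome_bundle> ", length(x$contigs), " contig(s), ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

## Extract one span, strand-aware. start/end 1-based inclusive.
.extract_span <- function(contigs, contig, start, end, strand) {
  s <- substring(contigs[contig], start, end)
  ifelse(strand == "-", revcomp(s), s)
}

## Splice spans of one transcript into mRNA order.
.splice <- function(contigs, contig, starts, ends, strand) {
  o <- order(starts)
  pieces <- substring(contigs[contig], starts[o], ends[o])
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Extract per-gene sequence classes from a genome bundle
#'
#' Builds one record per gene using a single transcript: the one flagged
#' canonical in the annotation if present, otherwise the transcript with the
#' longest total CDS, ties broken lexicographically by transcript id. CDS is
#' spliced with the stop codon included; introns are the gaps between
#' consecutive exons.
#'
#' @param bundle A `genome_bundle` from [load_genome()].
#' @return A tibble with one row per gene: `gene_id`, `transcript_id`,
#'   `contig`, `start`, `end`, `strand`, `cds`, `utr5`, `utr3`, `introns`
#'   (list column), `stop`, `gc3`, `intronic_gc`.
#' @export
gene_records <- function(bundle) {
  stopifnot(inherits(bundle, "genome_bundle"))
  feats <- bundle$features
  tx <- dplyr::filter(feats, .data$type %in% c("mRNA", "transcript"))
  cds <- dplyr::filter(feats, .data$type == "CDS")
  exon <- dplyr::filter(feats, .data$type == "exon")
  utr5f <- dplyr::filter(feats, .data$type == "five_prime_UTR")
  utr3f <- dplyr::filter(feats, .data$type == "three_prime_UTR")

  cds_len <- cds |>
    dplyr::group_by(.data$parent) |>
    dplyr::summarise(cds_len = sum(.data$end - .data$start + 1L))
  tx <- dplyr::left_join(tx, cds_len, by = c(id = "parent"))
  tx <- tx[!is.na(tx$cds_len), , drop = FALSE]

  pick <- tx |>
    dplyr::group_by(.data$parent) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$canonical) & .data$canonical == "1"),
                   dplyr::desc(.data$cds_len), .data$id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  records <- purrr::pmap(
    list(pick$parent, pick$id, pick$contig, pick$start, pick$end, pick$strand),
    function(gene_id, tx_id, contig, tstart, tend, strand) {
      cx <- cds[cds$parent == tx_id, , drop = FALSE]
      ex <- exon[exon$parent == tx_id, , drop = FALSE]
      u5 <- utr5f[utr5f$parent == tx_id, , drop = FALSE]
      u3 <- utr3f[utr3f$parent == tx_id, , drop = FALSE]
      cds_seq <- .splice(bundle$contigs, contig, cx$start, cx$end, strand)
      utr5 <- if (nrow(u5)) .splice(bundle$contigs, contig, u5$start, u5$end, strand) else ""
      utr3 <- if (nrow(u3)) .splice(bundle$contigs, contig, u3$start, u3$end, strand) else ""
      introns <- character(0)
      spans <- if (nrow(ex)) ex else cx
      if (nrow(spans) > 1L) {
        o <- order(spans$start)
        istart <- spans$end[o][-nrow(spans)] + 1L
        iend <- spans$start[o][-1L] - 1L
        keep <- iend >= istart
        introns <- unname(substring(bundle$contigs[contig], istart[keep], iend[keep]))
        if (strand == "-") introns <- rev(revcomp(introns))
      }
      tibble(gene_id = gene_id, transcript_id = tx_id, contig = contig,
             start = tstart, end = tend, strand = strand,
             cds = cds_seq, utr5 = utr5, utr3 = utr3,
             introns = list(introns))
    }
  ) |> dplyr::bind_rows()

  records$stop <- toupper(substring(records$cds, nchar(records$cds) - 2L))
  records$gc3 <- gc3(records$cds)
  records$intronic_gc <- intronic_gc(records$introns)
  records
}

#' Quality-control filter for gene records
#'
#' Retains genes whose CDS length is divisible by 3, that contain no
#' premature (in-frame internal) stop codon, and that terminate in TAA, TGA
#' or TAG. Rejection reasons and counts are attached as the `"rejections"`
#' attribute and reported via `message()`.
#'
#' @param records Tibble of gene records ([gene_records()] shape; only `cds`
#'   is required).
#' @return The surviving rows, with a `rejections` attribute (tibble of
#'   `reason`, `n`).
#' @export
qc_filter <- function(records) {
  cds <- toupper(records$cds)
  len_ok <- nchar(cds) %% 3L == 0L & nchar(cds) >= 6L
  stop_ok <- substring(cds, nchar(cds) - 2L) %in% STOPS
  internal_ok <- !vapply(cds, .has_internal_stop, logical(1), USE.NAMES = FALSE)
  # genes failing the length test cannot be frame-checked meaningfully
  keep <- len_ok & stop_ok & internal_ok
  rej <- tibble(
    reason = c("length_not_multiple_of_3", "premature_stop", "invalid_stop"),
    n = c(sum(!len_ok), sum(len_ok & !internal_ok), sum(len_ok & internal_ok & !stop_ok))
  )
  if (sum(!keep) > 0) {
    message(sum(!keep), " gene(s) rejected by QC (",
            paste(rej$reason, rej$n, sep = "=", collapse = ", "), ")")
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "rejections") <- rej
  out
}

.has_internal_stop <- function(cds) {
  n <- nchar(cds)
  if (n < 6L || n %% 3L != 0L) return(FALSE)
  codons <- substring(cds, seq(1L, n - 5L, by = 3L), seq(3L, n - 3L, by = 3L))
  any(codons %in% STOPS)
}

#' GC content at third codon positions
#'
#' GC3 is the fraction of third codon positions holding G or C, computed
#' over all codons except the stop codon (the stop is the response variable
#' in downstream analyses, so it is kept out of the covariate).
#'
#' @param cds Character vector of spliced CDS strings (stop included),
#'   lengths divisible by 3.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
gc3 <- function(cds) {
  vapply(cds, function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
    if (n < 6L) return(NA_real_)
    thirds <- encode_seq(s)[seq(3L, n - 3L, by = 3L)]
    thirds <- thirds[!is.na(thirds)]
    if (!length(thirds)) return(NA_real_)
    mean(thirds == 2L | thirds == 3L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content of concatenated introns
#'
#' @param introns A list of character vectors (one vector of intron
#'   sequences per gene). Intronless genes get `NA` and are excluded from
#'   intronic-GC analyses.
#' @return Numeric vector of fractions, `NA` where no intron sequence.
#' @export
intronic_gc <- function(introns) {
  vapply(introns, function(v) {
    if (!length(v)) return(NA_real_)
    gc_fraction(paste(v, collapse = ""))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Trinucleotide profile of a set of sequences
#'
#' Counts the 64 trinucleotides either over every overlapping window of
#' width 3 (`frame_free = TRUE`, step 1) or over in-frame codons only.
#' Windows containing `N` (or any non-ACGT symbol, which is treated as `N`)
#' are skipped.
#'
#' @param sequences Character vector of nucleotide strings.
#' @param frame_free Count overlapping windows (default) or in-frame codons.
#' @return A `trinuc_profile`: list with `counts` (named integer, length
#'   64), `frequencies` (named numeric summing to 1, or NA if empty),
#'   `total`, `frame_free`, `empty`.
#' @export
trinuc_profile <- function(sequences, frame_free = TRUE) {
  counts <- integer(64)
  for (s in sequences) {
    v <- encode_seq(s)
    L <- length(v)
    if (L < 3L) next
    if (frame_free) {
      a <- v[1:(L - 2L)]; b <- v[2:(L - 1L)]; cc <- v[3:L]
    } else {
      st <- seq(1L, L - 2L, by = 3L)
      a <- v[st]; b <- v[st + 1L]; cc <- v[st + 2L]
    }
    idx <- (a - 1L) * 16L + (b - 1L) * 4L + cc
    idx <- idx[!is.na(idx)]
    counts <- counts + tabulate(idx, nbins = 64L)
  }
  names(counts) <- TRINUCS
  total <- sum(counts)
  freqs <- if (total > 0) counts / total else setNames(rep(NA_real_, 64), TRINUCS)
  structure(list(counts = counts, frequencies = freqs, total = total,
                 frame_free = frame_free, empty = total == 0),
            class = "trinuc_profile")
}

#' Count trinucleotides from an integer-coded sequence matrix
#'
#' Fast path used for simulated sequence sets: rows are sequences, entries
#' are nucleotide codes 1..4.
#' @param m Integer matrix of nucleotide codes.
#' @return A `trinuc_profile` (frame-free).
#' @keywords internal
trinuc_profile_matrix <- function(m) {
  L <- ncol(m)
  idx <- (m[, 1:(L - 2L), drop = FALSE] - 1L) * 16L +
    (m[, 2:(L - 1L), drop = FALSE] - 1L) * 4L +
    m[, 3:L, drop = FALSE]
  counts <- tabulate(idx[!is.na(idx)], nbins = 64L)
  names(counts) <- TRINUCS
  total <- sum(counts)
  structure(list(counts = counts, frequencies = counts / total, total = total,
                 frame_free = TRUE, empty = total == 0),
            class = "trinuc_profile")
}

#' @export
print.trinuc_profile <- function(x, ...) {
  cat("<trinuc_profile> ", x$total, " windows (",
      if (x$frame_free) "frame-free" else "in-frame", ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.trinuc_profile <- function(x, ...) {
  tibble(trinuc = TRINUCS, count = unname(x$counts),
         frequency = unname(x$frequencies))
}

#' Relative usage of the three stop codons
#'
#' @param x A gene-record tibble (with a `stop` column), a
#'   `trinuc_profile`, or a named numeric vector of counts containing TAA,
#'   TGA and TAG.
#' @return Tibble with columns `stop`, `count`, `usage`; usages sum to 1.
#' @export
stop_usage <- function(x) {
  counts <- if (inherits(x, "trinuc_profile")) {
    x$counts[STOPS]
  } else if (is.data.frame(x)) {
    c(TAA = sum(x$stop == "TAA"), TGA = sum(x$stop == "TGA"),
      TAG = sum(x$stop == "TAG"))
  } else {
    x[STOPS]
  }
  counts[is.na(counts)] <- 0
  total <- sum(counts)
  if (total == 0) stop("no stop codons present", call. = FALSE)
  tibble(stop = STOPS, count = as.numeric(counts), usage = as.numeric(counts) / total)
}

#' Partition records into equal-size bins by a key
#'
#' Records are ordered by `key` (ties broken by `gene_id` when present for
#' determinism) and split into `bins` groups whose sizes differ by at most
#' one; bin 1 holds the lowest values.
#'
#' @param records A data frame.
#' @param key Column name (string) to order by.
#' @param bins Number of bins (default 10, i.e. deciles).
#' @return `records` with an integer `.bin` column added.
#' @export
decile_bins <- function(records, key, bins = 10) {
  n <- nrow(records)
  if (n < bins) stop("fewer records (", n, ") than bins (", bins, ")", call. = FALSE)
  tie <- if ("gene_id" %in% names(records)) records$gene_id else seq_len(n)
  o <- order(records[[key]], tie)
  sizes <- rep(n %/% bins, bins)
  extra <- n %% bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[o] <- rep(seq_len(bins), times = sizes)
  records$.bin <- bin
  records
}

#' Split records into two halves balancing flux events
#'
#' Orders records by `key` and cuts the ordered list at the point that
#' balances the total number of flux events between the two halves as
#' closely as possible (exactly, up to one event, when events are spread
#' across genes).
#'
#' @param records A data frame.
#' @param key Column name to order by (e.g. intronic GC).
#' @param events Name of a numeric column of per-gene flux-event counts.
#' @return `records` with a `.half` column (`"low"`/`"high"`); the achieved
#'   absolute event difference is attached as attribute `"event_diff"`.
#' @export
half_split <- function(records, key, events) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  tie <- if ("gene_id" %in% names(records)) records$gene_id else seq_len(n)
  o <- order(records[[key]], tie)
  ev <- records[[events]][o]
  total <- sum(ev)
  cum <- cumsum(ev)[-n]
  diff <- abs(total - 2 * cum)
  k <- which.min(diff)
  half <- character(n)
  half[o] <- rep(c("low", "high"), c(k, n - k))
  records$.half <- half
  attr(records, "event_diff") <- diff[k]
  records
}

#' GC content of fixed-width genome windows
#'
#' Tiles each contig with non-overlapping windows and reports their GC
#' fraction — the banded local-GC used to stratify mutations when per-site
#' centred windows are not needed.
#'
#' @param reference A `genome_bundle` or named character vector of contigs.
#' @param window Window width in bp (default 10000).
#' @return Tibble `contig`, `start`, `end` (0-based half-open), `gc`.
#' @export
window_gc <- function(reference, window = 10000) {
  contigs <- if (inherits(reference, "genome_bundle")) reference$contigs else reference
  out <- list()
  for (ctg in names(contigs)) {
    L <- nchar(contigs[[ctg]])
    starts <- seq(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    gc <- vapply(seq_along(starts), function(i) {
      gc_fraction(substring(contigs[[ctg]], starts[i] + 1L, ends[i]))
    }, numeric(1))
    out[[ctg]] <- tibble(contig = ctg, start = starts, end = ends, gc = gc)
  }
  dplyr::bind_rows(out)
}

#' Read a recombination map
#'
#' TSV with columns contig, start, end, rate (cM/Mb); intervals are taken
#' as 0-based half-open. A header line is tolerated.
#'
#' @param path Path to the TSV.
#' @return Tibble `contig`, `start`, `end`, `rate`, sorted and checked for
#'   overlap within contigs.
#' @export
read_recomb_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\S+\t[0-9]+\t[0-9]+\t", first)
  map <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  names(map) <- c("contig", "start", "end", "rate")[seq_len(ncol(map))]
  map <- as_tibble(map) |> dplyr::arrange(.data$contig, .data$start)
  if (any(map$rate < 0)) stop("negative recombination rate", call. = FALSE)
  ov <- map |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()] &
                                 dplyr::n() > 1))
  if (any(ov$bad)) stop("overlapping recombination intervals", call. = FALSE)
  map
}

#' Assign recombination rates to genes
#'
#' With SNP positions supplied, each gene gets the arithmetic mean of the
#' map rate at its internal SNPs. Without SNPs, the fallback is the
#' length-weighted mean rate of map intervals overlapping the gene span
#' (equivalently, the per-base average over covered bases); the mode used
#' is recorded in the `"recomb_mode"` attribute. Genes with no overlap or
#' no internal SNPs get `NA` and drop out of recombination analyses.
#'
#' @param records Gene records with `contig`, `start`, `end` (1-based
#'   inclusive).
#' @param map Recombination map tibble ([read_recomb_map()]).
#' @param snp_positions Optional tibble with `contig`, `pos` (1-based).
#' @return `records` with a `recomb_rate` column.
#' @export
assign_recombination <- function(records, map, snp_positions = NULL) {
  rate <- rep(NA_real_, nrow(records))
  for (ctg in unique(records$contig)) {
    m <- map[map$contig == ctg, , drop = FALSE]
    ridx <- which(records$contig == ctg)
    if (!nrow(m)) next
    if (!is.null(snp_positions)) {
      sp <- snp_positions[snp_positions$contig == ctg, , drop = FALSE]
      for (i in ridx) {
        pos <- sp$pos[sp$pos >= records$start[i] & sp$pos <= records$end[i]]
        if (!length(pos)) next
        j <- findInterval(pos - 1L, m$start)            # 0-based position
        ok <- j >= 1L & (pos - 1L) < m$end[pmax(j, 1L)]
        if (!any(ok)) next
        rate[i] <- mean(m$rate[j[ok]])
      }
    } else {
      for (i in ridx) {
        g0 <- records$start[i] - 1L                      # half-open gene span
        g1 <- records$end[i]
        ov <- pmin(m$end, g1) - pmax(m$start, g0)
        keep <- ov > 0
        if (!any(keep)) next
        rate[i] <- sum(m$rate[keep] * ov[keep]) / sum(ov[keep])
      }
    }
  }
  records$recomb_rate <- rate
  attr(records, "recomb_mode") <-
    if (is.null(snp_positions)) "length_weighted_overlap" else "internal_snp_mean"
  records
}

#' Read a protein-abundance table and attach it to gene records
#'
#' @param path TSV with columns gene id and abundance (ppm); header
#'   tolerated.
#' @return Tibble `gene_id`, `abundance`.
#' @export
read_abundance <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  ab <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  names(ab) <- c("gene_id", "abundance")
  as_tibble(ab)
}

#' @rdname read_abundance
#' @param records Gene records tibble.
#' @param abundance Tibble from `read_abundance()`.
#' @return `records` with an `abundance` column (`NA` where missing).
#' @export
assign_abundance <- function(records, abundance) {
  dplyr::left_join(records, abundance, by = "gene_id")
}
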