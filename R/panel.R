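# Marker screening: windowed D-value scan over phased population genotypes.

#' Read a phased VCF into a haplotype cohort
#'
#' Loads a phased VCF (pipe-separated `GT` fields) and returns the two
#' haplotype base matrices over all biallelic SNV records. Multi-allelic
#' records and indels are skipped (the panel is SNV-only by construction) and
#' reported via the `skipped` attribute; unphased genotypes are an error.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return An object of class `msmix_phased`: a list with `variants` (tibble
#'   of `chrom`, `pos`, `ref`, `alt`), `hap_a`/`hap_b` (site x individual
#'   base matrices) and `individuals`.
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_phased_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {  # single-record VCFs come back as a bare vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " non-SNV or multi-allelic record(s) skipped")
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (any(grepl("/", gt, fixed = TRUE))) {
    abort("read_phased_vcf(): unphased genotypes found; phased GT required")
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (any(!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1")))) {
    abort("read_phased_vcf(): GT alleles other than 0/1 after SNV filtering")
  }
  to_base <- function(x) {
    m <- matrix(fix$REF[row(gt)], nrow = nrow(gt))
    m[x == "1"] <- fix$ALT[row(gt)][x == "1"]
    dimnames(m) <- dimnames(gt)
    m
  }
  out <- list(
    variants = tibble(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT
    ),
    hap_a = to_base(a1),
    hap_b = to_base(a2),
    individuals = colnames(gt)
  )
  attr(out, "skipped") <- n_skip
  structure(out, class = "msmix_phased")
}

#' D-value of one window
#'
#' The D-value is the fraction of the `choose(N, 2)` unordered pairs of
#' individuals that are distinguishable within the window, a pair counting as
#' distinguishable when its members differ at `min_diff` or more SNP
#' positions. By default positions are compared as unordered diploid
#' genotypes (phase ignored); `compare = "haplotype"` instead compares phased
#' haplotypes under the best of the two haplotype pairings.
#'
#' @param genotypes A tibble with one row per individual and columns
#'   `hap1`, `hap2`: equal-length haplotype strings over the window's SNP
#'   positions (may be empty strings for a SNP-free window).
#' @param min_diff Minimum number of differing positions for a pair to count
#'   (default 2).
#' @param compare `"genotype"` (default) or `"haplotype"`.
#' @return A one-row tibble with `t` (distinguishable pairs), `n_pairs`
#'   (`choose(N, 2)`) and `d_value = t / n_pairs`.
#' @examples
#' g <- tibble::tibble(hap1 = c("AC", "AT"), hap2 = c("AC", "GT"))
#' compute_d_value(g)
#' @export
compute_d_value <- function(genotypes, min_diff = 2,
                            compare = c("genotype", "haplotype")) {
  compare <- match.arg(compare)
  stopifnot(is.data.frame(genotypes), all(c("hap1", "hap2") %in% names(genotypes)))
  h1 <- genotypes$hap1
  h2 <- genotypes$hap2
  n <- length(h1)
  if (n < 2L) abort("compute_d_value(): at least 2 individuals required")
  if (length(unique(nchar(c(h1, h2)))) > 1L) {
    abort("compute_d_value(): haplotype strings must have equal length")
  }
  n_pairs <- choose(n, 2)
  s <- nchar(h1[1])
  if (s == 0L) {
    return(tibble(t = 0L, n_pairs = n_pairs, d_value = 0))
  }
  if (compare == "genotype") {
    # per-position unordered genotype codes, then pairwise difference counts
    diffs <- matrix(0L, n, n)
    for (j in seq_len(s)) {
      a <- substr(h1, j, j)
      b <- substr(h2, j, j)
      gcode <- ifelse(a <= b, paste0(a, b), paste0(b, a))
      diffs <- diffs + outer(gcode, gcode, "!=")
    }
    t_count <- sum(diffs[upper.tri(diffs)] >= min_diff)
  } else {
    t_count <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d_same <- hamming(h1[i], h1[j]) + hamming(h2[i], h2[j])
        d_swap <- hamming(h1[i], h2[j]) + hamming(h2[i], h1[j])
        if (min(d_same, d_swap) >= min_diff) t_count <- t_count + 1L
      }
    }
  }
  tibble(t = as.integer(t_count), n_pairs = n_pairs,
         d_value = t_count / n_pairs)
}

#' Scan phased genotypes with a sliding window and score each window
#'
#' Slides a `window_size`-bp window along each chromosome (step `step`) and
#' computes the D-value of every window that contains at least one
#' segregating site. Windows without sites are not reported. Variant records
#' must be position-sorted within chromosome.
#'
#' @param cohort An `msmix_phased` object from [read_phased_vcf()], or a list
#'   with the same fields.
#' @param window_size Window width in bp (default 75).
#' @param step Step between window starts in bp (default 1).
#' @inheritParams compute_d_value
#' @return A tibble of window scores in genomic order: `chrom`, `start`,
#'   `end` (1-based, inclusive), `n_snps`, `snp_pos` (list of positions),
#'   `t`, `n_pairs`, `d_value`.
#' @export
scan_windows <- function(cohort, window_size = 75, step = 1, min_diff = 2,
                         compare = c("genotype", "haplotype")) {
  compare <- match.arg(compare)
  v <- cohort$variants
  if (nrow(v) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_snps = integer(), snp_pos = list(), t = integer(),
                  n_pairs = numeric(), d_value = numeric()))
  }
  out <- list()
  for (chr in unique(v$chrom)) {
    idx_chr <- which(v$chrom == chr)
    pos <- v$pos[idx_chr]
    if (is.unsorted(pos, strictly = FALSE)) {
      abort("scan_windows(): variant records must be sorted by position")
    }
    starts <- seq.int(max(1L, min(pos) - window_size + 1L), max(pos), by = step)
    for (st in starts) {
      en <- st + window_size - 1L
      in_win <- idx_chr[pos >= st & pos <= en]
      if (length(in_win) == 0L) next
      g <- tibble(
        hap1 = apply(cohort$hap_a[in_win, , drop = FALSE], 2, paste, collapse = ""),
        hap2 = apply(cohort$hap_b[in_win, , drop = FALSE], 2, paste, collapse = "")
      )
      sc <- compute_d_value(g, min_diff = min_diff, compare = compare)
      out[[length(out) + 1L]] <- tibble(
        chrom = chr, start = as.integer(st), end = as.integer(en),
        n_snps = length(in_win), snp_pos = list(v$pos[in_win]),
        t = sc$t, n_pairs = sc$n_pairs, d_value = sc$d_value
      )
    }
  }
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' Filter scored windows into a marker panel
#'
#' Applies the screening rules to window scores: keep windows with
#' `d_value >= d_min` whose sequence contains neither a homopolymer run of
#' `min_homopolymer`+ bases nor a contiguous 2-6 bp tandem repeat of
#' `min_copies`+ copies, optionally reduce to a non-overlapping set (greedy,
#' highest D first), and lay out an amplicon of under `max_amplicon` bp
#' centred on each retained window. Retained windows receive sequential locus
#' identifiers in genomic order.
#'
#' @param scores Window scores from [scan_windows()].
#' @param ref Reference sequences: a named character vector (one element per
#'   chromosome) or a `Biostrings::DNAStringSet`.
#' @param d_min Minimum D-value (default 0.6).
#' @param min_homopolymer,min_copies Repeat-filter thresholds passed to
#'   [repeat_tracts()].
#' @param max_amplicon Amplicons must be strictly shorter than this (140).
#' @param overlap `"greedy"` (default) keeps a non-overlapping subset chosen
#'   by decreasing D; `"all"` keeps every passing window.
#' @param locus_prefix Prefix for locus identifiers (default `"CHM"`).
#' @return A panel tibble: `locus_id`, `chrom`, `window_start`, `window_end`,
#'   `n_snps`, `snp_pos` (list), `amplicon_start`, `amplicon_end`,
#'   `d_value`, `t`, `n_pairs`.
#' @export
filter_windows <- function(scores, ref, d_min = 0.6, min_homopolymer = 6,
                           min_copies = 3, max_amplicon = 140,
                           overlap = c("greedy", "all"),
                           locus_prefix = "CHM") {
  overlap <- match.arg(overlap)
  if (!is.character(ref)) ref <- setNames(as.character(ref), names(ref))
  if (nrow(scores) == 0L) return(empty_panel())
  bad_chrom <- setdiff(unique(scores$chrom), names(ref))
  if (length(bad_chrom) > 0L) {
    abort(paste0("filter_windows(): no reference sequence for ",
                 paste(bad_chrom, collapse = ", ")))
  }
  if (any(scores$start < 1L | scores$end > nchar(ref[scores$chrom]))) {
    abort("filter_windows(): window outside the reference sequence")
  }
  seqs <- substr(ref[scores$chrom], scores$start, scores$end)
  clean <- !vapply(seqs, has_repeat, logical(1),
                   min_homopolymer = min_homopolymer, min_copies = min_copies)
  keep <- scores[scores$d_value >= d_min & clean, , drop = FALSE]
  if (overlap == "greedy" && nrow(keep) > 1L) {
    ord <- order(-keep$d_value, keep$chrom, keep$start)
    chosen <- logical(nrow(keep))
    for (i in ord) {
      clash <- chosen & keep$chrom == keep$chrom[i] &
        keep$start <= keep$end[i] & keep$end >= keep$start[i]
      if (!any(clash)) chosen[i] <- TRUE
    }
    keep <- keep[chosen, , drop = FALSE]
  }
  keep <- arrange(keep, .data$chrom, .data$start)
  if (nrow(keep) == 0L) return(empty_panel())
  win_len <- keep$end - keep$start + 1L
  flank <- pmax(0L, as.integer(floor((max_amplicon - 1L - win_len) / 2)))
  amp_start <- pmax(1L, keep$start - flank)
  amp_end <- pmin(nchar(ref[keep$chrom]), keep$end + flank)
  tibble(
    locus_id = sprintf("%s%03d", locus_prefix, seq_len(nrow(keep))),
    chrom = keep$chrom,
    window_start = keep$start, window_end = keep$end,
    n_snps = keep$n_snps, snp_pos = keep$snp_pos,
    amplicon_start = as.integer(amp_start), amplicon_end = as.integer(amp_end),
    d_value = keep$d_value, t = keep$t, n_pairs = keep$n_pairs
  )
}

empty_panel <- function() {
  tibble(locus_id = character(), chrom = character(),
         window_start = integer(), window_end = integer(),
         n_snps = integer(), snp_pos = list(),
         amplicon_start = integer(), amplicon_end = integer(),
         d_value = numeric(), t = integer(), n_pairs = numeric())
}

#' Screen a phased VCF into a marker panel
#'
#' Convenience wrapper: [read_phased_vcf()] + [scan_windows()] +
#' [filter_windows()].
#'
#' @param vcf Path to a phased VCF.
#' @param ref_fasta Path to the reference FASTA.
#' @inheritParams scan_windows
#' @inheritParams filter_windows
#' @return A panel tibble (see [filter_windows()]).
#' @export
screen_markers <- function(vcf, ref_fasta, window_size = 75, step = 1,
                           d_min = 0.6, min_diff = 2, ...) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("screen_markers() requires the Biostrings package")
  }
  cohort <- read_phased_vcf(vcf)
  ref <- Biostrings::readDNAStringSet(ref_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  scores <- scan_windows(cohort, window_size = window_size, step = step,
                         min_diff = min_diff)
  filter_windows(scores, ref, d_min = d_min, ...)
}

#' Write a panel as BED plus TSV sidecar
#'
#' The BED holds 0-based half-open amplicon intervals named by locus; the TSV
#' sidecar carries window coordinates, comma-separated SNP positions and the
#' D statistics.
#'
#' @param panel A panel tibble from [filter_windows()] or [sim_panel()].
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  bed <- data.frame(
    chrom = panel$chrom,
    start = panel$amplicon_start - 1L,
    end = panel$amplicon_end,
    name = panel$locus_id
  )
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv <- data.frame(
    locus_id = panel$locus_id, chrom = panel$chrom,
    window_start = panel$window_start, window_end = panel$window_end,
    snp_pos = vapply(panel$snp_pos, paste, character(1), collapse = ","),
    amplicon_start = panel$amplicon_start, amplicon_end = panel$amplicon_end,
    d_value = panel$d_value, t = panel$t, n_pairs = panel$n_pairs
  )
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read a panel TSV written by [write_panel()]
#'
#' @param path Path to the `.tsv` sidecar.
#' @return A panel tibble.
#' @export
read_panel <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  tibble(
    locus_id = d$locus_id, chrom = as.character(d$chrom),
    window_start = as.integer(d$window_start),
    window_end = as.integer(d$window_end),
    n_snps = lengths(strsplit(as.character(d$snp_pos), ",")),
    snp_pos = lapply(strsplit(as.character(d$snp_pos), ","), as.integer),
    amplicon_start = as.integer(d$amplicon_start),
    amplicon_end = as.integer(d$amplicon_end),
    d_value = d$d_value, t = as.integer(d$t), n_pairs = d$n_pairs
  )
}
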