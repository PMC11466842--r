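# Allele extraction: aligned paired-end reads -> per-locus allele counts.

#' Extract per-locus allele observations from aligned read pairs
#'
#' For every read pair overlapping a panel locus, reads the base at each of
#' the locus's SNP positions from both mates and concatenates them (in
#' position order) into one allele string per mate. A mate is used only if it
#' is fully mapped (mapped, primary, no soft/hard clipping) and its aligned
#' span covers every SNP position. A SNP position is masked -- making the
#' whole pair unevaluable for the locus -- when it lies within, or within 2
#' bp of, (a) a repeat tract on the reference amplicon (homopolymer run of 6+
#' or a contiguous 2-6 bp tandem repeat of 3+ copies, the same detectors the
#' screener uses), (b) an indel in that mate's alignment, or (c) a run of 2+
#' consecutive mismatched aligned columns. Mismatch-run and repeat masking
#' require the reference (`ref`); base qualities are ignored unless
#' `min_baseq > 0`.
#'
#' @param bam Path to a coordinate-sorted BAM (or SAM, converted on the fly).
#' @param panel Panel tibble (see [filter_windows()] / [sim_panel()]).
#' @param ref Named character vector or `DNAStringSet` of reference
#'   sequences; `NULL` disables mismatch-run and repeat masking.
#' @param min_baseq Minimum base quality at SNP positions (0 = off, the
#'   default; qualities are otherwise ignored).
#' @return A tibble of read-pair observations: `locus_id`, `qname`,
#'   `allele_r1`, `allele_r2`, `evaluable`, `reason`.
#' @seealso [build_profile()] to reduce observations to allele counts.
#' @export
extract_read_pairs <- function(bam, panel, ref = NULL, min_baseq = 0) {
  for (p in c("Rsamtools", "GenomicAlignments", "Biostrings", "S4Vectors")) {
    if (!requireNamespace(p, quietly = TRUE)) {
      abort(paste0("extract_read_pairs() requires the ", p, " package"))
    }
  }
  if (grepl("\\.sam$", bam, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(bam, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  if (!is.null(ref) && !is.character(ref)) {
    ref <- setNames(as.character(ref), names(ref))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(aln)
  cig <- GenomicAlignments::cigar(aln)
  a_chr <- as.character(GenomicAlignments::seqnames(aln))
  a_start <- GenomicAlignments::start(aln)
  a_end <- GenomicAlignments::end(aln)
  layered <- GenomicAlignments::sequenceLayer(mc$seq, cig)
  layered_q <- if (min_baseq > 0) {
    GenomicAlignments::sequenceLayer(methods::as(mc$qual, "BStringSet"), cig)
  } else NULL
  clipped <- grepl("[SH]", cig)

  out <- vector("list", nrow(panel))
  for (li in seq_len(nrow(panel))) {
    locus <- panel[li, ]
    snp <- sort(locus$snp_pos[[1]])
    hits <- which(a_chr == locus$chrom & a_start <= max(snp) &
                    a_end >= min(snp))
    if (length(hits) == 0L) next

    # reference-derived masks, shared by all reads of the locus
    repeat_mask <- rep(FALSE, length(snp))
    ref_chr <- NULL
    if (!is.null(ref)) {
      if (!locus$chrom %in% names(ref)) {
        abort(paste0("extract_read_pairs(): no reference for ", locus$chrom))
      }
      ref_chr <- ref[[locus$chrom]]
      amp_seq <- substr(ref_chr, locus$amplicon_start, locus$amplicon_end)
      tr <- repeat_tracts(amp_seq)
      if (nrow(tr) > 0L) {
        tr_start <- tr$start + locus$amplicon_start - 1L
        tr_end <- tr$end + locus$amplicon_start - 1L
        for (k in seq_along(tr_start)) {
          repeat_mask <- repeat_mask |
            (snp >= tr_start[k] - 2L & snp <= tr_end[k] + 2L)
        }
      }
    }

    mate_allele <- character(length(hits))
    mate_status <- character(length(hits))
    for (hi in seq_along(hits)) {
      i <- hits[hi]
      st <- mate_status[hi] <- "ok"
      if (clipped[i]) {
        mate_status[hi] <- "mate_unmapped_or_clipped"
        next
      }
      if (a_start[i] > min(snp) || a_end[i] < max(snp)) {
        mate_status[hi] <- "mate_not_covering"
        next
      }
      if (any(repeat_mask)) {
        mate_status[hi] <- "masked_repeat"
        next
      }
      lay <- as.character(layered[[i]])
      off <- snp - a_start[i] + 1L
      bases <- substring(lay, off, off)
      # indels: deletions occupy reference space; insertions anchor between
      # reference columns. Mask SNPs within 2 bp of either.
      dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig[i], ops = "D", pos = a_start[i])[[1]]
      ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig[i], ops = "I", pos = a_start[i])[[1]]
      masked <- rep(FALSE, length(snp))
      if (length(dr) > 0L) {
        for (k in seq_along(dr)) {
          masked <- masked | (snp >= S4Vectors::start(dr)[k] - 2L &
                                snp <= S4Vectors::end(dr)[k] + 2L)
        }
      }
      if (length(ir) > 0L) {
        for (k in seq_along(ir)) {
          masked <- masked | (snp >= S4Vectors::start(ir)[k] - 2L &
                                snp <= S4Vectors::start(ir)[k] + 2L)
        }
      }
      if (any(masked)) {
        mate_status[hi] <- "masked_indel"
        next
      }
      if (!is.null(ref_chr)) {
        ref_span <- substr(ref_chr, a_start[i], a_end[i])
        mm <- strsplit(lay, "")[[1]] != strsplit(ref_span, "")[[1]] &
          strsplit(lay, "")[[1]] != "-"
        r <- rle(mm)
        run_end <- cumsum(r$lengths)
        run_start <- run_end - r$lengths + 1L
        bad <- which(r$values & r$lengths >= 2L)
        run_mask <- rep(FALSE, length(snp))
        for (k in bad) {
          lo <- a_start[i] + run_start[k] - 1L - 2L
          hiy <- a_start[i] + run_end[k] - 1L + 2L
          run_mask <- run_mask | (snp >= lo & snp <= hiy)
        }
        if (any(run_mask)) {
          mate_status[hi] <- "masked_mismatch_run"
          next
        }
      }
      if (min_baseq > 0) {
        layq <- as.character(layered_q[[i]])
        qch <- substring(layq, off, off)
        if (any(utf8ToInt(paste(qch, collapse = "")) - 33L < min_baseq)) {
          mate_status[hi] <- "masked_baseq"
          next
        }
      }
      if (any(bases == "-" | bases == "")) {
        mate_status[hi] <- "masked_indel"
        next
      }
      mate_allele[hi] <- paste(bases, collapse = "")
    }

    qn <- mc$qname[hits]
    first_mate <- bitwAnd(mc$flag[hits], 64L) > 0L
    obs <- tibble(qname = qn, allele = mate_allele, status = mate_status,
                  first = first_mate) %>%
      group_by(.data$qname) %>%
      summarise(
        allele_r1 = first_or_na(.data$allele[order(!.data$first)], 1L),
        allele_r2 = first_or_na(.data$allele[order(!.data$first)], 2L),
        n_mates = n(),
        bad = paste(setdiff(unique(.data$status), "ok"), collapse = ";"),
        .groups = "drop"
      ) %>%
      mutate(
        reason = dplyr::case_when(
          .data$n_mates < 2L ~ "single_mate",
          .data$bad != "" ~ .data$bad,
          TRUE ~ "ok"
        ),
        evaluable = .data$reason == "ok",
        locus_id = locus$locus_id
      ) %>%
      select("locus_id", "qname", "allele_r1", "allele_r2",
             "evaluable", "reason")
    out[[li]] <- obs
  }
  bind_rows(out)
}

first_or_na <- function(x, i) {
  if (length(x) >= i && nzchar(x[i])) x[i] else NA_character_
}

#' Reduce read-pair observations to a per-locus allele profile
#'
#' A pair contributes one count to its allele iff it is evaluable and both
#' mates report the identical allele string; discordant pairs (whose mates
#' disagree -- overwhelmingly independent sequencing errors) contribute
#' nothing and are tallied in the `discards` attribute.
#'
#' @param observations Tibble from [extract_read_pairs()], or any tibble with
#'   `locus_id`, `allele_r1`, `allele_r2` and optionally `evaluable`.
#' @return A profile tibble `locus_id`, `allele`, `count` (class
#'   `msmix_profile`), with a `discards` attribute summarising dropped pairs
#'   by reason.
#' @export
build_profile <- function(observations) {
  if (nrow(observations) == 0L) {
    p <- msmix_tbl(tibble(locus_id = character(), allele = character(),
                          count = integer()), "msmix_profile")
    attr(p, "discards") <- tibble(reason = character(), n = integer())
    return(p)
  }
  obs <- observations
  if (!"evaluable" %in% names(obs)) obs$evaluable <- TRUE
  if (!"reason" %in% names(obs)) obs$reason <- ifelse(obs$evaluable, "ok", "masked")
  obs$concordant <- obs$evaluable & !is.na(obs$allele_r1) &
    !is.na(obs$allele_r2) & obs$allele_r1 == obs$allele_r2
  prof <- obs %>%
    filter(.data$concordant) %>%
    count(.data$locus_id, allele = .data$allele_r1, name = "count") %>%
    arrange(.data$locus_id, desc(.data$count), .data$allele)
  discards <- obs %>%
    filter(!.data$concordant) %>%
    mutate(reason = ifelse(.data$evaluable, "discordant", .data$reason)) %>%
    count(.data$reason, name = "n")
  prof <- msmix_tbl(prof, "msmix_profile")
  attr(prof, "discards") <- discards
  prof
}

#' Write / read per-sample profile TSVs
#'
#' @param profile Profile tibble (`locus_id`, `allele`, `count`).
#' @param path Output path.
#' @return `path`, invisibly (writer); a profile tibble (reader).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile[, c("locus_id", "allele", "count")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer"))
  msmix_tbl(as_tibble(d), "msmix_profile")
}
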