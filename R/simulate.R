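# Simulator: panels, populations, single-source samples and mixtures with a
# molecule-level PCR error layer and a per-base sequencing error layer.

# Printed composition of the 567-locus kit: loci per linked-SNP category.
default_category_counts <- function() {
  c(`1` = 48, `2` = 157, `3` = 246, `4` = 91, `5` = 25)
}

#' Category composition of a panel
#'
#' Tabulates loci by number of linked SNPs and the percentage each category
#' contributes.
#'
#' @param panel A panel tibble.
#' @return Tibble `category` (SNPs per locus), `n_loci`, `percentage`.
#' @export
panel_category_summary <- function(panel) {
  panel %>%
    count(category = .data$n_snps, name = "n_loci") %>%
    mutate(percentage = 100 * .data$n_loci / sum(.data$n_loci))
}

#' Category percentages from locus counts
#'
#' @param counts Named or unnamed vector of loci per category.
#' @return Tibble `category`, `n_loci`, `percentage`.
#' @export
category_percentages <- function(counts) {
  tibble(
    category = if (is.null(names(counts))) seq_along(counts)
               else as.integer(names(counts)),
    n_loci = as.integer(counts),
    percentage = as.numeric(unname(100 * counts / sum(counts)))
  )
}

#' Simulate a multi-SNP marker panel
#'
#' Draws a panel of `n_loci` markers whose linked-SNP category mix follows
#' `category_counts` (largest-remainder allocation, so the default 567-locus
#' panel reproduces the kit's printed 48/157/246/91/25 split exactly). Each
#' locus gets a 75-bp window inside a sub-140-bp amplicon on a synthetic
#' chromosome, `n` biallelic SNP positions, the full set of `2^n` haplotype
#' alleles, and haplotype frequencies drawn from a symmetric Dirichlet.
#' Amplicon sequences are generated free of the screener's repeat tracts so
#' extraction masking stays neutral on simulated data.
#'
#' @param n_loci Number of loci (default 567).
#' @param category_counts Relative weights (or counts) of the 1-5-SNP
#'   categories.
#' @param dirichlet Symmetric Dirichlet concentration for haplotype
#'   frequencies (default 0.25, which gives panels an expected
#'   heterozygosity around 0.55).
#' @param window_size,max_amplicon Window and amplicon-cap sizes in bp.
#' @param chrom Name of the synthetic chromosome.
#' @param seed Optional RNG seed.
#' @return A panel tibble (as [filter_windows()]) with additional list
#'   columns `haplotypes` and `freqs`, and the synthetic reference attached
#'   as attribute `ref` (named character vector).
#' @export
sim_panel <- function(n_loci = 567, category_counts = default_category_counts(),
                      dirichlet = 0.25, window_size = 75, max_amplicon = 140,
                      chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_cat <- allocate_counts(n_loci, category_counts)
  cats <- if (is.null(names(category_counts))) seq_along(category_counts)
          else as.integer(names(category_counts))
  n_snps <- rep(cats, n_cat)
  spacing <- 200L
  amp_len <- max_amplicon - 1L
  flank <- as.integer(floor((amp_len - window_size) / 2))
  bases <- c("A", "C", "G", "T")

  amp_start <- (seq_len(n_loci) - 1L) * spacing + 31L
  amp_end <- amp_start + amp_len - 1L
  win_start <- amp_start + flank
  win_end <- win_start + window_size - 1L

  ref_len <- n_loci * spacing + 100L
  ref_chars <- sample(bases, ref_len, replace = TRUE)

  snp_pos <- vector("list", n_loci)
  haplotypes <- vector("list", n_loci)
  freqs <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    s <- n_snps[i]
    # keep SNPs >= 3 bp apart so substituted alleles never mimic the
    # extractor's consecutive-mismatch artifact signature
    repeat {
      pos <- sort(sample(seq.int(win_start[i], win_end[i]), s))
      if (s == 1L || min(diff(pos)) >= 3L) break
    }
    snp_pos[[i]] <- pos
    # amplicon sequence without repeat tracts (resample until clean)
    idx <- amp_start[i]:amp_end[i]
    repeat {
      amp_seq <- paste(ref_chars[idx], collapse = "")
      if (!has_repeat(amp_seq)) break
      ref_chars[idx] <- sample(bases, length(idx), replace = TRUE)
    }
    ref_b <- ref_chars[pos]
    alt_b <- vapply(ref_b, function(b) sample(setdiff(bases, b), 1),
                    character(1))
    combos <- as.matrix(expand.grid(rep(list(c(0L, 1L)), s)))[, s:1, drop = FALSE]
    haps <- apply(combos, 1L, function(row) {
      paste(ifelse(row == 0L, ref_b, alt_b), collapse = "")
    })
    haplotypes[[i]] <- haps
    freqs[[i]] <- rdirichlet1(dirichlet, length(haps))
  }
  panel <- tibble(
    locus_id = sprintf("CHM%03d", seq_len(n_loci)),
    chrom = chrom,
    window_start = win_start, window_end = win_end,
    n_snps = as.integer(n_snps), snp_pos = snp_pos,
    amplicon_start = amp_start, amplicon_end = amp_end,
    d_value = NA_real_, t = NA_integer_, n_pairs = NA_real_,
    haplotypes = haplotypes, freqs = freqs
  )
  attr(panel, "ref") <- setNames(paste(ref_chars, collapse = ""), chrom)
  panel
}

#' Simulate a phased population over a panel
#'
#' Each individual receives two haplotypes per locus by independent draws
#' from the locus's haplotype frequencies, so Hardy-Weinberg equilibrium
#' holds by construction.
#'
#' @param panel A panel from [sim_panel()] (needs `haplotypes`, `freqs`).
#' @param n_individuals Population size.
#' @param seed Optional RNG seed.
#' @return Tibble `individual`, `locus_id`, `hap1`, `hap2`.
#' @export
sim_population <- function(panel, n_individuals, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("I%03d", seq_len(n_individuals))
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    haps <- panel$haplotypes[[i]]
    f <- panel$freqs[[i]]
    draw <- sample(haps, 2L * n_individuals, replace = TRUE, prob = f)
    out[[i]] <- tibble(
      individual = ids, locus_id = panel$locus_id[i],
      hap1 = draw[seq_len(n_individuals)],
      hap2 = draw[n_individuals + seq_len(n_individuals)]
    )
  }
  bind_rows(out)
}

#' True allele sets of selected individuals
#'
#' @param population Tibble from [sim_population()].
#' @param ids Individual identifiers.
#' @return Tibble `contributor`, `locus_id`, `allele` (distinct alleles).
#' @export
contributor_truth <- function(population, ids) {
  population %>%
    filter(.data$individual %in% ids) %>%
    tidyr::pivot_longer(c("hap1", "hap2"), values_to = "allele") %>%
    distinct(contributor = .data$individual, .data$locus_id, .data$allele)
}

# k mutated bases drawn from Binomial(L, p) conditioned on k >= 1.
rcond_binom_pos <- function(n, L, p) {
  if (n == 0L) return(integer())
  ks <- seq_len(L)
  w <- stats::dbinom(ks, L, p)
  sample(ks, n, replace = TRUE, prob = w)
}

# Mutate each string at k random positions to random different bases.
mutate_strings <- function(strings, ks) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_along(strings), function(i) {
    ch <- strsplit(strings[i], "")[[1]]
    pos <- sample.int(length(ch), ks[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1),
                      character(1))
    paste(ch, collapse = "")
  }, character(1))
}

#' Simulate amplicon read-pair profiles for a (possibly mixed) sample
#'
#' Implements the generative model end to end, per locus:
#'
#' 1. **Templates** -- for each contributor haplotype, template molecules
#'    `~ Poisson(total_ng x fraction / haploid_ng)`; zero molecules at a
#'    locus is dropout and is recorded in the truth.
#' 2. **PCR layer** -- each molecule's allele string is mutated once at rate
#'    `pcr_error` per base; both mates of every read pair inherit the
#'    molecule's allele, so these errors survive concordance filtering.
#' 3. **Depth** -- `Poisson(mean_depth)` read pairs per locus, assigned to
#'    molecules uniformly (proportionally to molecule counts).
#' 4. **Sequencing layer** -- each mate's bases are misread independently at
#'    `seq_error` per base; only pairs whose two mates report the identical
#'    allele are retained, exactly as [build_profile()] would.
#'
#' With `detail = "counts"` (default) the sequencing layer is drawn at
#' molecule-group level from its exact per-pair outcome probabilities
#' (identical in distribution, much faster); `detail = "pairs"`
#' additionally emits one record per read pair with its molecule id,
#' post-PCR allele and both mate alleles, for truth-tracing tests.
#'
#' @param panel Panel from [sim_panel()].
#' @param population Population from [sim_population()].
#' @param contributors Named numeric vector of mass fractions (names =
#'   individual ids), or a tibble `individual`, `fraction`. Must sum to 1.
#' @param total_ng Total DNA input in nanograms (default 1).
#' @param mean_depth Mean read pairs per locus (default 1150).
#' @param seq_error Per-base, per-mate sequencing error rate (default 0.001).
#' @param pcr_error Per-base, per-molecule PCR error rate (default 1e-4).
#' @param haploid_ng Haploid genome mass in ng driving the template-copy
#'   model (default 0.0033, i.e. 3.3 pg).
#' @param seed Optional RNG seed.
#' @param detail `"counts"` or `"pairs"` (see Details).
#' @return A list of class `msmix_sim`: `profile` (tibble `locus_id`,
#'   `allele`, `count` of concordant pairs), `truth` (list: `contributors`,
#'   `alleles` = per-contributor true alleles, `molecules` = molecule groups
#'   with read counts, `dropout` = contributor haplotypes with zero
#'   molecules), and under `detail = "pairs"` also `pairs`.
#' @export
sim_reads <- function(panel, population, contributors, total_ng = 1,
                      mean_depth = 1150, seq_error = 0.001, pcr_error = 1e-4,
                      haploid_ng = 0.0033, seed = NULL,
                      detail = c("counts", "pairs")) {
  detail <- match.arg(detail)
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(contributors)) {
    frac <- setNames(contributors$fraction, contributors$individual)
  } else {
    frac <- contributors
  }
  if (abs(sum(frac) - 1) > 1e-6) {
    abort("sim_reads(): contributor fractions must sum to 1")
  }
  miss <- setdiff(names(frac), unique(population$individual))
  if (length(miss) > 0L) {
    abort(paste0("sim_reads(): contributors absent from population: ",
                 paste(miss, collapse = ", ")))
  }

  geno <- population %>%
    filter(.data$individual %in% names(frac)) %>%
    tidyr::pivot_longer(c("hap1", "hap2"), names_to = "source_hap",
                        values_to = "hap")
  lambda <- total_ng * unname(frac[geno$individual]) / haploid_ng
  m <- rpois(nrow(geno), lambda)
  L <- nchar(geno$hap)

  # PCR layer: split each haplotype's molecules into unmutated + mutants
  p_any <- 1 - (1 - pcr_error)^L
  n_mut <- rbinom(nrow(geno), m, p_any)
  groups <- tibble(
    locus_id = geno$locus_id, contributor = geno$individual,
    source_hap = geno$source_hap, source_allele = geno$hap,
    allele = geno$hap, n_mol = m - n_mut, is_mutant = FALSE
  )
  mut_rows <- rep.int(seq_len(nrow(geno)), n_mut)
  if (length(mut_rows) > 0L) {
    Lm <- L[mut_rows]
    ks <- integer(length(mut_rows))
    for (Lv in unique(Lm)) {
      sel <- Lm == Lv
      ks[sel] <- rcond_binom_pos(sum(sel), Lv, pcr_error)
    }
    mutants <- tibble(
      locus_id = geno$locus_id[mut_rows],
      contributor = geno$individual[mut_rows],
      source_hap = geno$source_hap[mut_rows],
      source_allele = geno$hap[mut_rows],
      allele = mutate_strings(geno$hap[mut_rows], unname(ks)),
      n_mol = 1L, is_mutant = TRUE
    )
    groups <- bind_rows(groups, mutants)
  }
  dropout <- groups %>%
    filter(!.data$is_mutant & .data$n_mol == 0L) %>%
    anti_join(groups %>% filter(.data$n_mol > 0L),
              by = c("locus_id", "contributor", "source_allele")) %>%
    distinct(.data$locus_id, .data$contributor, .data$source_allele)
  groups <- filter(groups, .data$n_mol > 0L)

  # depth: Poisson pairs per locus, multinomial over molecules
  groups <- arrange(groups, .data$locus_id)
  lid <- unique(panel$locus_id)
  reads <- integer(nrow(groups))
  gsplit <- split(seq_len(nrow(groups)), groups$locus_id)
  for (g in gsplit) {
    np <- rpois(1L, mean_depth)
    if (np == 0L) next
    reads[g] <- as.integer(rmultinom(1L, np, groups$n_mol[g]))
  }
  groups$reads <- reads

  truth <- list(
    contributors = tibble(individual = names(frac), fraction = unname(frac)),
    alleles = contributor_truth(population, names(frac)),
    molecules = groups,
    dropout = dropout,
    config = list(total_ng = total_ng, mean_depth = mean_depth,
                  seq_error = seq_error, pcr_error = pcr_error,
                  haploid_ng = haploid_ng)
  )

  if (detail == "pairs") {
    act <- groups[groups$reads > 0L, , drop = FALSE]
    pair_grp <- rep.int(seq_len(nrow(act)), act$reads)
    n_pairs_tot <- length(pair_grp)
    molecule <- vapply(seq_len(n_pairs_tot), function(i) {
      sample.int(act$n_mol[pair_grp[i]], 1L)
    }, integer(1))
    pre <- act$allele[pair_grp]
    Lp <- nchar(pre)
    r1 <- pre; r2 <- pre
    e1 <- rbinom(n_pairs_tot, Lp, seq_error)
    e2 <- rbinom(n_pairs_tot, Lp, seq_error)
    if (any(e1 > 0)) {
      r1[e1 > 0] <- mutate_strings(pre[e1 > 0], e1[e1 > 0])
    }
    if (any(e2 > 0)) {
      r2[e2 > 0] <- mutate_strings(pre[e2 > 0], e2[e2 > 0])
    }
    pairs <- tibble(
      locus_id = act$locus_id[pair_grp],
      contributor = act$contributor[pair_grp],
      source_hap = act$source_hap[pair_grp],
      molecule = paste0(act$locus_id[pair_grp], ":", pair_grp, ":", molecule),
      pre_seq_allele = pre, allele_r1 = r1, allele_r2 = r2,
      concordant = r1 == r2
    )
    profile <- pairs %>%
      filter(.data$concordant) %>%
      count(.data$locus_id, allele = .data$allele_r1, name = "count")
    out <- list(profile = msmix_tbl(profile, "msmix_profile"),
                truth = truth, pairs = pairs)
    class(out) <- "msmix_sim"
    return(out)
  }

  # counts mode: exact group-level law of the concordance-filtered outcome
  Lg <- nchar(groups$allele)
  p_base_ok <- (1 - seq_error)^2
  p_base_sw <- seq_error^2 / 3
  p_conc <- (p_base_ok + p_base_sw)^Lg
  p_cc <- (1 - seq_error)^(2 * Lg)
  n_conc <- rbinom(nrow(groups), groups$reads, p_conc)
  n_cc <- rbinom(nrow(groups), n_conc, ifelse(p_conc > 0, p_cc / p_conc, 0))
  n_cw <- n_conc - n_cc
  prof <- tibble(locus_id = groups$locus_id, allele = groups$allele,
                 count = n_cc)
  cw_rows <- rep.int(seq_len(nrow(groups)), n_cw)
  if (length(cw_rows) > 0L) {
    p_cond <- p_base_sw / (p_base_ok + p_base_sw)
    ks <- vapply(cw_rows, function(i) {
      rcond_binom_pos(1L, Lg[i], p_cond)
    }, integer(1))
    prof <- bind_rows(prof, tibble(
      locus_id = groups$locus_id[cw_rows],
      allele = mutate_strings(groups$allele[cw_rows], ks),
      count = 1L
    ))
  }
  profile <- prof %>%
    filter(.data$count > 0L) %>%
    group_by(.data$locus_id, .data$allele) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  out <- list(profile = msmix_tbl(profile, "msmix_profile"), truth = truth)
  class(out) <- "msmix_sim"
  out
}

#' Simulate a cohort of single-source sample profiles
#'
#' Runs [sim_reads()] once per individual and stacks the profiles with a
#' `sample_id` column, the shape [estimate_error_profile()] consumes.
#'
#' @inheritParams sim_reads
#' @param individuals Individual ids to sequence (one sample each).
#' @return Tibble `sample_id`, `locus_id`, `allele`, `count`.
#' @export
sim_cohort_profiles <- function(panel, population, individuals, total_ng = 1,
                                mean_depth = 1150, seq_error = 0.001,
                                pcr_error = 1e-4, haploid_ng = 0.0033,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(individuals, function(id) {
    sim <- sim_reads(panel, population, setNames(1, id), total_ng = total_ng,
                     mean_depth = mean_depth, seq_error = seq_error,
                     pcr_error = pcr_error, haploid_ng = haploid_ng)
    mutate(sim$profile, sample_id = id)
  })
  bind_rows(out) %>% select("sample_id", "locus_id", "allele", "count")
}

#' Experimental design grids of the mixture and sensitivity studies
#'
#' `kind = "table1"` returns the 75-sample mixture design: 25 two-person,
#' 25 three-person and 23 four-person mixtures over ratio series from 90:10
#' down to sub-percent minors, plus one balanced 5-person and one balanced
#' 10-person mixture. `kind = "dilution"` returns the sensitivity design:
#' 2 single-source samples x 10 two-fold inputs (5 ng down to ~0.0098 ng)
#' x 3 replicates = 60 samples. Ratio labels are kept verbatim; `fractions`
#' are the labels normalised to sum to 1.
#'
#' @param kind `"table1"` or `"dilution"`.
#' @return A tibble, one row per planned sample: `design_id`,
#'   `n_contributors`, `ratio` (label), `fractions` (list), `total_ng`,
#'   and for the dilution design `sample` and `replicate`.
#' @export
design_grid <- function(kind = c("table1", "dilution")) {
  kind <- match.arg(kind)
  if (kind == "dilution") {
    inputs <- c(5, 2.5, 1.25, 0.625, 0.3125, 0.15625, 0.078125, 0.0390625,
                0.01953125, 0.00976563)
    grid <- tidyr::expand_grid(sample = c("A", "B"), total_ng = inputs,
                               replicate = 1:3)
    return(grid %>%
             mutate(design_id = sprintf("DIL%02d", row_number()),
                    n_contributors = 1L, ratio = "100",
                    fractions = list(1)) %>%
             select("design_id", "n_contributors", "ratio", "fractions",
                    "total_ng", "sample", "replicate"))
  }
  series <- list(
    list(r = c(90, 10), ng = c(5, 2, 1, 0.5, 0.2, 0.1, 0.05)),
    list(r = c(95, 5), ng = c(5, 2, 1, 0.5, 0.2, 0.1)),
    list(r = c(98, 2), ng = c(5, 2, 1, 0.5, 0.2)),
    list(r = c(99, 1), ng = c(5, 2, 1, 0.5)),
    list(r = c(99.5, 0.5), ng = c(5, 2, 1)),
    list(r = c(70, 20, 10), ng = c(5, 2, 1, 0.5, 0.2, 0.1, 0.05)),
    list(r = c(85, 10, 5), ng = c(5, 2, 1, 0.5, 0.2, 0.1)),
    list(r = c(94, 4, 2), ng = c(5, 2, 1, 0.5, 0.2)),
    list(r = c(97, 2, 1), ng = c(5, 2, 1, 0.5)),
    list(r = c(98.5, 1, 0.5), ng = c(5, 2, 1)),
    list(r = c(50, 20, 20, 10), ng = c(5, 2, 1, 0.5, 0.2, 0.1, 0.05)),
    list(r = c(65, 20, 10, 5), ng = c(5, 2, 1, 0.5, 0.2, 0.1)),
    list(r = c(86, 8, 4, 2), ng = c(5, 2, 1, 0.5, 0.2)),
    list(r = c(93, 4, 2, 1), ng = c(5, 2, 1)),
    list(r = c(96.5, 0.2, 0.1, 0.05), ng = c(5, 2)),
    list(r = rep(20, 5), ng = 5),
    list(r = rep(10, 10), ng = 10)
  )
  rows <- lapply(series, function(s) {
    tibble(
      n_contributors = length(s$r),
      ratio = paste(s$r, collapse = ":"),
      fractions = list(s$r / sum(s$r)),
      total_ng = s$ng
    )
  })
  bind_rows(rows) %>%
    mutate(design_id = sprintf("MIX%02d", row_number())) %>%
    select("design_id", "n_contributors", "ratio", "fractions", "total_ng")
}

#' Write a pairs-mode simulation as SAM + reference FASTA
#'
#' Renders each simulated read pair as two fully mapped 139-bp alignments
#' over the locus amplicon (the amplicon reference sequence with the mate's
#' allele substituted at the SNP positions), so the alignment-facing filters
#' of [extract_read_pairs()] can be integration-tested against simulator
#' truth.
#'
#' @param sim An `msmix_sim` from `sim_reads(..., detail = "pairs")`.
#' @param panel The panel the simulation used (carries the `ref` attribute).
#' @param prefix Output prefix; writes `<prefix>.sam` and `<prefix>.fa`.
#' @return The two paths, invisibly.
#' @export
write_sim_sam <- function(sim, panel, prefix) {
  if (is.null(sim$pairs)) {
    abort("write_sim_sam(): needs a simulation run with detail = \"pairs\"")
  }
  ref <- attr(panel, "ref")
  if (is.null(ref)) abort("write_sim_sam(): panel lacks the ref attribute")
  chrom <- names(ref)[1]
  fa_path <- paste0(prefix, ".fa")
  writeLines(c(paste0(">", chrom), as.character(ref[[1]])), fa_path)

  p <- sim$pairs %>%
    inner_join(select(panel, "locus_id", "amplicon_start", "amplicon_end",
                      "snp_pos"),
               by = "locus_id")
  amp_seq <- substring(ref[[1]], p$amplicon_start, p$amplicon_end)
  place_allele <- function(amp, allele, snp, astart) {
    ch <- strsplit(amp, "")[[1]]
    ch[snp - astart + 1L] <- strsplit(allele, "")[[1]]
    paste(ch, collapse = "")
  }
  seq1 <- vapply(seq_len(nrow(p)), function(i) {
    place_allele(amp_seq[i], p$allele_r1[i], p$snp_pos[[i]],
                 p$amplicon_start[i])
  }, character(1))
  seq2 <- vapply(seq_len(nrow(p)), function(i) {
    place_allele(amp_seq[i], p$allele_r2[i], p$snp_pos[[i]],
                 p$amplicon_start[i])
  }, character(1))
  qname <- sprintf("%s_p%06d", p$locus_id, seq_len(nrow(p)))
  len <- nchar(seq1)
  cig <- paste0(len, "M")
  qual <- vapply(len, function(l) paste(rep("I", l), collapse = ""),
                 character(1))
  sam_line <- function(qn, flag, pos, cg, sq, ql) {
    paste(qn, flag, chrom, pos, 60L, cg, "=", pos, 0L, sq, ql, sep = "\t")
  }
  lines <- c(
    paste0("@HD\tVN:1.6\tSO:coordinate"),
    paste0("@SQ\tSN:", chrom, "\tLN:", nchar(ref[[1]])),
    as.vector(rbind(
      sam_line(qname, 99L, p$amplicon_start, cig, seq1, qual),
      sam_line(qname, 147L, p$amplicon_start, cig, seq2, qual)
    ))
  )
  sam_path <- paste0(prefix, ".sam")
  writeLines(lines, sam_path)
  invisible(c(sam = sam_path, fasta = fa_path))
}
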