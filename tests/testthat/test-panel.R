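# Marker screening: D-value, window scan, panel filters.

test_that("D-value handles degenerate cohorts", {
  same <- tibble::tibble(hap1 = rep("ACG", 10), hap2 = rep("ACG", 10))
  sc <- compute_d_value(same)
  expect_equal(sc$t, 0L)
  expect_equal(sc$d_value, 0)

  two <- tibble::tibble(hap1 = c("AA", "CC"), hap2 = c("AA", "CC"))
  sc <- compute_d_value(two)
  expect_equal(sc$t, 1L)
  expect_equal(sc$d_value, 1)

  empty <- tibble::tibble(hap1 = c("", ""), hap2 = c("", ""))
  sc <- compute_d_value(empty)
  expect_equal(sc$t, 0L)
  expect_equal(sc$d_value, 0)

  expect_error(compute_d_value(tibble::tibble(hap1 = "A", hap2 = "A")),
               "at least 2")
})

test_that("D-value matches the exhaustive pairwise oracle on a toy cohort", {
  g <- tibble::tibble(
    hap1 = c("ACA", "ACC", "GCA", "GTC", "ACA"),
    hap2 = c("ACA", "GCA", "GCC", "GTC", "GTA")
  )
  o <- oracle_d_value(g$hap1, g$hap2)
  sc <- compute_d_value(g)
  expect_equal(sc$t, o$t)
  expect_equal(sc$n_pairs, o$n_pairs)
  expect_equal(sc$d_value, o$d)
})

test_that("D-value equals the oracle on random cohorts (N <= 20, S <= 10)", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    s <- sample(1:10, 1)
    g <- random_cohort(n, s, bases = c("A", "C", "G", "T"))
    o <- oracle_d_value(g$hap1, g$hap2)
    sc <- compute_d_value(g)
    expect_equal(sc$t, o$t)
    expect_equal(sc$d_value, o$d)
    expect_gte(sc$d_value, 0)
    expect_lte(sc$d_value, 1)
  }
})

test_that("D is invariant to relabeling; duplication adds exactly the copied relations", {
  set.seed(7)
  for (rep in 1:10) {
    g <- random_cohort(8, 4)
    sc0 <- compute_d_value(g)
    perm <- g[sample(nrow(g)), ]
    expect_equal(compute_d_value(perm)$d_value, sc0$d_value)
    # duplicating individual i adds one indistinguishable pair (i vs copy)
    # plus a copy of i's relations to everyone else
    i <- 3L
    d_i <- sum(vapply(seq_len(nrow(g))[-i], function(j) {
      oracle_d_value(g$hap1[c(i, j)], g$hap2[c(i, j)])$t
    }, integer(1)))
    dup <- dplyr::bind_rows(g, g[i, ])
    sc1 <- compute_d_value(dup)
    expect_equal(sc1$t, sc0$t + d_i)
    expect_equal(sc1$n_pairs, choose(9, 2))
  }
})

test_that("phase-aware comparison is available and at least as strict", {
  # identical unordered genotypes but distinct haplotype phasings
  g <- tibble::tibble(hap1 = c("ACT", "AAT"), hap2 = c("CAT", "CCT"))
  expect_equal(compute_d_value(g, compare = "genotype")$t, 0L)
  expect_equal(compute_d_value(g, compare = "haplotype")$t, 1L)
})

test_that("window scan scores every covered window and matches per-window recompute", {
  set.seed(11)
  n_ind <- 6
  pos <- c(10L, 35L, 60L, 61L, 130L, 180L)
  hap_a <- matrix(sample(c("A", "C"), length(pos) * n_ind, TRUE),
                  nrow = length(pos))
  hap_b <- matrix(sample(c("A", "C"), length(pos) * n_ind, TRUE),
                  nrow = length(pos))
  cohort <- list(
    variants = tibble::tibble(chrom = "chr1", pos = pos,
                              ref = "A", alt = "C"),
    hap_a = hap_a, hap_b = hap_b,
    individuals = sprintf("S%d", 1:n_ind)
  )
  scores <- scan_windows(cohort, window_size = 50, step = 1)
  expect_true(all(scores$n_snps >= 1))
  expect_false(is.unsorted(scores$start))
  # spot-check 10 windows against compute_d_value on the window's sites
  for (i in sample(nrow(scores), 10)) {
    idx <- match(scores$snp_pos[[i]], pos)
    g <- tibble::tibble(
      hap1 = apply(hap_a[idx, , drop = FALSE], 2, paste, collapse = ""),
      hap2 = apply(hap_b[idx, , drop = FALSE], 2, paste, collapse = "")
    )
    expect_equal(scores$d_value[i], compute_d_value(g)$d_value)
  }
})

test_that("a single segregating site can never be distinguishable", {
  cohort <- list(
    variants = tibble::tibble(chrom = "chr1", pos = 50L, ref = "A",
                              alt = "C"),
    hap_a = matrix(c("A", "C", "A", "C"), nrow = 1),
    hap_b = matrix(c("A", "A", "C", "C"), nrow = 1),
    individuals = sprintf("S%d", 1:4)
  )
  scores <- scan_windows(cohort, window_size = 20)
  expect_true(all(scores$t == 0L))
  expect_true(all(scores$d_value == 0))
})

test_that("empty variant sets and unsorted input are handled", {
  cohort <- list(variants = tibble::tibble(chrom = character(),
                                           pos = integer(),
                                           ref = character(),
                                           alt = character()),
                 hap_a = matrix(character(), 0, 0),
                 hap_b = matrix(character(), 0, 0), individuals = character())
  expect_equal(nrow(scan_windows(cohort)), 0L)

  bad <- list(
    variants = tibble::tibble(chrom = "chr1", pos = c(100L, 50L),
                              ref = "A", alt = "C"),
    hap_a = matrix("A", 2, 2), hap_b = matrix("C", 2, 2),
    individuals = c("S1", "S2")
  )
  expect_error(scan_windows(bad), "sorted")
})

test_that("window filters enforce D threshold, repeat content and bounds", {
  clean <- "ACGGTCAGTTCGAATGCCAT"  # 20 bp, no tracts
  ref_clean <- c(chr1 = paste(
    "TTGACCGGAATCGTGACATG", clean, "CATGGAATTCCGGATAGCTA",
    "AAAAAAAA", "GCGCGCGC", "TGCATGACGTTCAGGATCCATTGACGTAGCATCAGTTACGGATCATGA",
    sep = ""))  # homopolymer at 61-68, tandem at 69-76, clean elsewhere
  mk <- function(start, d) tibble::tibble(
    chrom = "chr1", start = start, end = start + 19L, n_snps = 2L,
    snp_pos = list(c(start + 3L, start + 10L)), t = NA_integer_,
    n_pairs = 10, d_value = d
  )
  scores <- dplyr::bind_rows(
    mk(21L, 0.59),   # clean but below threshold
    mk(21L, 0.80),   # clean, passes
    mk(61L, 0.90),   # homopolymer AAAAAAAA at 61-68
    mk(69L, 0.90)    # GCGCGCGC tandem at 69-76
  )
  out <- filter_windows(scores, ref_clean, overlap = "all")
  expect_equal(nrow(out), 1L)
  expect_equal(out$window_start, 21L)
  expect_equal(out$d_value, 0.8)
  expect_lt(out$amplicon_end - out$amplicon_start + 1L, 140L)
  expect_true(out$amplicon_start <= out$window_start &&
                out$amplicon_end >= out$window_end)

  expect_error(filter_windows(mk(1000L, 0.9), ref_clean), "outside")
})

test_that("greedy selection keeps the best of overlapping windows", {
  ref <- c(chr1 = paste(rep(c("A", "C", "G", "T", "A", "C", "T", "G"), 40),
                        collapse = ""))
  mk <- function(start, d) tibble::tibble(
    chrom = "chr1", start = start, end = start + 19L, n_snps = 2L,
    snp_pos = list(c(start + 3L, start + 10L)), t = NA_integer_,
    n_pairs = 10, d_value = d
  )
  scores <- dplyr::bind_rows(mk(10L, 0.7), mk(15L, 0.9), mk(50L, 0.8))
  out <- filter_windows(scores, ref, overlap = "greedy")
  expect_equal(out$window_start, c(15L, 50L))
  expect_equal(out$locus_id, c("CHM001", "CHM002"))
})

test_that("phased VCF round-trips into the scanner", {
  skip_if_not_installed("vcfR")
  tmp <- tempfile(fileext = ".vcf")
  gt <- rbind(
    c("0|0", "0|1", "1|1", "1|0"),
    c("0|1", "1|1", "0|0", "0|0"),
    c("0|0", "0|0", "0|1", "1|1")
  )
  write_toy_vcf(tmp, rep("chr1", 3), c(30L, 42L, 55L),
                c("A", "G", "T"), c("C", "A", "G"), gt)
  cohort <- read_phased_vcf(tmp)
  expect_s3_class(cohort, "msmix_phased")
  expect_equal(dim(cohort$hap_a), c(3L, 4L))
  expect_equal(cohort$hap_a[1, ], setNames(c("A", "A", "C", "C"),
                                           sprintf("S%02d", 1:4)))
  expect_equal(cohort$hap_b[1, ], setNames(c("A", "C", "C", "A"),
                                           sprintf("S%02d", 1:4)))
  scores <- scan_windows(cohort, window_size = 30)
  g <- tibble::tibble(
    hap1 = apply(cohort$hap_a, 2, paste, collapse = ""),
    hap2 = apply(cohort$hap_b, 2, paste, collapse = "")
  )
  full <- scores[scores$n_snps == 3, ]
  expect_true(all(full$d_value == compute_d_value(g)$d_value))
})

test_that("non-SNV records are skipped and unphased input errors", {
  skip_if_not_installed("vcfR")
  tmp <- tempfile(fileext = ".vcf")
  gt <- rbind(c("0|0", "0|1"), c("0|0", "1|1"), c("0|1", "0|0"))
  write_toy_vcf(tmp, rep("chr1", 3), c(10L, 20L, 30L),
                c("A", "AT", "G"), c("C", "A", "GTT"), gt)
  expect_message(cohort <- read_phased_vcf(tmp), "skipped")
  expect_equal(nrow(cohort$variants), 1L)

  tmp2 <- tempfile(fileext = ".vcf")
  write_toy_vcf(tmp2, "chr1", 10L, "A", "C", rbind(c("0/0", "0/1")))
  expect_error(read_phased_vcf(tmp2), "phased")
})

test_that("panel BED/TSV round-trip preserves the panel", {
  panel <- sim_panel(8, seed = 3)
  prefix <- tempfile()
  paths <- write_panel(panel, prefix)
  expect_true(file.exists(paths["bed"]))
  back <- read_panel(paths["tsv"])
  expect_equal(back$locus_id, panel$locus_id)
  expect_equal(back$snp_pos, panel$snp_pos)
  expect_equal(back$amplicon_start, panel$amplicon_start)
  bed <- read.table(paths["bed"], sep = "\t")
  expect_equal(bed$V2, panel$amplicon_start - 1L)  # 0-based half-open
  expect_equal(bed$V3, panel$amplicon_end)
})
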