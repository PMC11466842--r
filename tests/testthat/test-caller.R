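# Iterative binomial caller: exact tail, FDR rounds, templates.

test_that("binomial tail matches the pmf-summation oracle", {
  expect_equal(binomial_tail(0, 100, 0.01), 1)
  expect_equal(binomial_tail(3, 100, 0), 0)
  expect_equal(binomial_tail(5, 1000, 0.001), oracle_binom_tail(5, 1000, 0.001),
               tolerance = 1e-12)
  # Poisson sanity anchor for the worked case
  expect_equal(binomial_tail(5, 1000, 0.001), 3.66e-3, tolerance = 0.01)

  grid <- expand.grid(c = c(1, 2, 5, 20), n = c(50, 1000, 5000),
                      e = c(1e-6, 1e-4, 0.002, 0.05))
  for (i in seq_len(nrow(grid))) {
    got <- binomial_tail(grid$c[i], grid$n[i], grid$e[i])
    want <- oracle_binom_tail(grid$c[i], grid$n[i], grid$e[i])
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(binomial_tail(10, 5, 0.1), "c must")
  expect_error(binomial_tail(1, 5, 1.5), "e must")
})

test_that("tail probability is monotone decreasing in the candidate count", {
  p <- binomial_tail(1:50, 1000 + 1:50, 2e-4)
  expect_true(all(diff(p) < 0))
})

test_that("single-allele locus yields only the untested major", {
  ep <- toy_error_profile("L1", c(`1` = 0.001))
  calls <- call_alleles(prof("L1", A = 1000), ep)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$status, "major")
  expect_equal(calls$iteration, 0L)
  expect_true(is.na(calls$p_value))
})

test_that("a lone stray read is kept as artifact under the binomial test", {
  ep <- toy_error_profile("L1", c(`1` = 0.001, `2` = 1e-4, `3` = 1e-6))
  calls <- call_alleles(prof("L1", AAA = 990, AAT = 1), ep)
  aat <- calls[calls$allele == "AAT", ]
  expect_equal(aat$status, "artifact")
  expect_equal(aat$template, "AAA")
  expect_equal(aat$n, 1L)
  expect_equal(aat$p_value, oracle_binom_tail(1, 991, 0.001),
               tolerance = 1e-12)
  expect_gte(aat$q_value, 0.005)
})

test_that("the three-allele worked case follows the hand-executed trace", {
  ep <- toy_error_profile("L1", c(`1` = 0.002, `2` = 1e-4, `3` = 1e-6))
  p <- prof("L1", AAA = 950, TTG = 40, AAT = 10)
  calls <- call_alleles(p, ep, fdr = 0.005)

  # round 1 tests both candidates against the major AAA
  p_ttg <- oracle_binom_tail(40, 990, 1e-6)
  p_aat <- oracle_binom_tail(10, 960, 0.002)
  q_oracle <- p.adjust(c(p_ttg, p_aat), "BH")
  expect_equal(calls$status[calls$allele == "AAA"], "major")
  expect_equal(calls$p_value[calls$allele == "TTG"], p_ttg, tolerance = 1e-12)
  expect_equal(calls$p_value[calls$allele == "AAT"], p_aat, tolerance = 1e-10)
  expect_equal(sort(calls$q_value[calls$allele %in% c("TTG", "AAT")]),
               sort(q_oracle), tolerance = 1e-10)
  expect_equal(calls$status[calls$allele == "TTG"], "minor")
  expect_equal(calls$status[calls$allele == "AAT"], "minor")
  expect_equal(calls$n[calls$allele == "TTG"], 3L)
  expect_equal(calls$n[calls$allele == "AAT"], 1L)
  expect_true(all(calls$iteration[calls$allele != "AAA"] == 1L))
  expect_equal(sum(calls$count), 1000L)
})

test_that("later rounds retest against the nearest accepted template", {
  # ATT vs the huge major TTT (n = 1) is indistinguishable from noise in
  # round 1, but vs the accepted minor ATA (n = 1, template count 400) its
  # 30 reads are a wild excess: it must be accepted in round 2 with the
  # lexicographically smaller of the equidistant templates.
  ep <- toy_error_profile("L1", c(`1` = 2e-3, `2` = 2e-4, `3` = 1e-6))
  p <- prof("L1", TTT = 100000, ATA = 400, ATT = 30)
  calls <- call_alleles(p, ep, fdr = 0.005)
  att <- calls[calls$allele == "ATT", ]
  expect_equal(calls$status[calls$allele == "ATA"], "minor")
  expect_equal(calls$iteration[calls$allele == "ATA"], 1L)
  expect_equal(att$status, "minor")
  expect_equal(att$template, "ATA")
  expect_equal(att$n, 1L)
  expect_equal(att$iteration, 2L)
  expect_equal(att$p_value, oracle_binom_tail(30, 430, 2e-3),
               tolerance = 1e-10)
})

test_that("termination leaves remaining candidates as artifacts with audit fields", {
  ep <- toy_error_profile("L1", c(`1` = 0.01, `2` = 1e-3, `3` = 1e-4))
  p <- prof("L1", AAA = 1000, AAT = 8, ATT = 3)
  calls <- call_alleles(p, ep, fdr = 0.005)
  arts <- calls[calls$status == "artifact", ]
  expect_true(all(!is.na(arts$p_value)))
  expect_true(all(!is.na(arts$q_value)))
  expect_true(all(arts$q_value >= 0.005))
  expect_true(all(arts$template %in% calls$allele[calls$status != "artifact"]))
})

test_that("calls are invariant to the order of profile rows", {
  ep <- toy_error_profile("L1", c(`1` = 0.002, `2` = 1e-4, `3` = 1e-6))
  p <- prof("L1", AAA = 950, TTG = 40, AAT = 10, ATT = 2)
  set.seed(1)
  base <- call_alleles(p, ep)
  for (i in 1:5) {
    shuf <- p[sample(nrow(p)), ]
    expect_equal(call_alleles(shuf, ep), base)
  }
})

test_that("major-allele count ties break to the lexicographically smallest", {
  ep <- toy_error_profile("L1", c(`1` = 0.001))
  calls <- call_alleles(prof("L1", T = 500, A = 500), ep)
  expect_equal(calls$allele[calls$status == "major"], "A")
})

test_that("call_sample concatenates independent per-locus results", {
  ep <- dplyr::bind_rows(
    toy_error_profile("L1", c(`1` = 0.002, `2` = 1e-4)),
    toy_error_profile("L2", c(`1` = 0.002, `2` = 1e-4))
  )
  class(ep) <- c("msmix_error_profile", class(tibble::tibble()))
  attr(ep, "floor_rate") <- 1e-6
  p <- dplyr::bind_rows(prof("L1", AA = 900, AC = 100),
                        prof("L2", GG = 800, GT = 4))
  both <- call_sample(p, ep)
  solo <- dplyr::bind_rows(
    call_alleles(prof("L1", AA = 900, AC = 100), ep),
    call_alleles(prof("L2", GG = 800, GT = 4), ep)
  )
  expect_equal(tibble::as_tibble(both), tibble::as_tibble(solo))
  expect_equal(nrow(call_sample(p[0, ], ep)), 0L)
  expect_error(call_sample(prof("LX", AA = 10), ep), "absent")
})

test_that("sample-wide FDR pools each round's p-values across loci", {
  ep <- dplyr::bind_rows(
    toy_error_profile("L1", c(`1` = 0.002)),
    toy_error_profile("L2", c(`1` = 0.002))
  )
  class(ep) <- c("msmix_error_profile", class(tibble::tibble()))
  attr(ep, "floor_rate") <- 1e-6
  p <- dplyr::bind_rows(prof("L1", AA = 900, AC = 12),
                        prof("L2", GG = 900, GT = 5))
  pooled <- call_sample(p, ep, fdr_scope = "sample")
  p1 <- oracle_binom_tail(12, 912, 0.002)
  p2 <- oracle_binom_tail(5, 905, 0.002)
  q_pool <- p.adjust(c(p1, p2), "BH")
  got <- pooled$q_value[match(c("AC", "GT"), pooled$allele)]
  expect_equal(got, q_pool, tolerance = 1e-10)
})

test_that("accepted set grows monotonically and acceptance is monotone in count", {
  ep <- toy_error_profile("L1", c(`1` = 0.002, `2` = 1e-4, `3` = 1e-6))
  # same locus, increasing minor count: once accepted, stays accepted
  accepted <- vapply(c(2, 5, 10, 30, 100), function(cc) {
    calls <- call_alleles(prof("L1", AAA = 1000, ATT = cc), ep)
    calls$status[calls$allele == "ATT"] == "minor"
  }, logical(1))
  expect_true(all(diff(as.integer(accepted)) >= 0))
  # iteration indices are contiguous from 1 among accepted minors
  p <- prof("L1", AAA = 5000, CCA = 400, CCC = 30, TTT = 25)
  calls <- call_alleles(p, ep)
  iters <- sort(unique(calls$iteration[calls$status == "minor"]))
  expect_equal(iters, seq_along(iters))
})

test_that("an unseen mismatch count falls back to the floor rate with a warning", {
  ep <- toy_error_profile("L1", c(`1` = 0.002))  # no n=2 entry
  expect_warning(
    calls <- call_alleles(prof("L1", AAA = 1000, ATT = 50), ep),
    "floor"
  )
  att <- calls[calls$allele == "ATT", ]
  expect_equal(att$p_value, oracle_binom_tail(50, 1050, 1e-6),
               tolerance = 1e-10)
})

test_that("FDR is controlled under read-independent errors with a correct profile", {
  # sequencing-only errors and the analytically correct class-level error
  # rates: the per-read binomial null is exactly specified, so
  # accepted-but-false minors must be rare. (Profiles *estimated* from finite
  # cohorts under-cover rare classes via the floor rate, and molecule-level
  # PCR errors violate read independence; both effects are documented.)
  e <- 0.003
  panel <- sim_panel(150, seed = 201)
  pop <- sim_population(panel, 20, seed = 202)
  ids <- sprintf("I%03d", 1:20)
  profiles <- sim_cohort_profiles(panel, pop, ids, mean_depth = 1150,
                                  seq_error = e, pcr_error = 0,
                                  seed = 203)
  # analytic rate of concordant distance-n artifacts among concordant pairs
  ep <- panel %>%
    dplyr::mutate(n = lapply(n_snps, seq_len)) %>%
    dplyr::select(locus_id, s = n_snps, n) %>%
    tidyr::unnest(n) %>%
    dplyr::mutate(
      e_rate = choose(s, n) * (e^2 / 3)^n * ((1 - e)^2)^(s - n) /
        (((1 - e)^2 + e^2 / 3)^s),
      n_samples = 0L, usable = TRUE
    ) %>%
    dplyr::select(locus_id, n, e_rate, n_samples, usable)
  class(ep) <- c("msmix_error_profile", class(tibble::tibble()))
  attr(ep, "floor_rate") <- 1e-6
  n_false <- 0L
  n_acc <- 0L
  for (id in ids) {
    p <- dplyr::filter(profiles, sample_id == id)
    calls <- call_sample(dplyr::select(p, -sample_id), ep)
    truth <- contributor_truth(pop, id)
    minors <- dplyr::filter(calls, status == "minor")
    n_acc <- n_acc + nrow(minors)
    n_false <- n_false + sum(!paste(minors$locus_id, minors$allele) %in%
                               paste(truth$locus_id, truth$allele))
  }
  expect_gt(n_acc, 500)
  # <= 0.5% plus 3-sigma binomial Monte-Carlo slack
  expect_lte(n_false / n_acc, 0.005 + 3 * sqrt(0.005 * 0.995 / n_acc))
})
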