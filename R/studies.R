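# End-to-end simulation studies: minor-allele distinguishability and
# empirical FDR control of the caller.

#' Minor-allele distinguishability study on simulated mixtures
#'
#' Simulates the full workflow under the mixture-study conditions: a
#' 567-locus panel and population; a locus-specific error profile estimated
#' from `n_ref` simulated single-source samples; then 2-, 3- and 4-person
#' mixtures with the minor contributor at `minor_fraction` of the template
#' mass (the remaining mass split equally among the other contributors),
#' sequenced at `mean_depth` pairs per locus with the two-layer error model,
#' and called at `fdr`. Reports the pooled fraction of minor-unique alleles
#' the caller recovered across all mixtures.
#'
#' @param seed RNG seed for the whole study.
#' @param n_loci Panel size (default 567).
#' @param n_ref Single-source samples behind the error profile (default 100).
#' @param ks Contributor counts of the mixtures (default 2:4).
#' @param reps_per_k Mixtures simulated per contributor count (default 4,
#'   i.e. 12 mixtures pooled).
#' @param minor_fraction Minor contributor's mass fraction (default 0.005).
#' @param total_ng Total input mass in ng (default 1).
#' @param mean_depth,seq_error,pcr_error,haploid_ng Passed to [sim_reads()].
#' @param fdr Caller FDR threshold (default 0.005).
#' @param dirichlet Haplotype-frequency concentration (default 0.25).
#' @return A list: `percent` (pooled minor-unique detection, percent),
#'   `n_unique`, `n_called`, `per_mixture` (one row per mixture).
#' @export
run_minor_detection_study <- function(seed, n_loci = 567, n_ref = 100,
                                      ks = 2:4, reps_per_k = 4,
                                      minor_fraction = 0.005, total_ng = 1,
                                      mean_depth = 1150, seq_error = 0.001,
                                      pcr_error = 1e-4, haploid_ng = 0.0033,
                                      fdr = 0.005, dirichlet = 0.25) {
  set.seed(seed)
  n_pool <- max(ks) * reps_per_k
  panel <- sim_panel(n_loci, dirichlet = dirichlet)
  population <- sim_population(panel, n_ref + n_pool)
  ids <- sprintf("I%03d", seq_len(n_ref + n_pool))
  ref_ids <- ids[seq_len(n_ref)]
  pool_ids <- ids[-seq_len(n_ref)]

  ref_profiles <- sim_cohort_profiles(
    panel, population, ref_ids, total_ng = total_ng, mean_depth = mean_depth,
    seq_error = seq_error, pcr_error = pcr_error, haploid_ng = haploid_ng
  )
  errprof <- estimate_error_profile(ref_profiles, panel = panel)

  per_mix <- list()
  next_id <- 1L
  for (k in ks) {
    for (r in seq_len(reps_per_k)) {
      if (next_id + k - 1L > length(pool_ids)) next_id <- 1L
      contribs <- pool_ids[next_id:(next_id + k - 1L)]
      next_id <- next_id + k
      minor <- contribs[k]
      fr <- setNames(c(rep((1 - minor_fraction) / (k - 1), k - 1),
                       minor_fraction), contribs)
      sim <- sim_reads(panel, population, fr, total_ng = total_ng,
                       mean_depth = mean_depth, seq_error = seq_error,
                       pcr_error = pcr_error, haploid_ng = haploid_ng)
      calls <- call_sample(sim$profile, errprof, fdr = fdr)
      md <- minor_distinguishability(calls, sim$truth$alleles, minor)
      per_mix[[length(per_mix) + 1L]] <- mutate(
        md, n_contributors = k, replicate = r)
    }
  }
  per_mix <- bind_rows(per_mix)
  n_unique <- sum(per_mix$n_unique)
  n_called <- sum(per_mix$n_called)
  list(
    percent = 100 * n_called / n_unique,
    n_unique = n_unique, n_called = n_called,
    per_mixture = per_mix
  )
}

#' Empirical false-discovery study of the caller on single-source samples
#'
#' Simulates `n_samples` single-source samples under the standard error
#' model, estimates the error profile on the first half, and runs the caller
#' on the second half. In a single-source sample the individual's two
#' haplotypes are the only true alleles, so every accepted minor allele
#' outside them is a false discovery. Reports the pooled empirical
#' false-discovery proportion among accepted minor alleles.
#'
#' @inheritParams run_minor_detection_study
#' @param n_samples Total single-source samples (default 200; half train the
#'   error profile, half are called).
#' @return A list: `percent` (pooled FDP among accepted minors, percent),
#'   `n_accepted`, `n_false`, `per_sample` tibble.
#' @export
run_fdr_study <- function(seed, n_samples = 200, n_loci = 567, total_ng = 1,
                          mean_depth = 1150, seq_error = 0.001,
                          pcr_error = 1e-4, haploid_ng = 0.0033, fdr = 0.005,
                          dirichlet = 0.25) {
  set.seed(seed)
  panel <- sim_panel(n_loci, dirichlet = dirichlet)
  population <- sim_population(panel, n_samples)
  ids <- sprintf("I%03d", seq_len(n_samples))
  half <- floor(n_samples / 2)
  train_ids <- ids[seq_len(half)]
  test_ids <- ids[(half + 1):n_samples]

  train_profiles <- sim_cohort_profiles(
    panel, population, train_ids, total_ng = total_ng,
    mean_depth = mean_depth, seq_error = seq_error, pcr_error = pcr_error,
    haploid_ng = haploid_ng
  )
  errprof <- estimate_error_profile(train_profiles, panel = panel)

  per_sample <- vector("list", length(test_ids))
  for (i in seq_along(test_ids)) {
    id <- test_ids[i]
    sim <- sim_reads(panel, population, setNames(1, id),
                     total_ng = total_ng, mean_depth = mean_depth,
                     seq_error = seq_error, pcr_error = pcr_error,
                     haploid_ng = haploid_ng)
    calls <- call_sample(sim$profile, errprof, fdr = fdr)
    truth <- sim$truth$alleles
    minors <- calls %>%
      filter(.data$status == "minor") %>%
      mutate(false_call = !paste(.data$locus_id, .data$allele) %in%
               paste(truth$locus_id, truth$allele))
    per_sample[[i]] <- tibble(
      sample_id = id,
      n_accepted = nrow(minors),
      n_false = sum(minors$false_call)
    )
  }
  per_sample <- bind_rows(per_sample)
  n_acc <- sum(per_sample$n_accepted)
  n_false <- sum(per_sample$n_false)
  list(
    percent = 100 * n_false / max(n_acc, 1L),
    n_accepted = n_acc, n_false = n_false,
    per_sample = per_sample
  )
}
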