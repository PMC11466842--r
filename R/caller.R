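# Iterative binomial allele caller with FDR control.

#' Exact binomial upper tail P(X >= c)
#'
#' Probability that a Binomial(`n_total`, `e`) count reaches at least `c`.
#' This is the caller's null tail: if a candidate allele were pure artifact
#' of its template at error rate `e`, its read count among the
#' template+candidate reads would be binomial, and a very small tail
#' probability rejects the artifact hypothesis.
#'
#' @param c Observed candidate count(s).
#' @param n_total Total template + candidate counts.
#' @param e Error rate(s) in `[0, 1]`.
#' @return `P(X >= c)`, vectorised.
#' @examples
#' binomial_tail(5, 1000, 0.001)
#' @export
binomial_tail <- function(c, n_total, e) {
  if (any(c < 0) || any(c > n_total)) {
    abort("binomial_tail(): c must satisfy 0 <= c <= n_total")
  }
  if (any(e < 0) || any(e > 1)) {
    abort("binomial_tail(): e must lie in [0, 1]")
  }
  pbinom(c - 1, n_total, e, lower.tail = FALSE)
}

# Per-locus error-rate lookup: named vector n -> e, with floor fallback.
error_lookup <- function(error_profile, floor_rate) {
  split(
    setNames(error_profile$e_rate, error_profile$n),
    error_profile$locus_id
  )
}

# Core iterative caller on bare vectors. `e_vec` is the locus's n -> e map
# (named numeric); missing n fall back to floor_rate (with one warning when
# warn_missing). Returns the calls data frame columns as a list.
call_alleles_core <- function(alleles, counts, e_vec, fdr, floor_rate,
                              warn_missing = TRUE) {
  ord <- order(-counts, alleles)
  alleles <- alleles[ord]
  counts <- counts[ord]
  k <- length(alleles)
  status <- rep("artifact", k)
  template <- rep(NA_character_, k)
  n_dist <- rep(NA_integer_, k)
  p_val <- rep(NA_real_, k)
  q_val <- rep(NA_real_, k)
  iter <- rep(NA_integer_, k)
  status[1] <- "major"
  iter[1] <- 0L
  if (k == 1L) {
    return(list(allele = alleles, count = counts, status = status,
                template = template, n = n_dist, p_value = p_val,
                q_value = q_val, iteration = iter))
  }
  accepted <- 1L
  remaining <- 2:k
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    nt <- nearest_template(alleles[remaining], alleles[accepted])
    n_r <- nt$n
    tpl <- nt$template
    e_r <- unname(e_vec[as.character(n_r)])
    if (anyNA(e_r)) {
      if (warn_missing) {
        warn(paste0("call_alleles(): no e_l(n) entry for n = ",
                    paste(unique(n_r[is.na(e_r)]), collapse = ","),
                    "; using floor rate ", floor_rate))
      }
      e_r[is.na(e_r)] <- floor_rate
    }
    tpl_count <- counts[match(tpl, alleles)]
    p_r <- binomial_tail(counts[remaining], tpl_count + counts[remaining], e_r)
    q_r <- p.adjust(p_r, method = "BH")
    template[remaining] <- tpl
    n_dist[remaining] <- n_r
    p_val[remaining] <- p_r
    q_val[remaining] <- q_r
    iter[remaining] <- round_i
    ok <- q_r < fdr
    if (!any(ok)) break
    newly <- remaining[ok]
    status[newly] <- "minor"
    accepted <- c(accepted, newly)
    remaining <- remaining[!ok]
    if (length(remaining) == 0L) break
  }
  list(allele = alleles, count = counts, status = status, template = template,
       n = n_dist, p_value = p_val, q_value = q_val, iteration = iter)
}

#' Call true alleles at one locus
#'
#' Implements the iterative artifact test. Round 1: the best-supported allele
#' is the major allele (count ties broken towards the lexicographically
#' smallest string); every remaining candidate with count `c` at Hamming
#' distance `n` from the major is tested with
#' `binomial_tail(c, count_major + c, e_l(n))`, the round's p-values are
#' Benjamini-Hochberg corrected together, and candidates with `q < fdr`
#' become true minor alleles. Later rounds retest the remaining candidates
#' against their most similar true allele (minimum Hamming distance,
#' lexicographic tie-break) with `N = count_template + c`. The procedure
#' stops when a round accepts nothing; unaccepted candidates are artifacts.
#'
#' @param profile Profile tibble for one locus (`locus_id`, `allele`,
#'   `count`); every allele string must have the locus's length.
#' @param error_profile `msmix_error_profile` from
#'   [estimate_error_profile()]; must contain the locus.
#' @param fdr FDR threshold for accepting minors (default 0.005, i.e. 0.5%).
#' @return An `msmix_calls` tibble: `locus_id`, `allele`, `count`, `status`
#'   (`major`/`minor`/`artifact`), `template`, `n`, `p_value`, `q_value`,
#'   `iteration` (0 for the major; for others, the round in which the allele
#'   was accepted or last tested).
#' @export
call_alleles <- function(profile, error_profile, fdr = 0.005) {
  stopifnot(nrow(profile) > 0L)
  lid <- unique(profile$locus_id)
  if (length(lid) != 1L) {
    abort("call_alleles(): profile must cover exactly one locus")
  }
  floor_rate <- attr(error_profile, "floor_rate") %||% 1e-6
  ep <- error_profile[error_profile$locus_id == lid, , drop = FALSE]
  if (nrow(ep) == 0L) {
    abort(paste0("call_alleles(): locus ", lid, " absent from error profile"))
  }
  e_vec <- setNames(ep$e_rate, ep$n)
  res <- call_alleles_core(profile$allele, profile$count, e_vec, fdr,
                           floor_rate)
  msmix_tbl(tibble(locus_id = lid, !!!res), "msmix_calls")
}

#' Call every locus of a sample
#'
#' Applies [call_alleles()] to each locus of a per-sample profile. With
#' `fdr_scope = "locus"` (default) each locus's rounds are corrected
#' independently; with `"sample"` the rounds run synchronised across loci and
#' each round's p-values are pooled into one Benjamini-Hochberg correction.
#'
#' @param profiles Profile tibble over loci (`locus_id`, `allele`, `count`).
#' @inheritParams call_alleles
#' @param fdr_scope `"locus"` or `"sample"` (see Details).
#' @return An `msmix_calls` tibble over all loci.
#' @export
call_sample <- function(profiles, error_profile, fdr = 0.005,
                        fdr_scope = c("locus", "sample")) {
  fdr_scope <- match.arg(fdr_scope)
  if (nrow(profiles) == 0L) {
    return(msmix_tbl(tibble(locus_id = character(), allele = character(),
                            count = integer(), status = character(),
                            template = character(), n = integer(),
                            p_value = numeric(), q_value = numeric(),
                            iteration = integer()), "msmix_calls"))
  }
  floor_rate <- attr(error_profile, "floor_rate") %||% 1e-6
  missing <- setdiff(unique(profiles$locus_id),
                     unique(error_profile$locus_id))
  if (length(missing) > 0L) {
    abort(paste0("call_sample(): loci absent from error profile: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  e_map <- split(setNames(error_profile$e_rate, error_profile$n),
                 error_profile$locus_id)
  ord <- order(profiles$locus_id, -profiles$count, profiles$allele)
  lid <- profiles$locus_id[ord]
  al <- profiles$allele[ord]
  ct <- profiles$count[ord]
  bounds <- c(which(c(TRUE, lid[-1L] != lid[-length(lid)])), length(lid) + 1L)
  n_loci <- length(bounds) - 1L

  if (fdr_scope == "locus") {
    res <- vector("list", n_loci)
    for (g in seq_len(n_loci)) {
      i <- bounds[g]:(bounds[g + 1L] - 1L)
      core <- call_alleles_core(al[i], ct[i], e_map[[lid[i[1]]]], fdr,
                                floor_rate, warn_missing = FALSE)
      res[[g]] <- tibble(locus_id = lid[i[1]], !!!core)
    }
    return(msmix_tbl(bind_rows(res), "msmix_calls"))
  }

  # sample-wide FDR: synchronised rounds, pooled BH per round
  states <- vector("list", n_loci)
  for (g in seq_len(n_loci)) {
    i <- bounds[g]:(bounds[g + 1L] - 1L)
    k <- length(i)
    states[[g]] <- list(
      locus_id = lid[i[1]], allele = al[i], count = ct[i],
      status = c("major", rep("artifact", k - 1L)),
      template = rep(NA_character_, k), n = rep(NA_integer_, k),
      p = rep(NA_real_, k), q = rep(NA_real_, k),
      iter = c(0L, rep(NA_integer_, k - 1L)),
      accepted = 1L, remaining = if (k > 1L) 2:k else integer()
    )
  }
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    idx <- list(); pvals <- list()
    for (g in seq_len(n_loci)) {
      s <- states[[g]]
      if (length(s$remaining) == 0L) next
      nt <- nearest_template(s$allele[s$remaining], s$allele[s$accepted])
      e_vec <- e_map[[s$locus_id]]
      e_r <- unname(e_vec[as.character(nt$n)])
      e_r[is.na(e_r)] <- floor_rate
      tpl_count <- s$count[match(nt$template, s$allele)]
      p_r <- binomial_tail(s$count[s$remaining],
                           tpl_count + s$count[s$remaining], e_r)
      s$template[s$remaining] <- nt$template
      s$n[s$remaining] <- nt$n
      s$p[s$remaining] <- p_r
      s$iter[s$remaining] <- round_i
      states[[g]] <- s
      idx[[length(idx) + 1L]] <- cbind(g, s$remaining)
      pvals[[length(pvals) + 1L]] <- p_r
    }
    if (length(pvals) == 0L) break
    p_all <- unlist(pvals)
    q_all <- p.adjust(p_all, method = "BH")
    pos <- do.call(rbind, idx)
    any_new <- FALSE
    for (r in seq_along(p_all)) {
      g <- pos[r, 1L]; i <- pos[r, 2L]
      states[[g]]$q[i] <- q_all[r]
    }
    for (g in unique(pos[, 1L])) {
      s <- states[[g]]
      ok <- s$remaining[!is.na(s$q[s$remaining]) &
                          s$q[s$remaining] < fdr &
                          s$iter[s$remaining] == round_i]
      if (length(ok) > 0L) {
        any_new <- TRUE
        s$status[ok] <- "minor"
        s$accepted <- c(s$accepted, ok)
        s$remaining <- setdiff(s$remaining, ok)
        states[[g]] <- s
      }
    }
    if (!any_new) break
  }
  res <- lapply(states, function(s) {
    tibble(locus_id = s$locus_id, allele = s$allele, count = s$count,
           status = s$status, template = s$template, n = s$n,
           p_value = s$p, q_value = s$q, iteration = s$iter)
  })
  msmix_tbl(bind_rows(res), "msmix_calls")
}

#' Accepted (true) alleles of a call set
#'
#' @param calls An `msmix_calls` tibble.
#' @return Tibble of `locus_id`, `allele`, `status` for major + minor calls.
#' @export
true_alleles <- function(calls) {
  calls %>%
    filter(.data$status %in% c("major", "minor")) %>%
    select("locus_id", "allele", "status")
}
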