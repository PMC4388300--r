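# Bootstrap and permutation inference on divergent vs background windows,
# plus the chromosome clustering and enrichment tests.

#' Bootstrap comparison of a statistic between two window groups
#'
#' Resamples each group with replacement `n_boot` times. Group confidence
#' intervals are the 2.5 and 97.5 percentiles of the bootstrap means. The
#' two-sided p-value counts bootstrap mean-difference replicates whose
#' deviation from the observed difference is at least as large as the
#' observed difference itself (i.e. recentred replicates crossing zero),
#' with a +1 correction in numerator and denominator so p is never 0.
#'
#' @param values_in Statistic values for the focal group (e.g. divergent
#'   windows); NAs dropped with counts reported.
#' @param values_out Values for the comparison group (background windows).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; the operation is bit-reproducible given
#'   (seed, n_boot).
#' @param statistic Optional name carried into the result.
#' @return A tibble of class `divscan_boot` with one row: means, CIs,
#'   `p_raw`, `n_boot`, `seed`, dropped-NA counts.
#' @export
bootstrap_compare <- function(values_in, values_out, n_boot = 10000, seed = 1,
                              statistic = NA_character_) {
  xin <- values_in[!is.na(values_in)]
  xout <- values_out[!is.na(values_out)]
  if (length(xin) == 0 || length(xout) == 0) {
    fatal("a group is empty (or entirely missing) for this statistic",
          class = "divscan_data_error")
  }
  res <- with_seed(derive_seed(seed, paste0("bootstrap_compare:", statistic)), {
    bm_in <- boot_means(xin, n_boot)
    bm_out <- boot_means(xout, n_boot)
    list(bm_in = bm_in, bm_out = bm_out)
  })
  d_obs <- mean(xin) - mean(xout)
  d_boot <- res$bm_in - res$bm_out
  p <- (1 + sum(abs(d_boot - d_obs) >= abs(d_obs))) / (n_boot + 1)
  p <- min(p, 1)
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  ci_in <- ci(res$bm_in); ci_out <- ci(res$bm_out)
  structure(tibble::tibble(
    statistic = statistic,
    mean_in = mean(xin), ci_low_in = ci_in[1], ci_high_in = ci_in[2],
    mean_out = mean(xout), ci_low_out = ci_out[1], ci_high_out = ci_out[2],
    diff = d_obs, p_raw = p,
    n_in = length(xin), n_out = length(xout),
    n_dropped_in = sum(is.na(values_in)), n_dropped_out = sum(is.na(values_out)),
    n_boot = n_boot, seed = seed
  ), class = c("divscan_boot", "tbl_df", "tbl", "data.frame"))
}

# means of `n_boot` with-replacement resamples, vectorised in blocks to
# bound memory at ~8e6 doubles
boot_means <- function(x, n_boot) {
  n <- length(x)
  block <- max(1L, min(n_boot, as.integer(8e6 / n)))
  out <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    b <- min(block, n_boot - done)
    m <- matrix(x[sample.int(n, n * b, replace = TRUE)], nrow = b)
    out[(done + 1):(done + b)] <- rowMeans(m)
    done <- done + b
  }
  out
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate control; monotone in rank and capped at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    fatal("p-values must lie in [0, 1]", class = "divscan_config_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Permutation test excluding named loci
#'
#' Drops windows overlapping the exclusion set (e.g. known mimicry loci),
#' then tests whether the statistic differs between divergent and
#' background windows by permuting the divergent labels: observed value is
#' the difference of group means, p = (1 + #{|null| >= |obs|}) /
#' (n_perm + 1).
#'
#' @param stats Window tibble with columns `scaffold`, `start`, `end` and
#'   the statistic column.
#' @param divergent Logical per window.
#' @param exclude Interval tibble (`scaffold`, `start`, `end`) of loci to
#'   exclude; `NULL` for none.
#' @param statistic Name of the statistic column in `stats`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A list: `observed`, `p`, `n_used`, `n_excluded`, `n_perm`,
#'   `seed`.
#' @export
permutation_excluding <- function(stats, divergent, exclude = NULL,
                                  statistic, n_perm = 1000, seed = 1) {
  x <- stats[[statistic]]
  if (is.null(x)) fatal(paste0("no column '", statistic, "' in stats"),
                        class = "divscan_config_error")
  keep <- rep(TRUE, nrow(stats))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (k in seq_len(nrow(exclude))) {
      hit <- stats$scaffold == exclude$scaffold[k] &
        stats$start < exclude$end[k] & exclude$start[k] < stats$end
      keep[hit] <- FALSE
    }
  }
  ok <- keep & !is.na(x)
  lab <- divergent[ok]
  v <- x[ok]
  if (!any(lab) || all(lab)) {
    fatal("both divergent and background windows must remain after exclusion",
          class = "divscan_data_error")
  }
  obs <- mean(v[lab]) - mean(v[!lab])
  null <- with_seed(derive_seed(seed, paste0("permutation_excluding:", statistic)), {
    k <- sum(lab)
    vapply(seq_len(n_perm), function(i) {
      pl <- sample.int(length(v), k)
      mean(v[pl]) - mean(v[-pl])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p = p, n_used = sum(ok), n_excluded = sum(!keep),
       n_perm = n_perm, seed = seed)
}

# signed-rank sum over paired differences; zero differences drop out
signed_rank_stat <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0) return(0)
  r <- rank(abs(d))
  sum(sign(d) * r)
}

#' Monte-Carlo paired Wilcoxon test for chromosome clustering of regions
#'
#' Tests whether divergent-region counts per chromosome deviate from the
#' counts expected if regions were placed proportionally to chromosome
#' length. The observed statistic is the Wilcoxon signed-rank sum between
#' observed and expected per-chromosome counts; its null distribution is
#' simulated by placing the same number of regions uniformly at random
#' with probability proportional to chromosome length. `Z` is the observed
#' statistic standardised against the simulated null; p is the two-sided
#' Monte-Carlo tail probability.
#'
#' @param region_chroms Character vector: chromosome of each region.
#' @param chrom_lengths Tibble/data frame with `name`, `length` covering
#'   every chromosome (including ones with zero regions).
#' @param n_sim Number of simulated placements (default 10000).
#' @param seed Integer seed.
#' @return A list of class `divscan_clustering`: `observed` (counts),
#'   `expected`, `statistic`, `Z`, `p`, `n_sim`, `seed`.
#' @export
chromosome_clustering <- function(region_chroms, chrom_lengths,
                                  n_sim = 10000, seed = 1) {
  cl <- tibble::as_tibble(chrom_lengths)
  if (any(cl$length <= 0)) fatal("chromosome lengths must be positive",
                                 class = "divscan_config_error")
  bad <- setdiff(unique(region_chroms), cl$name)
  if (length(bad) > 0) {
    fatal(paste0("region(s) on unknown chromosome(s): ", paste(bad, collapse = ", ")),
          class = "divscan_data_error")
  }
  if (nrow(cl) < 5) warn("fewer than 5 chromosomes: clustering test is underpowered")
  n_regions <- length(region_chroms)
  obs <- as.numeric(table(factor(region_chroms, levels = cl$name)))
  prob <- cl$length / sum(cl$length)
  expected <- n_regions * prob
  s_obs <- signed_rank_stat(obs - expected)
  s_null <- with_seed(derive_seed(seed, "chromosome_clustering"), {
    sims <- stats::rmultinom(n_sim, n_regions, prob)
    apply(sims, 2, function(cnt) signed_rank_stat(cnt - expected))
  })
  mu <- mean(s_null); sdev <- stats::sd(s_null)
  z <- if (sdev > 0) (s_obs - mu) / sdev else 0
  p <- (1 + sum(abs(s_null - mu) >= abs(s_obs - mu))) / (n_sim + 1)
  structure(list(observed = stats::setNames(obs, cl$name),
                 expected = stats::setNames(expected, cl$name),
                 statistic = s_obs, Z = z, p = min(p, 1),
                 n_sim = n_sim, seed = seed),
            class = "divscan_clustering")
}

#' @export
print.divscan_clustering <- function(x, ...) {
  cat(sprintf("<chromosome clustering> %d regions on %d chromosomes: Z = %.3f, p = %.4g (n_sim = %d)\n",
              sum(x$observed), length(x$observed), x$Z, x$p, x$n_sim))
  invisible(x)
}

#' Enrichment of divergent sequence on focal chromosomes
#'
#' Fisher's exact test on the 2x2 table of (divergent bp, non-divergent
#' bp) x (focal chromosomes, other chromosomes), with bp rescaled to
#' integer kilobase units so the normalization by chromosome length is
#' exact. A count-based variant (regions rather than bp) is available via
#' `unit = "regions"`.
#'
#' @param divergent_bp Named numeric: divergent bp per chromosome.
#' @param chrom_lengths Tibble with `name`, `length` for all chromosomes.
#' @param focal_chroms Chromosomes carrying the loci of interest (e.g.
#'   color-pattern chromosomes).
#' @param unit `"bp"` (default; table in kb units) or `"regions"` (counts
#'   of regions vs windows outside them; supply counts in `divergent_bp`).
#' @return A list: `odds_ratio`, `p`, `table`, `flagged` (TRUE when a
#'   margin is zero and the OR is undefined).
#' @export
colorpattern_enrichment <- function(divergent_bp, chrom_lengths, focal_chroms,
                                    unit = c("bp", "regions")) {
  unit <- match.arg(unit)
  cl <- tibble::as_tibble(chrom_lengths)
  bad <- setdiff(focal_chroms, cl$name)
  if (length(bad) > 0) fatal(paste0("unknown focal chromosome(s): ",
                                    paste(bad, collapse = ", ")),
                             class = "divscan_config_error")
  div <- stats::setNames(rep(0, nrow(cl)), cl$name)
  div[names(divergent_bp)] <- divergent_bp
  focal <- cl$name %in% focal_chroms
  scale <- if (unit == "bp") 1000 else 1
  d_f <- round(sum(div[focal]) / scale)
  d_n <- round(sum(div[!focal]) / scale)
  t_f <- round(sum(cl$length[focal]) / scale)
  t_n <- round(sum(cl$length[!focal]) / scale)
  tab <- matrix(c(d_f, t_f - d_f, d_n, t_n - d_n), nrow = 2,
                dimnames = list(c("divergent", "background"),
                                c("focal", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, table = tab, flagged = TRUE))
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab,
       flagged = FALSE)
}
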