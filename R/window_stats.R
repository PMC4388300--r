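# Per-window population-genetic statistics.
#
# All windowed estimators share the same calling convention: an
# `allele_counts` object, the site-to-window assignment vector from
# assign_sites(), and the window tibble; they return one row per window.
# Undefined values propagate as NA, never as 0 (except where a statistic
# is 0 by convention on SNP-free windows, noted per function).

# per-site allele frequencies and called-allele totals for one population
site_freq <- function(counts, pop) {
  n <- counts$called[, pop]
  p <- ifelse(n > 0, counts$alt[, pop] / n, NA_real_)
  list(p = p, n = n)
}

#' Windowed AMOVA-style F_ST between two populations
#'
#' Two-level (among/within population) variance-component estimator in the
#' Weir-Cockerham form, computed from allele frequencies and per-site
#' called-allele counts, with component sums taken over sites before the
#' ratio ("ratio of sums"). Sites need at least 2 called alleles in each
#' population to contribute. Negative estimates are kept; a window with no
#' usable site, or a non-positive denominator, is `NA`.
#'
#' @param counts An `allele_counts` object.
#' @param pop_a,pop_b Population labels.
#' @param win Integer window id per site (from [assign_sites()]).
#' @param windows Window tibble (from [make_windows()]).
#' @return Tibble with columns `window_id`, `fst`.
#' @export
window_fst <- function(counts, pop_a, pop_b, win, windows) {
  comp <- fst_site_components(counts, pop_a, pop_b)
  ok <- !is.na(comp$a)
  num <- rowsum_by(comp$a[ok], win[ok], windows$window_id)
  den <- rowsum_by((comp$a + comp$b)[ok], win[ok], windows$window_id)
  fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  tibble::tibble(window_id = windows$window_id, fst = fst)
}

# Weir-Cockerham two-level components per site (a: among-pop, b: within-pop)
fst_site_components <- function(counts, pop_a, pop_b) {
  fa <- site_freq(counts, pop_a)
  fb <- site_freq(counts, pop_b)
  n1 <- fa$n; n2 <- fb$n
  p1 <- fa$p; p2 <- fb$p
  usable <- n1 >= 2 & n2 >= 2
  ntot <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / ntot
  nc <- ntot - (n1^2 + n2^2) / ntot            # r - 1 = 1
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - 2)
  a <- ifelse(usable, (msp - msg) / nc, NA_real_)
  b <- ifelse(usable, msg, NA_real_)
  list(a = a, b = b, usable = usable)
}

# sum values by window id over the full window universe (absent -> NA)
rowsum_by <- function(x, group, universe, absent = NA_real_) {
  if (length(x) == 0) return(rep(absent, length(universe)))
  rs <- rowsum(x, group)
  out <- rep(absent, length(universe))
  out[match(as.integer(rownames(rs)), universe)] <- rs[, 1]
  out
}

# count TRUEs by window id over the full window universe (absent -> 0)
count_by <- function(flag, group, universe) {
  out <- rowsum_by(as.numeric(flag), group, universe, absent = 0)
  out
}

#' Windowed nucleotide diversity and segregating-site density
#'
#' Unbiased per-site heterozygosity `2 p (1-p) n / (n-1)` summed over SNPs
#' and divided by the window length in bp; segregating-site density is the
#' number of sites polymorphic in the population divided by window length.
#' SNP-free windows are 0 for both (SNP-only convention).
#'
#' @inheritParams window_fst
#' @param pop Population label.
#' @return Tibble with columns `window_id`, `pi`, `s_density`.
#' @export
window_pi <- function(counts, pop, win, windows) {
  f <- site_freq(counts, pop)
  ok <- f$n >= 2
  h <- 2 * f$p * (1 - f$p) * f$n / (f$n - 1)
  pi_sum <- rowsum_by(h[ok], win[ok], windows$window_id, absent = 0)
  seg <- f$n > 0 & counts$alt[, pop] > 0 & counts$alt[, pop] < counts$called[, pop]
  s <- count_by(seg, win, windows$window_id)
  tibble::tibble(window_id = windows$window_id,
                 pi = pi_sum / windows$length,
                 s_density = s / windows$length)
}

#' Windowed absolute sequence divergence d_XY
#'
#' Mean pairwise between-population difference per bp:
#' sum over SNPs of `pA (1-pB) + pB (1-pA)`, divided by window length.
#' SNP-free windows are 0 (SNP-only convention). Multiply by `length` and
#' sum across windows for the genome-aggregate substitution count.
#'
#' @inheritParams window_fst
#' @return Tibble with columns `window_id`, `dxy`.
#' @export
window_dxy <- function(counts, pop_a, pop_b, win, windows) {
  fa <- site_freq(counts, pop_a)
  fb <- site_freq(counts, pop_b)
  term <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  ok <- !is.na(term)
  dsum <- rowsum_by(term[ok], win[ok], windows$window_id, absent = 0)
  tibble::tibble(window_id = windows$window_id, dxy = dsum / windows$length)
}

#' Tajima's D per window
#'
#' Standard normalized difference between the pairwise-diversity and
#' Watterson estimators of theta, using the published constants
#' (a1, a2, b1, b2, c1, c2, e1, e2) for sample size `n` chromosomes.
#' Requires at least one segregating site and n >= 4; otherwise `NA`.
#' With missing genotypes, `n` is taken as the maximum called-allele count
#' across the window's sites.
#'
#' @inheritParams window_pi
#' @return Tibble with columns `window_id`, `tajimas_d`.
#' @export
window_tajimas_d <- function(counts, pop, win, windows) {
  f <- site_freq(counts, pop)
  seg <- f$n >= 2 & counts$alt[, pop] > 0 & counts$alt[, pop] < counts$called[, pop]
  h <- 2 * f$p * (1 - f$p) * f$n / (f$n - 1)
  S <- count_by(seg, win, windows$window_id)
  pi_sum <- rowsum_by(h[seg], win[seg], windows$window_id, absent = 0)
  ok <- f$n > 0
  nmax <- max_by(f$n[ok], win[ok], windows$window_id)
  d <- tajima_d_stat(S, pi_sum, nmax)
  tibble::tibble(window_id = windows$window_id, tajimas_d = d)
}

max_by <- function(x, group, universe) {
  out <- rep(NA_real_, length(universe))
  if (length(x) == 0) return(out)
  mx <- tapply(x, group, max)
  out[match(as.integer(names(mx)), universe)] <- as.numeric(mx)
  out
}

#' Tajima's D from summary quantities
#'
#' @param S Number of segregating sites (vectorised).
#' @param pi_sum Sum over sites of unbiased heterozygosity (mean pairwise
#'   differences).
#' @param n Number of sampled chromosomes.
#' @return Tajima's D, `NA` where `S < 1` or `n < 4`.
#' @export
tajima_d_stat <- function(S, pi_sum, n) {
  out <- rep(NA_real_, length(S))
  ok <- !is.na(S) & !is.na(n) & S >= 1 & n >= 4
  if (!any(ok)) return(out)
  nn <- n[ok]; ss <- S[ok]; pp <- pi_sum[ok]
  a1 <- vapply(nn, function(m) sum(1 / seq_len(m - 1)), numeric(1))
  a2 <- vapply(nn, function(m) sum(1 / seq_len(m - 1)^2), numeric(1))
  b1 <- (nn + 1) / (3 * (nn - 1))
  b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  vr <- e1 * ss + e2 * ss * (ss - 1)
  out[ok] <- ifelse(vr > 0, (pp - ss / a1) / sqrt(vr), NA_real_)
  out
}

#' Fraction of fixed differences per window
#'
#' Share of the window's SNPs (with calls in both populations) at which
#' the allele sets of the two populations are disjoint, i.e. one
#' population is fixed for one allele and the other for the other.
#'
#' @inheritParams window_fst
#' @return Tibble with columns `window_id`, `fixed_frac`.
#' @export
window_fixed_diff <- function(counts, pop_a, pop_b, win, windows) {
  fa <- site_freq(counts, pop_a)
  fb <- site_freq(counts, pop_b)
  usable <- fa$n > 0 & fb$n > 0
  disjoint <- usable & ((fa$p == 0 & fb$p == 1) | (fa$p == 1 & fb$p == 0))
  n_use <- count_by(usable, win, windows$window_id)
  n_fix <- count_by(disjoint, win, windows$window_id)
  tibble::tibble(window_id = windows$window_id,
                 fixed_frac = ifelse(n_use > 0, n_fix / n_use, NA_real_))
}

#' Mean derived allele frequency per window
#'
#' Mean over the window's polarized SNPs of derived count / called
#' alleles in the population. Requires [polarize()] to have been run;
#' windows with no polarized SNP are `NA`.
#'
#' @inheritParams window_pi
#' @return Tibble with columns `window_id`, `daf`.
#' @export
window_daf <- function(counts, pop, win, windows) {
  if (is.null(counts$polarized)) {
    fatal("counts are not polarized; run polarize() first",
          class = "divscan_data_error")
  }
  n <- counts$called[, pop]
  ok <- counts$polarized & n > 0
  daf <- counts$der[, pop] / n
  s <- rowsum_by(daf[ok], win[ok], windows$window_id)
  m <- count_by(ok, win, windows$window_id)
  tibble::tibble(window_id = windows$window_id,
                 daf = ifelse(m > 0, s / m, NA_real_))
}

#' Maximum pairwise LD (r^2) per window
#'
#' r^2 is the squared Pearson correlation between the allele-dosage
#' vectors of two SNPs across the chosen samples, computed over jointly
#' non-missing entries. Sites must pass a minor-allele-count filter
#' (default MAC >= 2); all in-window pairs are enumerated and the maximum
#' is reported (the mean over pairs is returned alongside). Windows with
#' fewer than two eligible SNPs are `NA`.
#'
#' @param vm A `variant_matrix`.
#' @param win Integer window id per site.
#' @param windows Window tibble.
#' @param samples Sample ids to use; default all ingroup samples.
#' @param min_mac Minimum minor-allele count per site (default 2).
#' @return Tibble with columns `window_id`, `max_r2`, `mean_r2`.
#' @export
window_max_r2 <- function(vm, win, windows, samples = NULL, min_mac = 2) {
  if (is.null(samples)) {
    st <- vm$sample_table
    samples <- st$sample_id[st$role == "ingroup"]
  }
  d <- vm$dosage[, samples, drop = FALSE]
  pl <- matrix(vm$ploidy[samples], nrow = nrow(d), ncol = ncol(d), byrow = TRUE)
  ac <- rowSums(d, na.rm = TRUE)
  an <- rowSums(pl * !is.na(d))
  mac <- pmin(ac, an - ac)
  eligible <- mac >= min_mac
  max_r2 <- mean_r2 <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    idx <- which(win == windows$window_id[i] & eligible)
    if (length(idx) < 2) next
    r <- suppressWarnings(stats::cor(t(d[idx, , drop = FALSE]),
                                     use = "pairwise.complete.obs"))
    r2 <- r[upper.tri(r)]^2
    if (all(is.na(r2))) next
    max_r2[i] <- max(r2, na.rm = TRUE)
    mean_r2[i] <- mean(r2, na.rm = TRUE)
  }
  tibble::tibble(window_id = windows$window_id, max_r2 = max_r2, mean_r2 = mean_r2)
}

#' Patterson's D (ABBA-BABA) from derived allele frequencies
#'
#' For the taxon ordering (p1, p2, p3, outgroup), per polarized site
#' `ABBA = (1-f1) f2 f3` and `BABA = f1 (1-f2) f3` where `f` are derived
#' allele frequencies and the outgroup defines the ancestral state (its
#' derived frequency is 0 by construction).
#' `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)` over the requested
#' window set; `NA` when the denominator is 0.
#'
#' @inheritParams window_fst
#' @param p1,p2,p3 Population labels in the four-taxon ordering.
#' @return A list with `per_window` (tibble: window_id, abba_sum,
#'   baba_sum, patterson_d) and `genome` (list: abba, baba, D over all
#'   windows).
#' @export
patterson_d <- function(counts, p1, p2, p3, win, windows) {
  if (is.null(counts$polarized)) {
    fatal("counts are not polarized; run polarize() first",
          class = "divscan_data_error")
  }
  f <- lapply(c(p1, p2, p3), function(p) {
    n <- counts$called[, p]
    ifelse(n > 0, counts$der[, p] / n, NA_real_)
  })
  abba <- (1 - f[[1]]) * f[[2]] * f[[3]]
  baba <- f[[1]] * (1 - f[[2]]) * f[[3]]
  ok <- counts$polarized & !is.na(abba) & !is.na(baba)
  abba_sum <- rowsum_by(abba[ok], win[ok], windows$window_id, absent = 0)
  baba_sum <- rowsum_by(baba[ok], win[ok], windows$window_id, absent = 0)
  den <- abba_sum + baba_sum
  per_window <- tibble::tibble(
    window_id = windows$window_id,
    abba_sum = abba_sum, baba_sum = baba_sum,
    patterson_d = ifelse(den > 0, (abba_sum - baba_sum) / den, NA_real_)
  )
  tot_a <- sum(abba_sum); tot_b <- sum(baba_sum)
  genome <- list(abba = tot_a, baba = tot_b,
                 D = if (tot_a + tot_b > 0) (tot_a - tot_b) / (tot_a + tot_b) else NA_real_)
  list(per_window = per_window, genome = genome)
}

#' Compute the full per-window statistics table
#'
#' One row per window; per population pair: `fst_<A>_<B>`, `dxy_<A>_<B>`,
#' `fixed_frac_<A>_<B>`, `n_snps_<A>_<B>`; per population: `pi_<P>`,
#' `s_density_<P>`, `tajimas_d_<P>`, `daf_<P>`; plus `max_r2`, `mean_r2`
#' and, when a four-taxon ordering is given, `abba_sum`, `baba_sum`,
#' `patterson_d`. Polarization-dependent columns are filled only when the
#' sample table contains outgroup samples.
#'
#' @param vm A `variant_matrix`.
#' @param windows Window tibble from [make_windows()].
#' @param sample_table Sample table; defaults to the one attached to `vm`.
#' @param pairs List of 2-vectors of population labels; default all
#'   ingroup pairs.
#' @param d_taxa Optional 3-vector (p1, p2, p3) for Patterson's D.
#' @param min_mac Minor-allele-count filter for LD (default 2).
#' @return A tibble, one row per window, with attribute `"genome_d"`
#'   (genome-wide Patterson's D) when `d_taxa` is given.
#' @export
window_stats <- function(vm, windows, sample_table = vm$sample_table,
                         pairs = NULL, d_taxa = NULL, min_mac = 2) {
  sample_table <- validate_sample_table(sample_table)
  counts <- allele_counts(vm, sample_table)
  if (counts$has_outgroup) counts <- polarize(counts)
  win <- assign_sites(vm, windows)
  pops <- counts$pops
  if (is.null(pairs)) {
    pairs <- utils::combn(pops, 2, simplify = FALSE)
  }
  out <- windows
  out$n_snps <- count_by(rep(TRUE, length(win)), win, windows$window_id)
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]; sfx <- paste0("_", a, "_", b)
    fa <- site_freq(counts, a); fb <- site_freq(counts, b)
    out[[paste0("n_snps", sfx)]] <-
      count_by(fa$n > 0 & fb$n > 0, win, windows$window_id)
    out[[paste0("fst", sfx)]] <- window_fst(counts, a, b, win, windows)$fst
    out[[paste0("dxy", sfx)]] <- window_dxy(counts, a, b, win, windows)$dxy
    out[[paste0("fixed_frac", sfx)]] <-
      window_fixed_diff(counts, a, b, win, windows)$fixed_frac
  }
  for (p in pops) {
    ps <- window_pi(counts, p, win, windows)
    out[[paste0("pi_", p)]] <- ps$pi
    out[[paste0("s_density_", p)]] <- ps$s_density
    out[[paste0("tajimas_d_", p)]] <-
      window_tajimas_d(counts, p, win, windows)$tajimas_d
    if (counts$has_outgroup) {
      out[[paste0("daf_", p)]] <- window_daf(counts, p, win, windows)$daf
    }
  }
  ld <- window_max_r2(vm, win, windows,
                      samples = sample_table$sample_id[sample_table$role == "ingroup"],
                      min_mac = min_mac)
  out$max_r2 <- ld$max_r2
  out$mean_r2 <- ld$mean_r2
  if (!is.null(d_taxa)) {
    if (!counts$has_outgroup) {
      fatal("Patterson's D requires outgroup samples for polarization",
            class = "divscan_data_error")
    }
    pd <- patterson_d(counts, d_taxa[1], d_taxa[2], d_taxa[3], win, windows)
    out$abba_sum <- pd$per_window$abba_sum
    out$baba_sum <- pd$per_window$baba_sum
    out$patterson_d <- pd$per_window$patterson_d
    attr(out, "genome_d") <- pd$genome
  }
  out
}
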