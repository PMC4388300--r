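# Estimator unit and oracle tests on small genotype tables.

test_that("polarization follows the outgroup-consensus rule", {
  ids <- c("i1", "i2", "o1", "o2")
  st <- test_sample_table(ids, c("popA", "popA", "out", "out"),
                          roles = c("ingroup", "ingroup", "outgroup", "outgroup"))
  # rows: outgroup hom-ref; outgroup hom-alt; outgroup segregating;
  # outgroup fully missing
  dos <- rbind(c(1, 2, 0, 0),
               c(1, 2, 2, 2),
               c(1, 2, 0, 1),
               c(1, 2, NA, NA))
  colnames(dos) <- ids
  vm <- vm_from_dosage(dos, sample_table = st)
  counts <- polarize(allele_counts(vm))
  expect_equal(counts$polarized, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(counts$der[1, "popA"]), 3)        # derived = alt
  expect_equal(unname(counts$der[2, "popA"]), 4 - 3)    # derived = ref
  expect_true(all(is.na(counts$der[3:4, ])))

  st_noout <- test_sample_table(ids, c("popA", "popA", "popB", "popB"))
  vm2 <- vm_from_dosage(dos, sample_table = st_noout)
  expect_error(polarize(allele_counts(vm2)), class = "divscan_data_error")
})

test_that("polarizable fraction approaches 1 when the outgroup split dwarfs the ingroup", {
  # 2 ingroup pops + a deep outgroup population joining at 8 (4N0 units)
  model <- demographic_model(
    samples = c(10L, 10L, 4L), theta = 20,
    events = data.frame(time = c(0.5, 8), kind = c("join", "join"),
                        i = c(2L, 3L), j = c(1L, 1L), x = NA))
  sim <- simulate_dataset(model, n_loci = 30, seed = 9,
                          outgroup_pops = "pop3")
  counts <- polarize(allele_counts(sim$vm))
  expect_gt(mean(counts$polarized), 0.9)
})

test_that("window F_ST is 1 at complete fixation and <= 0 for identical frequencies", {
  w <- one_window()
  cf <- counts_from_freqs(alt_a = 20, n_a = 20, alt_b = 0, n_b = 20)
  expect_equal(window_fst(cf, "popA", "popB", 1L, w)$fst, 1.0)

  cf2 <- counts_from_freqs(alt_a = 10, n_a = 20, alt_b = 10, n_b = 20)
  expect_lte(window_fst(cf2, "popA", "popB", 1L, w)$fst, 0)

  # empty window is missing, not an error
  cf3 <- counts_from_freqs(alt_a = 10, n_a = 20, alt_b = 10, n_b = 20)
  w2 <- rbind(one_window(), one_window())
  w2$window_id <- 1:2; w2$start <- c(0L, 5000L); w2$end <- c(5000L, 10000L)
  f <- window_fst(cf3, "popA", "popB", 1L, w2)
  expect_true(is.na(f$fst[2]))
})

test_that("window F_ST matches an independent per-site ANOVA oracle", {
  set.seed(42)
  for (rep in 1:20) {
    ns <- 10
    n_a <- sample(4:20, ns, replace = TRUE)
    n_b <- sample(4:20, ns, replace = TRUE)
    alt_a <- vapply(n_a, function(n) sample(0:n, 1), integer(1))
    alt_b <- vapply(n_b, function(n) sample(0:n, 1), integer(1))
    cf <- counts_from_freqs(alt_a, n_a, alt_b, n_b)
    cf$called <- cbind(popA = n_a, popB = n_b)
    got <- window_fst(cf, "popA", "popB", rep(1L, ns), one_window())$fst
    expect_equal(got, fst_anova_oracle(alt_a, n_a, alt_b, n_b), tolerance = 1e-12)
  }
})

test_that("window pi matches the single-site closed form and is 0 without SNPs", {
  w <- one_window()
  cf <- counts_from_freqs(alt_a = 10, n_a = 20, alt_b = 0, n_b = 20)
  got <- window_pi(cf, "popA", 1L, w)
  expect_equal(got$pi, (2 * 0.25 * 20 / 19) / 5000, tolerance = 1e-12)
  expect_equal(got$s_density, 1 / 5000)
  got_b <- window_pi(cf, "popB", 1L, w)
  expect_equal(got_b$pi, 0)
  expect_equal(got_b$s_density, 0)
})

test_that("mean pi times locus length recovers theta on panmictic loci", {
  model <- demographic_model(samples = 20L, theta = 10)
  sim <- simulate_dataset(model, n_loci = 400, seed = 31, diploidize = TRUE)
  w <- make_windows(sim$scaffold_lengths, width = 5000)
  counts <- allele_counts(sim$vm)
  win <- assign_sites(sim$vm, w)
  pi_bp <- window_pi(counts, "pop1", win, w)$pi
  # E[pi] = theta per locus; Monte Carlo s.e. from the replicate spread
  est <- mean(pi_bp * 5000)
  se <- stats::sd(pi_bp * 5000) / sqrt(length(pi_bp))
  expect_lt(abs(est - 10), 3 * se)
})

test_that("d_xy matches closed forms and exhaustive haplotype-pair enumeration", {
  w <- one_window()
  cf <- counts_from_freqs(alt_a = 20, n_a = 20, alt_b = 0, n_b = 20)
  expect_equal(window_dxy(cf, "popA", "popB", 1L, w)$dxy, 1 / 5000)
  cf0 <- counts_from_freqs(alt_a = 0, n_a = 20, alt_b = 0, n_b = 20)
  expect_equal(window_dxy(cf0, "popA", "popB", 1L, w)$dxy, 0)

  # haploid toy data: package value vs all inter-population pairs
  set.seed(7)
  ha <- matrix(rbinom(5 * 6, 1, 0.4), nrow = 5)   # 5 sites x 6 haploids popA
  hb <- matrix(rbinom(5 * 4, 1, 0.6), nrow = 5)   # 4 haploids popB
  pair_mean <- mean(vapply(seq_len(ncol(ha)), function(i)
    mean(colSums(ha[, i] != hb)), numeric(1))) / 5000
  cf2 <- counts_from_freqs(rowSums(ha), 6, rowSums(hb), 4)
  expect_equal(window_dxy(cf2, "popA", "popB", rep(1L, 5), w)$dxy,
               pair_mean, tolerance = 1e-12)
})

test_that("d_xy is invariant to relabeling samples within populations", {
  model <- heliconius_im_models()$migration
  sim <- simulate_dataset(model, n_loci = 2, seed = 12)
  w <- make_windows(sim$scaffold_lengths, width = 5000)
  win <- assign_sites(sim$vm, w)
  counts <- allele_counts(sim$vm)
  base <- window_dxy(counts, "pop1", "pop2", win, w)$dxy
  # shuffle sample ids within pop1
  st <- sim$sample_table
  p1 <- which(st$population == "pop1")
  st2 <- st; st2$sample_id[p1] <- rev(st2$sample_id[p1])
  counts2 <- allele_counts(sim$vm, st2)
  expect_equal(window_dxy(counts2, "pop1", "pop2", win, w)$dxy, base)
})

test_that("Tajima's D handles its degenerate cases and matches a digit-level oracle", {
  w <- one_window()
  # S = 0 -> missing
  cf0 <- counts_from_freqs(alt_a = 0, n_a = 8, alt_b = 0, n_b = 8)
  expect_true(is.na(window_tajimas_d(cf0, "popA", 1L, w)$tajimas_d))

  # independent oracle from haplotype matrices: pairwise differences by
  # exhaustive enumeration, constants recomputed from the published formulas
  tajima_oracle <- function(h) {
    n <- ncol(h)
    S <- sum(apply(h, 1, function(r) length(unique(r)) > 1))
    if (S == 0) return(NA_real_)
    pi_sum <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) pi_sum <- pi_sum + sum(h[, i] != h[, j])
    pi_sum <- pi_sum / choose(n, 2)
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  set.seed(5)
  for (rep in 1:10) {
    h <- matrix(rbinom(12 * 20, 1, runif(1, 0.1, 0.9)), ncol = 20)
    h <- h[apply(h, 1, function(r) length(unique(r)) > 1), , drop = FALSE]
    if (nrow(h) == 0) next
    cf <- counts_from_freqs(rowSums(h), 20, rowSums(h), 20)
    got <- window_tajimas_d(cf, "popA", rep(1L, nrow(h)), w)$tajimas_d
    expect_equal(got, tajima_oracle(h), tolerance = 1e-10)
  }
})

test_that("fixed-difference fraction counts disjoint allele sets", {
  w <- one_window()
  cf <- counts_from_freqs(alt_a = c(10, 0, 20, 5), n_a = 20,
                          alt_b = c(10, 20, 20, 7), n_b = 20)
  # site 2 is the only disjoint one (popA all ref, popB all alt)
  expect_equal(window_fixed_diff(cf, "popA", "popB", rep(1L, 4), w)$fixed_frac, 0.25)
  cf_same <- counts_from_freqs(alt_a = c(3, 7), n_a = 10, alt_b = c(3, 7), n_b = 10)
  expect_equal(window_fixed_diff(cf_same, "popA", "popB", rep(1L, 2), w)$fixed_frac, 0)

  # brute-force set-intersection scan on random tables
  set.seed(11)
  for (rep in 1:10) {
    alt_a <- sample(0:6, 8, replace = TRUE); alt_b <- sample(0:6, 8, replace = TRUE)
    cf2 <- counts_from_freqs(alt_a, 6, alt_b, 6)
    brute <- mean(vapply(1:8, function(s) {
      sets_a <- unique(c(rep("alt", alt_a[s]), rep("ref", 6 - alt_a[s])))
      sets_b <- unique(c(rep("alt", alt_b[s]), rep("ref", 6 - alt_b[s])))
      length(intersect(sets_a, sets_b)) == 0
    }, logical(1)))
    expect_equal(window_fixed_diff(cf2, "popA", "popB", rep(1L, 8), w)$fixed_frac,
                 brute)
  }
})

test_that("derived allele frequency averages polarized sites only", {
  ids <- c("i1", "i2", "o1")
  st <- test_sample_table(ids, c("popA", "popA", "out"),
                          roles = c("ingroup", "ingroup", "outgroup"))
  dos <- rbind(c(2, 2, 0),    # all derived (anc = ref), daf 1
               c(1, 2, 2),    # anc = alt, derived count 4-3=1, daf 0.25
               c(0, 1, 1))    # outgroup het -> unpolarized
  colnames(dos) <- ids
  counts <- polarize(allele_counts(vm_from_dosage(dos, sample_table = st)))
  w <- one_window()
  expect_equal(window_daf(counts, "popA", rep(1L, 3), w)$daf, mean(c(1, 0.25)))
  # a window with only the unpolarized site is missing
  w2 <- rbind(w, w); w2$window_id <- 1:2
  expect_true(is.na(window_daf(counts, "popA", c(1L, 1L, 2L), w2)$daf[2]))
})

test_that("max r^2 matches the exhaustive all-pairs oracle and honours filters", {
  w <- one_window()
  # identical dosage vectors -> r^2 = 1
  dos <- rbind(c(0, 1, 2, 1, 0, 2), c(0, 1, 2, 1, 0, 2))
  vm <- vm_from_dosage(dos)
  expect_equal(window_max_r2(vm, rep(1L, 2), w)$max_r2, 1)

  # monomorphic-after-masking site is skipped (MAC filter)
  dos2 <- rbind(c(0, 1, 2, 1, 0, 2), c(0, 0, 0, 0, 0, 1))
  expect_true(is.na(window_max_r2(vm_from_dosage(dos2), rep(1L, 2), w)$max_r2))

  set.seed(19)
  for (rep in 1:10) {
    dos3 <- matrix(sample(c(0:2, NA), 5 * 12, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), nrow = 5)
    vm3 <- vm_from_dosage(dos3)
    got <- window_max_r2(vm3, rep(1L, 5), w, min_mac = 2)$max_r2
    # brute force over all C(5,2) pairs with the same eligibility rule
    ac <- rowSums(dos3, na.rm = TRUE); an <- rowSums(!is.na(dos3)) * 2
    elig <- which(pmin(ac, an - ac) >= 2)
    best <- NA_real_
    if (length(elig) >= 2) {
      for (i in elig) for (j in elig) if (i < j) {
        ok <- !is.na(dos3[i, ]) & !is.na(dos3[j, ])
        if (sum(ok) < 2) next
        r <- suppressWarnings(cor(dos3[i, ok], dos3[j, ok]))
        if (!is.na(r)) best <- max(best, r^2, na.rm = TRUE)
      }
    }
    expect_equal(got, best)
  }
})

test_that("Patterson's D behaves at forced sites and is antisymmetric in p1/p2", {
  ids <- c("a1", "b1", "c1", "o1")
  st <- test_sample_table(ids, c("p1", "p2", "p3", "out"),
                          roles = c("ingroup", "ingroup", "ingroup", "outgroup"))
  w <- one_window()
  # single site: p1 ancestral, p2 and p3 fixed derived -> ABBA = 1, D = 1
  dos <- matrix(c(0, 2, 2, 0), nrow = 1, dimnames = list(NULL, ids))
  counts <- polarize(allele_counts(vm_from_dosage(dos, sample_table = st)))
  pd <- patterson_d(counts, "p1", "p2", "p3", 1L, w)
  expect_equal(pd$genome$abba, 1)
  expect_equal(pd$genome$baba, 0)
  expect_equal(pd$genome$D, 1)

  # p1 == p2 everywhere -> D = 0
  dos2 <- rbind(c(1, 1, 2, 0), c(2, 2, 1, 0), c(1, 1, 1, 0))
  colnames(dos2) <- ids
  counts2 <- polarize(allele_counts(vm_from_dosage(dos2, sample_table = st)))
  expect_equal(patterson_d(counts2, "p1", "p2", "p3", rep(1L, 3), w)$genome$D, 0)

  # antisymmetry under swapping p1 and p2
  set.seed(23)
  dos3 <- cbind(a1 = sample(0:2, 20, TRUE), b1 = sample(0:2, 20, TRUE),
                c1 = sample(0:2, 20, TRUE), o1 = 0)
  counts3 <- polarize(allele_counts(vm_from_dosage(dos3, sample_table = st)))
  d12 <- patterson_d(counts3, "p1", "p2", "p3", rep(1L, 20), w)$genome$D
  d21 <- patterson_d(counts3, "p2", "p1", "p3", rep(1L, 20), w)$genome$D
  expect_equal(d12, -d21)
  expect_lte(abs(d12), 1)
})

test_that("Patterson's D is near 0 under a no-migration demography", {
  # a no-migration species tree ((p1,p2),p3) with a deep outgroup and
  # enough incomplete lineage sorting that ABBA/BABA sites actually occur
  model_out <- demographic_model(
    samples = c(10L, 10L, 10L, 4L), theta = 20,
    events = data.frame(
      time = c(0.2, 0.5, 4),
      kind = c("join", "join", "join"),
      i = c(2L, 3L, 4L), j = c(1L, 1L, 1L),
      x = NA_real_))
  sim2 <- simulate_dataset(model_out, n_loci = 400, seed = 78,
                           outgroup_pops = "pop4")
  w <- make_windows(sim2$scaffold_lengths, width = 5000)
  win <- assign_sites(sim2$vm, w)
  counts <- polarize(allele_counts(sim2$vm))
  pd <- patterson_d(counts, "pop1", "pop2", "pop3", win, w)
  per_locus <- pd$per_window$patterson_d
  se <- stats::sd(per_locus, na.rm = TRUE) / sqrt(sum(!is.na(per_locus)))
  expect_lt(abs(mean(per_locus, na.rm = TRUE)), 3 * se + 0.02)
  expect_lt(abs(pd$genome$D), 3 * se + 0.02)
})

test_that("windowed statistics are invariant to site order within a window", {
  model <- heliconius_im_models()$migration
  sim <- simulate_dataset(model, n_loci = 2, seed = 55)
  w <- make_windows(sim$scaffold_lengths, width = 5000)
  st <- window_stats(sim$vm, w)
  # shuffle site rows (keeping scaffold grouping valid by re-sorting wrongly
  # ordered positions is forbidden, so shuffle then rebuild through the
  # validated constructor path by reordering both sites and dosage)
  set.seed(2)
  ord <- sample(nrow(sim$vm$sites))
  vm2 <- sim$vm
  vm2$sites <- vm2$sites[ord, ]
  vm2$dosage <- vm2$dosage[ord, , drop = FALSE]
  ord2 <- order(vm2$sites$scaffold, vm2$sites$position)
  vm2$sites <- vm2$sites[ord2, ]
  vm2$dosage <- vm2$dosage[ord2, , drop = FALSE]
  st2 <- window_stats(vm2, w)
  expect_equal(st2, st)
})
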