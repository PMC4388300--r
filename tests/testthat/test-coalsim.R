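# Simulator correctness: parser round-trips, rate calibration against
# closed-form coalescent expectations, and a distributional cross-check
# against an independent coalescent implementation.

test_that("the bundled ms commands parse to the expected models", {
  # typeset text often carries unicode minus signs and multiplication
  # placeholders; the parser must accept those verbatim
  cmd <- paste("ms 60 10000 −t 34.6 −I 3 20 20 20",
               "−max 11.53 11.53 0 × 12.56 0 4.89 ×",
               "−n 1 0.35 −n 2 1.59 −n 3 0.22",
               "−ej 0.761 3 2 −en 0.761 2 0.035",
               "−ej 2.48 2 1 −en 2.48 1 1")
  m <- parse_ms_command(cmd)
  expect_equal(m$n_pops, 3)
  expect_equal(m$samples, c(20L, 20L, 20L))
  expect_equal(m$theta, 34.6)
  M <- matrix(0, 3, 3)
  M[1, 2] <- 11.53; M[1, 3] <- 11.53; M[2, 3] <- 12.56; M[3, 2] <- 4.89
  expect_equal(m$migration, M)
  expect_equal(m$sizes, c(0.35, 1.59, 0.22))
  expect_equal(m$events$kind, c("join", "resize", "join", "resize"))
  expect_equal(m$events$time, c(0.761, 0.761, 2.48, 2.48))
  expect_equal(m$events$i, c(3L, 2L, 2L, 1L))
  expect_equal(m$events$j[c(1, 3)], c(2L, 1L))
  expect_equal(m$events$x[c(2, 4)], c(0.035, 1))
  # the bundled constructor carries the same models
  expect_equal(heliconius_im_models()$migration, m)
  nm <- heliconius_im_models()$no_migration
  expect_true(all(nm$migration == 0))
  expect_equal(nm$events, m$events)

  # -I with no migration flag means zero migration
  m2 <- parse_ms_command("ms 6 1 -t 2 -I 3 2 2 2 -ej 1 2 1 -ej 1 3 1")
  expect_true(all(m2$migration == 0))

  expect_error(parse_ms_command("ms 4 1 -t 2 -Z 3"), "-Z",
               class = "divscan_config_error")
  expect_error(parse_ms_command("ms 5 1 -t 2 -I 2 2 2"),
               class = "divscan_config_error")
})

test_that("format/parse round-trips are idempotent on random valid models", {
  set.seed(61)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    M <- matrix(round(runif(k * k, 0, 5), 2), k, k); diag(M) <- 0
    ev <- tibble::tibble(
      time = sort(round(runif(k - 1, 0.1, 3), 3)),
      kind = "join", i = seq(k, 2L), j = seq(k - 1L, 1L), x = NA_real_)
    m <- demographic_model(sample(2:10, k) * 2L, round(runif(1, 1, 40), 1),
                           migration = M, sizes = round(runif(k, 0.2, 2), 2),
                           events = ev)
    s1 <- format_ms_command(m)
    s2 <- format_ms_command(parse_ms_command(s1))
    expect_identical(s1, s2)
  }
})

test_that("a model whose populations never merge is rejected", {
  expect_error(demographic_model(c(2L, 2L), theta = 1),
               class = "divscan_config_error")
  # migration connects them: fine
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(demographic_model(c(2L, 2L), 1, migration = M),
                  "demographic_model")
})

test_that("panmictic TMRCA and Watterson expectations calibrate the rates", {
  # smaller-scale calibration; the acceptance suite runs the full version
  m2 <- demographic_model(2L, theta = 1)
  set.seed(71)
  t2 <- replicate(4000, simulate_genealogy(m2)$tmrca)
  expect_lt(abs(mean(t2) - 0.5), 3 * sd(t2) / sqrt(length(t2)))

  m10 <- demographic_model(10L, theta = 34.6)
  set.seed(72)
  S <- replicate(2000, {
    g <- simulate_genealogy(m10)
    nrow(drop_mutations(g, 34.6)$geno)
  })
  expected <- 34.6 * sum(1 / (1:9))
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))
})

test_that("cross-population coalescence cannot predate contact", {
  m <- demographic_model(c(4L, 4L), theta = 1,
                         events = data.frame(time = 10, kind = "join",
                                             i = 2L, j = 1L, x = NA))
  # pairwise MRCA times from the parent pointers
  mrca_time <- function(g, a, b) {
    anc <- function(v) {
      path <- v
      while (g$parent[v] > 0) { v <- g$parent[v]; path <- c(path, v) }
      path
    }
    common <- intersect(anc(a), anc(b))
    min(g$time[common])
  }
  set.seed(3)
  for (rep in 1:20) {
    g <- simulate_genealogy(m)
    for (a in 1:4) for (b in 5:8) expect_gt(mrca_time(g, a, b), 10)
  }
})

test_that("mutation dropping respects theta and mode", {
  m <- demographic_model(6L, theta = 5)
  set.seed(81)
  g <- simulate_genealogy(m)
  expect_equal(nrow(drop_mutations(g, theta = 0)$geno), 0)

  # pair sample: E[S] = theta under infinite sites
  m2 <- demographic_model(2L, theta = 34.6)
  set.seed(82)
  S <- replicate(3000, nrow(drop_mutations(simulate_genealogy(m2), 34.6)$geno))
  expect_lt(abs(mean(S) - 34.6), 3 * sd(S) / sqrt(length(S)))

  # finite-sites recurrent hits lose biallelic SNPs relative to infinite sites
  set.seed(83)
  cmp <- replicate(400, {
    g <- simulate_genealogy(m2)
    c(is = nrow(drop_mutations(g, 34.6, mode = "infinite_sites")$geno),
      jc = nrow(drop_mutations(g, 34.6, mode = "jukes_cantor")$geno))
  })
  expect_lt(mean(cmp["jc", ]), mean(cmp["is", ]))
})

test_that("simulated datasets are deterministic and structurally sound", {
  m <- heliconius_im_models()$migration
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_dataset(m, 3, seed = 5, out_dir = d1)
  s2 <- simulate_dataset(m, 3, seed = 5, out_dir = d2)
  expect_identical(readLines(file.path(d1, "sim.vcf")),
                   readLines(file.path(d2, "sim.vcf")))
  expect_equal(s1$vm$sites, s2$vm$sites)

  # per-population sample counts match the model (20 haploids -> 10 diploids)
  expect_equal(unname(table(s1$sample_table$population)), rep(10L, 3),
               ignore_attr = TRUE)
  expect_true(all(s1$vm$ploidy == 2))

  # odd haploid counts cannot be diploidized
  modd <- demographic_model(c(3L, 4L), 1,
                            events = data.frame(time = 1, kind = "join",
                                                i = 2L, j = 1L, x = NA))
  expect_error(simulate_dataset(modd, 1, seed = 1, diploidize = TRUE),
               class = "divscan_config_error")
  expect_s3_class(simulate_dataset(modd, 2, seed = 1, diploidize = FALSE)$vm,
                  "variant_matrix")
})

test_that("pipeline statistics are exchangeable under within-population relabeling", {
  m <- heliconius_im_models()$migration
  sim <- simulate_dataset(m, 30, seed = 19)
  w <- make_windows(sim$scaffold_lengths, 5000)
  counts <- allele_counts(sim$vm)
  win <- assign_sites(sim$vm, w)
  f1 <- window_fst(counts, "pop1", "pop2", win, w)$fst
  # permute which samples carry which ids within each population
  st2 <- sim$sample_table
  set.seed(20)
  for (p in unique(st2$population)) {
    i <- which(st2$population == p)
    st2$sample_id[i] <- sample(st2$sample_id[i])
  }
  f2 <- window_fst(allele_counts(sim$vm, st2), "pop1", "pop2", win, w)$fst
  expect_equal(f2, f1)
})

test_that("migration suppresses F_ST for every population pair", {
  mods <- heliconius_im_models()
  fc <- fst_distribution_comparison(mods$migration, mods$no_migration,
                                    n_loci = 120, seed = 33)
  expect_true(all(fc$ratio_per_pair > 1))
  expect_gt(fc$ratio_mean, 1)
  # identical models give a ratio near 1
  fc_same <- fst_distribution_comparison(mods$migration, mods$migration,
                                         n_loci = 120, seed = 34)
  expect_lt(abs(fc_same$ratio_mean - 1), 0.25)
})

test_that("strong symmetric migration drives F_ST toward 0", {
  M <- matrix(200, 2, 2); diag(M) <- 0
  m <- demographic_model(c(20L, 20L), theta = 10, migration = M)
  sim <- simulate_dataset(m, 60, seed = 44)
  w <- make_windows(sim$scaffold_lengths, 5000)
  f <- window_fst(allele_counts(sim$vm), "pop1", "pop2",
                  assign_sites(sim$vm, w), w)$fst
  expect_lt(abs(mean(f, na.rm = TRUE)), 0.02)
})

test_that("segregating-site distributions match an independent coalescent implementation", {
  # reference counts generated by msprime's ms-compatible CLI with the
  # commands recorded in the fixture headers
  ref_dir <- system.file("extdata", package = "divscan")
  for (fx in c("msref_segsites_migration.txt", "msref_segsites_no_migration.txt")) {
    ref <- scan(file.path(ref_dir, fx), comment.char = "#", quiet = TRUE)
    model <- if (grepl("no_migration", fx)) heliconius_im_models()$no_migration
             else heliconius_im_models()$migration
    set.seed(91)
    S <- replicate(2000, {
      g <- simulate_genealogy(model)
      stats::rpois(1, model$theta * g$total_length)
    })
    ks <- suppressWarnings(stats::ks.test(S, ref))
    expect_gt(ks$p.value, 0.01)
  }
})
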