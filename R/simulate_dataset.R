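# Turning simulated loci into the same data structures the empirical
# pipeline consumes: a variant matrix, a sample table, and (optionally)
# a plain-text VCF + TSV on disk.

#' Simulate a multi-locus dataset under a demographic model
#'
#' Simulates `n_loci` independent loci (one genealogy each, no intra-locus
#' recombination), drops mutations, and assembles a `variant_matrix` in
#' which each locus is its own scaffold (`locus_0001`, ...). Haploid
#' simulated samples are paired into pseudo-diploids by default so the
#' interface matches an empirical VCF. The VCF REF allele is the ancestral
#' state, so downstream polarization against simulated outgroup
#' populations behaves as with real data. Fully determined by `seed`.
#'
#' @param model A `demographic_model`.
#' @param n_loci Number of independent loci (>= 1).
#' @param length Locus length in bp (default 5000).
#' @param seed Integer seed.
#' @param diploidize Pair consecutive haploids within each population into
#'   diploids (default TRUE; haploid counts must then be even).
#' @param mode Mutation mode passed to [drop_mutations()].
#' @param outgroup_pops Populations (e.g. `"pop3"`) whose samples get role
#'   `"outgroup"` in the sample table.
#' @param out_dir If non-NULL, write `sim.vcf`, `samples.tsv`,
#'   `scaffolds.tsv` and `provenance.json` there.
#' @return A list: `vm` (a `variant_matrix`), `sample_table`,
#'   `scaffold_lengths`, `loci` (per-locus tibble: scaffold, n_snps,
#'   tmrca, total_length), `paths` (when written).
#' @export
simulate_dataset <- function(model, n_loci, length = 5000, seed = 1,
                             diploidize = TRUE,
                             mode = c("infinite_sites", "jukes_cantor"),
                             outgroup_pops = character(),
                             out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_loci >= 1)
  if (diploidize && any(model$samples %% 2 != 0)) {
    fatal("diploidize requires an even haploid sample count per population",
          class = "divscan_config_error")
  }
  k <- model$n_pops
  pop_names <- paste0("pop", seq_len(k))
  loci <- with_seed(derive_seed(seed, "simulate_dataset"), {
    lapply(seq_len(n_loci), function(l) {
      g <- simulate_genealogy(model)
      lc <- drop_mutations(g, model$theta, length = length, mode = mode)
      list(locus = lc, tmrca = g$tmrca, total_length = g$total_length)
    })
  })
  bases <- c("A", "C", "G", "T")
  ref_alt <- with_seed(derive_seed(seed, "simulate_dataset:bases"), {
    n_sites_total <- sum(vapply(loci, function(z) length(z$locus$position), integer(1)))
    ref <- sample(bases, n_sites_total, replace = TRUE)
    shift <- sample.int(3, n_sites_total, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1 + shift) %% 4 + 1]
    list(ref = ref, alt = alt)
  })

  scaf_names <- sprintf("locus_%04d", seq_len(n_loci))
  # sample naming and (possibly diploid) genotype assembly
  if (diploidize) {
    n_ind <- model$samples %/% 2
  } else {
    n_ind <- model$samples
  }
  sample_ids <- unlist(lapply(seq_len(k), function(p)
    sprintf("%s_ind%02d", pop_names[p], seq_len(n_ind[p]))))
  ploidy <- rep(if (diploidize) 2L else 1L, sum(n_ind))
  names(ploidy) <- sample_ids
  sample_table <- tibble::tibble(
    sample_id = sample_ids,
    population = rep(pop_names, n_ind),
    role = ifelse(rep(pop_names, n_ind) %in% outgroup_pops, "outgroup", "ingroup")
  )

  sites_list <- vector("list", n_loci)
  dos_list <- vector("list", n_loci)
  off <- 0L
  per_locus <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    lc <- loci[[l]]$locus
    ns <- length(lc$position)
    per_locus[[l]] <- tibble::tibble(scaffold = scaf_names[l], n_snps = ns,
                                     tmrca = loci[[l]]$tmrca,
                                     total_length = loci[[l]]$total_length)
    if (ns == 0) next
    idx <- off + seq_len(ns)
    sites_list[[l]] <- tibble::tibble(
      scaffold = scaf_names[l], position = as.integer(lc$position),
      ref = ref_alt$ref[idx], alt = ref_alt$alt[idx])
    g <- lc$geno
    if (diploidize) {
      g <- g[, seq(1, ncol(g), by = 2), drop = FALSE] +
        g[, seq(2, ncol(g), by = 2), drop = FALSE]
    }
    dos_list[[l]] <- g
    off <- off + ns
  }
  sites <- dplyr::bind_rows(sites_list)
  if (nrow(sites) == 0) {
    fatal("simulation produced no SNPs at all; increase theta or n_loci",
          class = "divscan_data_error")
  }
  dosage <- do.call(rbind, dos_list)
  colnames(dosage) <- sample_ids
  vm <- structure(list(sites = sites, dosage = dosage, ploidy = ploidy,
                       sample_table = sample_table,
                       report = list(n_input = nrow(sites), n_kept = nrow(sites),
                                     dropped_indel = 0L, dropped_multiallelic = 0L)),
                  class = "variant_matrix")
  scaffold_lengths <- tibble::tibble(name = scaf_names, length = length)
  out <- list(vm = vm, sample_table = sample_table,
              scaffold_lengths = scaffold_lengths,
              loci = dplyr::bind_rows(per_locus), paths = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(out_dir, "sim.vcf"),
                  samples = file.path(out_dir, "samples.tsv"),
                  scaffolds = file.path(out_dir, "scaffolds.tsv"),
                  provenance = file.path(out_dir, "provenance.json"))
    write_sim_vcf(vm, scaffold_lengths, paths$vcf)
    readr::write_tsv(sample_table, paths$samples)
    readr::write_tsv(scaffold_lengths, paths$scaffolds, col_names = FALSE)
    jsonlite::write_json(
      list(ms_command = format_ms_command(model), n_loci = n_loci,
           locus_length = length, seed = seed, diploidize = diploidize,
           mode = mode, outgroup_pops = outgroup_pops,
           package_version = as.character(utils::packageVersion("divscan"))),
      paths$provenance, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- paths
  }
  out
}

# minimal plain-text VCF v4.2 writer for simulated genotype matrices
write_sim_vcf <- function(vm, scaffold_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=divscan coalescent simulator",
    sprintf("##contig=<ID=%s,length=%d>", scaffold_lengths$name,
            scaffold_lengths$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vm$dosage)), collapse = "\t")), con)
  if (nrow(vm$sites) == 0) return(invisible(path))
  gt_code <- function(dos, pl) {
    if (pl == 1L) as.character(dos) else c("0/0", "0/1", "1/1")[dos + 1L]
  }
  gt <- vapply(seq_len(ncol(vm$dosage)), function(j)
    gt_code(vm$dosage[, j], vm$ploidy[j]), character(nrow(vm$sites)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(vm$sites))
  lines <- paste(vm$sites$scaffold, vm$sites$position, ".",
                 vm$sites$ref, vm$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Compare F_ST distributions with and without migration
#'
#' Simulates both models (which must share the sample configuration),
#' computes per-locus AMOVA-style F_ST for every population pair with the
#' pipeline's own estimator, and returns the empirical distributions plus
#' the no-migration / with-migration ratio of mean F_ST per pair and
#' averaged over pairs, with a bootstrap CI over loci for the averaged
#' ratio. Loci with no SNPs (F_ST undefined) are excluded with a count.
#'
#' @param model_mig,model_nomig `demographic_model`s with and without
#'   migration.
#' @param n_loci Loci per model (default 1000).
#' @param length Locus length bp (default 5000).
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates for the ratio CI (default 1000).
#' @return A list of class `divscan_fst_comparison`: `per_locus` (tibble:
#'   model, pair, scaffold, fst), `mean_fst` (tibble per model x pair),
#'   `ratio_per_pair`, `ratio_mean`, `ratio_ci`, `n_excluded`.
#' @export
fst_distribution_comparison <- function(model_mig, model_nomig, n_loci = 1000,
                                        length = 5000, seed = 1, n_boot = 1000) {
  if (!identical(model_mig$samples, model_nomig$samples)) {
    fatal("models must share the sample configuration", class = "divscan_config_error")
  }
  sims <- list(
    with_migration = simulate_dataset(model_mig, n_loci, length,
                                      seed = derive_seed(seed, "fstcmp:mig")),
    no_migration = simulate_dataset(model_nomig, n_loci, length,
                                    seed = derive_seed(seed, "fstcmp:nomig"))
  )
  per_locus <- purrr::imap_dfr(sims, function(sim, nm) {
    windows <- make_windows(sim$scaffold_lengths, width = length)
    counts <- allele_counts(sim$vm)
    win <- assign_sites(sim$vm, windows)
    pops <- counts$pops
    purrr::map_dfr(utils::combn(pops, 2, simplify = FALSE), function(pr) {
      f <- window_fst(counts, pr[1], pr[2], win, windows)
      tibble::tibble(model = nm, pair = paste(pr, collapse = "_"),
                     scaffold = windows$scaffold, fst = f$fst)
    })
  })
  n_excluded <- sum(is.na(per_locus$fst))
  mean_fst <- per_locus |>
    dplyr::group_by(.data$model, .data$pair) |>
    dplyr::summarise(mean_fst = mean(.data$fst, na.rm = TRUE),
                     n = sum(!is.na(.data$fst)), .groups = "drop")
  wide <- tidyr::pivot_wider(mean_fst[, c("model", "pair", "mean_fst")],
                             names_from = "model", values_from = "mean_fst")
  ratio_per_pair <- stats::setNames(wide$no_migration / wide$with_migration,
                                    wide$pair)
  ratio_mean <- mean(ratio_per_pair)
  # bootstrap over loci, resampling each model's loci independently
  ratio_ci <- with_seed(derive_seed(seed, "fstcmp:boot"), {
    pairs <- unique(per_locus$pair)
    mats <- lapply(c("no_migration", "with_migration"), function(m) {
      sapply(pairs, function(pr)
        per_locus$fst[per_locus$model == m & per_locus$pair == pr])
    })
    reps <- vapply(seq_len(n_boot), function(b) {
      idx1 <- sample.int(nrow(mats[[1]]), replace = TRUE)
      idx2 <- sample.int(nrow(mats[[2]]), replace = TRUE)
      num <- colMeans(mats[[1]][idx1, , drop = FALSE], na.rm = TRUE)
      den <- colMeans(mats[[2]][idx2, , drop = FALSE], na.rm = TRUE)
      mean(num / den)
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })
  structure(list(per_locus = per_locus, mean_fst = mean_fst,
                 ratio_per_pair = ratio_per_pair, ratio_mean = ratio_mean,
                 ratio_ci = ratio_ci, n_excluded = n_excluded,
                 n_loci = n_loci, seed = seed),
            class = "divscan_fst_comparison")
}

#' @export
print.divscan_fst_comparison <- function(x, ...) {
  cat(sprintf("<F_ST comparison> %d loci/model; mean F_ST ratio (no-mig / mig) = %.2f [%.2f, %.2f]\n",
              x$n_loci, x$ratio_mean, x$ratio_ci[1], x$ratio_ci[2]))
  for (pr in names(x$ratio_per_pair)) {
    cat(sprintf("  %s: ratio %.2f\n", pr, x$ratio_per_pair[pr]))
  }
  invisible(x)
}
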