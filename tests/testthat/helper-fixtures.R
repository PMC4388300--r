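# Fixtures are built in code: small VCFs written to tempfiles, dosage
# matrices assembled directly, and demographic models from ms commands.

write_test_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

test_sample_table <- function(samples, populations, roles = NULL) {
  tibble::tibble(sample_id = samples, population = populations,
                 role = roles %||% rep("ingroup", length(samples)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# variant_matrix straight from a dosage matrix (sites x samples)
vm_from_dosage <- function(dosage, positions = NULL, scaffold = "scf1",
                           ploidy = 2L, sample_table = NULL) {
  ns <- nrow(dosage)
  ids <- colnames(dosage) %||% sprintf("s%02d", seq_len(ncol(dosage)))
  colnames(dosage) <- ids
  if (is.null(sample_table)) {
    sample_table <- test_sample_table(ids, rep("popA", length(ids)))
  }
  structure(list(
    sites = tibble::tibble(scaffold = scaffold,
                           position = positions %||% seq_len(ns),
                           ref = "A", alt = "T"),
    dosage = dosage,
    ploidy = stats::setNames(rep(ploidy, length(ids)), ids),
    sample_table = sample_table,
    report = list(n_input = ns, n_kept = ns, dropped_indel = 0L,
                  dropped_multiallelic = 0L)),
    class = "variant_matrix")
}

# two-population haploid counts object built directly from per-site
# (alt, called) pairs; handy for estimator unit tests
counts_from_freqs <- function(alt_a, n_a, alt_b, n_b) {
  ns <- length(alt_a)
  structure(list(
    sites = tibble::tibble(scaffold = "scf1", position = seq_len(ns),
                           ref = "A", alt = "T"),
    pops = c("popA", "popB"),
    alt = cbind(popA = alt_a, popB = alt_b),
    called = cbind(popA = rep(n_a, length.out = ns),
                   popB = rep(n_b, length.out = ns)),
    out_alt = rep(0, ns), out_called = rep(0, ns),
    has_outgroup = FALSE, der = NULL, polarized = NULL),
    class = "allele_counts")
}

one_window <- function(n_sites = NULL, length = 5000) {
  tibble::tibble(window_id = 1L, scaffold = "scf1", start = 0L,
                 end = as.integer(length), length = as.integer(length),
                 short = FALSE)
}

# independent brute-force F_ST oracle: per-site two-level ANOVA on raw 0/1
# allele observations via lm/anova, ratio of summed variance components
fst_anova_oracle <- function(alt_a, n_a, alt_b, n_b) {
  num <- den <- 0
  for (s in seq_along(alt_a)) {
    y <- c(rep(1, alt_a[s]), rep(0, n_a[s] - alt_a[s]),
           rep(1, alt_b[s]), rep(0, n_b[s] - alt_b[s]))
    g <- factor(c(rep("A", n_a[s]), rep("B", n_b[s])))
    if (n_a[s] < 2 || n_b[s] < 2) next
    tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
    msa <- tab$`Mean Sq`[1]
    msw <- tab$`Mean Sq`[2]
    N <- n_a[s] + n_b[s]
    n0 <- N - (n_a[s]^2 + n_b[s]^2) / N   # r - 1 = 1
    num <- num + (msa - msw) / n0
    den <- den + (msa - msw) / n0 + msw
  }
  if (den <= 1e-12) NA_real_ else num / den   # undefined when no variance at all
}

# direct transcription of the two-tier linking rule, evaluated by brute
# force over all enclosed stretches (single scaffold)
link_oracle <- function(fst, t_hi, t_lo) {
  n <- length(fst)
  hi <- !is.na(fst) & fst >= t_hi
  div <- hi
  hi_idx <- which(hi)
  if (length(hi_idx) >= 2) {
    for (k in 1:(length(hi_idx) - 1)) {
      i <- hi_idx[k]; j <- hi_idx[k + 1]
      if (j > i + 1) {
        mid <- (i + 1):(j - 1)
        if (all(!is.na(fst[mid]) & fst[mid] >= t_lo)) div[mid] <- TRUE
      }
    }
  }
  div
}
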