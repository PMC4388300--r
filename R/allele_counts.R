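#' Per-population allele counts at each site
#'
#' Collapses the per-sample dosage matrix into, for every site and every
#' ingroup population, the count of ALT alleles and the number of called
#' alleles (missing genotypes reduce the called total rather than dropping
#' the site). Outgroup samples are pooled into a single combined outgroup
#' used for polarization.
#'
#' @param vm A `variant_matrix`.
#' @param sample_table Sample table; defaults to the one attached to `vm`.
#' @return An `allele_counts` object: list with `sites`, `pops`, matrices
#'   `alt` and `called` (sites x populations), combined-outgroup vectors
#'   `out_alt`/`out_called`, and (after [polarize()]) `der` and
#'   `polarized`.
#' @export
allele_counts <- function(vm, sample_table = vm$sample_table) {
  sample_table <- validate_sample_table(sample_table)
  ing <- sample_table[sample_table$role == "ingroup", ]
  pops <- unique(ing$population)
  ns <- nrow(vm$sites)
  alt <- called <- matrix(0, nrow = ns, ncol = length(pops),
                          dimnames = list(NULL, pops))
  for (p in pops) {
    ids <- ing$sample_id[ing$population == p]
    d <- vm$dosage[, ids, drop = FALSE]
    pl <- matrix(vm$ploidy[ids], nrow = ns, ncol = length(ids), byrow = TRUE)
    alt[, p] <- rowSums(d, na.rm = TRUE)
    called[, p] <- rowSums(pl * !is.na(d))
  }
  outg <- sample_table$sample_id[sample_table$role == "outgroup"]
  if (length(outg) > 0) {
    d <- vm$dosage[, outg, drop = FALSE]
    pl <- matrix(vm$ploidy[outg], nrow = ns, ncol = length(outg), byrow = TRUE)
    out_alt <- rowSums(d, na.rm = TRUE)
    out_called <- rowSums(pl * !is.na(d))
  } else {
    out_alt <- out_called <- rep(0, ns)
  }
  structure(list(sites = vm$sites, pops = pops, alt = alt, called = called,
                 out_alt = out_alt, out_called = out_called,
                 has_outgroup = length(outg) > 0,
                 der = NULL, polarized = NULL),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %d sites x %d population(s)%s\n",
              nrow(x$sites), length(x$pops),
              if (!is.null(x$polarized))
                sprintf(", %d polarized", sum(x$polarized)) else ""))
  invisible(x)
}

#' Polarize alleles against the combined outgroup
#'
#' The ancestral allele at a site is the allele fixed across all
#' non-missing outgroup alleles; sites where the outgroup segregates, or
#' where every outgroup call is missing, are marked unpolarized and are
#' excluded from derived-allele-frequency and Patterson's D computations.
#'
#' @param counts An `allele_counts` object built from a sample table that
#'   contains at least one outgroup sample.
#' @return `counts` with `der` (derived-allele count matrix) and
#'   `polarized` (logical per site) filled in.
#' @export
polarize <- function(counts) {
  if (!counts$has_outgroup) {
    fatal("no outgroup samples: cannot polarize ancestral/derived alleles",
          class = "divscan_data_error")
  }
  anc_ref <- counts$out_called > 0 & counts$out_alt == 0
  anc_alt <- counts$out_called > 0 & counts$out_alt == counts$out_called
  counts$polarized <- anc_ref | anc_alt
  der <- counts$alt
  der[anc_alt, ] <- counts$called[anc_alt, , drop = FALSE] - counts$alt[anc_alt, , drop = FALSE]
  der[!counts$polarized, ] <- NA_real_
  counts$der <- der
  counts
}
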