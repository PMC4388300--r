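#' Read a sample table
#'
#' The sample table maps each VCF sample to a population and a role. It is
#' a tab-separated file with three columns: `sample_id`, `population`,
#' `role`, where role is `"ingroup"` or `"outgroup"`. Outgroup samples are
#' used only to polarize ancestral vs derived alleles.
#'
#' @param path Path to a TSV file with columns sample_id, population, role.
#' @return A tibble with columns `sample_id`, `population`, `role`.
#' @export
read_sample_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_sample_table(tab)
}

#' Validate (and normalise) a sample table
#'
#' @param tab A data frame with columns sample_id, population, role.
#' @return The validated tibble.
#' @export
validate_sample_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  need <- c("sample_id", "population", "role")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    fatal(paste0("sample table is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "divscan_config_error")
  }
  if (anyDuplicated(tab$sample_id)) {
    fatal("sample_id values must be unique", class = "divscan_config_error")
  }
  bad <- setdiff(unique(tab$role), c("ingroup", "outgroup"))
  if (length(bad) > 0) {
    fatal(paste0("unknown role(s): ", paste(bad, collapse = ", ")),
          class = "divscan_config_error")
  }
  tab[need]
}

#' Read scaffold lengths
#'
#' A two-column TSV (`name`, `length`) in the style of a FASTA index: one
#' row per scaffold with its length in bp.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name` (character), `length` (integer bp).
#' @export
read_scaffold_lengths <- function(path) {
  tab <- readr::read_tsv(path,
                         col_names = c("name", "length"),
                         col_types = "cd", progress = FALSE)
  if (any(tab$length <= 0)) fatal("scaffold lengths must be positive",
                                  class = "divscan_config_error")
  tab
}

#' Read a BED file of named intervals
#'
#' Standard BED coordinates (0-based start, exclusive end) are consumed
#' as-is. Used for named loci (e.g. mimicry genes) and chromosome
#' assignments of scaffolds.
#'
#' @param path Path to a BED file (3+ columns; 4th column used as name).
#' @return A tibble with columns `scaffold`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()),
                         comment = "#", progress = FALSE)
  if (ncol(tab) < 3) fatal("BED file needs at least 3 columns", class = "divscan_data_error")
  out <- tibble::tibble(
    scaffold = as.character(tab[[1]]),
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_
  )
  if (any(out$start >= out$end)) fatal("BED intervals must satisfy start < end",
                                       class = "divscan_data_error")
  out
}

#' Load biallelic SNPs from a VCF into a variant matrix
#'
#' Reads a (possibly gzipped) multi-sample VCF and keeps only biallelic
#' SNP records; indels and multiallelic records are dropped and counted in
#' the attached load report. Genotypes are collapsed to per-sample counts
#' of the ALT allele ("dosage"); any genotype containing a missing allele
#' is stored as `NA`.
#'
#' @param vcf_path Path to the VCF file.
#' @param sample_table Sample table (see [read_sample_table()]); all its
#'   sample_ids must be present in the VCF header. Samples in the VCF but
#'   not in the table are ignored.
#' @return A `variant_matrix` object: a list with elements `sites` (tibble:
#'   scaffold, position, ref, alt), `dosage` (integer matrix, sites x
#'   samples, `NA` = missing), `ploidy` (integer per sample) and `report`
#'   (dropped-record counts).
#' @export
load_variants <- function(vcf_path, sample_table) {
  sample_table <- validate_sample_table(sample_table)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_all <- vcf@gt
  vcf_samples <- colnames(gt_all)[-1]
  absent <- setdiff(sample_table$sample_id, vcf_samples)
  if (length(absent) > 0) {
    fatal(paste0("sample(s) not present in VCF header: ", paste(absent, collapse = ", ")),
          class = "divscan_data_error")
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  is_snp <- !is_multi & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1
  is_indel <- !is_multi & !is_snp
  keep <- which(is_snp)
  report <- list(
    n_input = nrow(fix),
    n_kept = length(keep),
    dropped_indel = sum(is_indel),
    dropped_multiallelic = sum(is_multi)
  )
  if (length(keep) == 0) fatal("no biallelic SNPs retained from VCF",
                               class = "divscan_data_error")

  sites <- tibble::tibble(
    scaffold = fix[keep, "CHROM"],
    position = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep]
  )
  gt <- gt_all[keep, sample_table$sample_id, drop = FALSE]
  # strip any FORMAT payload beyond GT
  gt <- sub(":.*$", "", gt)
  dosage <- matrix(stringr::str_count(gt, stringr::fixed("1")),
                   nrow = nrow(gt), ncol = ncol(gt))
  dosage[grepl(".", gt, fixed = TRUE) | is.na(gt)] <- NA_integer_
  colnames(dosage) <- sample_table$sample_id
  n_alleles <- matrix(stringr::str_count(gt, "[0-9.]"),
                      nrow = nrow(gt), ncol = ncol(gt))
  ploidy <- apply(n_alleles, 2, function(x) {
    x <- x[!is.na(x) & x > 0]
    if (length(x) == 0) 2L else as.integer(max(x))
  })
  names(ploidy) <- sample_table$sample_id

  ord <- order(sites$scaffold, sites$position)
  vm <- structure(
    list(sites = sites[ord, ], dosage = dosage[ord, , drop = FALSE],
         ploidy = ploidy, sample_table = sample_table, report = report),
    class = "variant_matrix"
  )
  validate_variant_matrix(vm)
}

validate_variant_matrix <- function(vm) {
  s <- vm$sites
  by_scaf <- split(s$position, s$scaffold)
  if (any(vapply(by_scaf, function(p) any(diff(p) <= 0), logical(1)))) {
    fatal("site positions must be strictly increasing within each scaffold",
          class = "divscan_data_error")
  }
  pl <- matrix(vm$ploidy, nrow = nrow(vm$dosage), ncol = ncol(vm$dosage), byrow = TRUE)
  if (any(vm$dosage > pl, na.rm = TRUE)) {
    fatal("dosage exceeds ploidy", class = "divscan_data_error")
  }
  vm
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d biallelic SNPs x %d samples on %d scaffold(s)\n",
              nrow(x$sites), ncol(x$dosage), length(unique(x$sites$scaffold))))
  cat(sprintf("  dropped on load: %d indel, %d multiallelic\n",
              x$report$dropped_indel, x$report$dropped_multiallelic))
  invisible(x)
}

#' Tidy site table of a variant matrix
#'
#' @param x A `variant_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per site x sample carrying the dosage.
#' @method tidy variant_matrix
#' @export
tidy.variant_matrix <- function(x, ...) {
  tibble::tibble(
    scaffold = rep(x$sites$scaffold, ncol(x$dosage)),
    position = rep(x$sites$position, ncol(x$dosage)),
    sample_id = rep(colnames(x$dosage), each = nrow(x$sites)),
    dosage = as.vector(x$dosage)
  )
}

#' Write window statistics to TSV
#'
#' @param stats A window statistics tibble (from [window_stats()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}

#' Write divergent regions as 6-column BED
#'
#' Columns: scaffold, start, end, region id, number of member windows,
#' mean window F_ST of the region.
#'
#' @param regions A region tibble (from [link_windows()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$scaffold,
    start = regions$start,
    end = regions$end,
    name = paste0("region_", regions$region_id),
    score = regions$n_windows,
    fst = signif(regions$mean_fst, 6)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
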