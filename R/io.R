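# Plain-text interchange: TSV for tabular artifacts, VCF for genotypes.
# Every writer emits a header with stable column order and is re-readable
# by the package's own readers.

#' Write / read a tab-separated table
#'
#' Thin wrappers fixing the package's TSV dialect: header row, tab
#' separator, no quoting, no row names.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv_file` returns a data frame.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read an item-parameter table
#'
#' Columns: `item_id`, `domain`, `subdomain`, `anchor`, `a`, `a_spec`,
#' `b1..b(K-1)` (NA-padded).
#'
#' @param items item parameter data frame.
#' @param path file path.
#' @export
write_item_bank <- function(items, path) {
  cols <- c(intersect(c("study", "item_id", "domain", "subdomain",
                        "anchor", "a", "a_spec"), names(items)),
            .bank_bcols(items))
  write_tsv_file(items[, cols], path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) read_tsv_file(path)

#' Read genotypes from a VCF file
#'
#' Dosages come from the `DS` FORMAT field when present, otherwise from
#' `GT` hard calls mapped 0/0 -> 0, 0/1 -> 1, 1/1 -> 2. Missing genotypes
#' are imputed to the variant's mean dosage and counted in the
#' `"n_imputed"` attribute. Multiallelic records are skipped with a
#' warning. Positions are 1-based per the VCF convention. Coded allele =
#' ALT. Coded-allele frequency and info score are taken from the `AF` and
#' `R2` INFO keys when present, else `caf` is computed from the dosages
#' and `info` set to 1.
#'
#' @param path path to a VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  fmt <- unique(v@gt[, "FORMAT"])
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    D <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    D <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    D[clean == "0/0"] <- 0
    D[clean %in% c("0/1", "1/0")] <- 1
    D[clean == "1/1"] <- 2
  }
  D <- t(D)                       # samples x variants
  n_imputed <- 0L
  for (j in seq_len(ncol(D))) {
    na <- is.na(D[, j])
    if (any(na)) {
      D[na, j] <- mean(D[!na, j])
      n_imputed <- n_imputed + sum(na)
    }
  }
  info_field <- function(key) {
    pat <- paste0("(^|;)", key, "=([^;]+)")
    out <- rep(NA_real_, nrow(fix))
    hit <- grepl(pat, fix$INFO)
    out[hit] <- as.numeric(sub(paste0(".*", pat, ".*"), "\\2",
                               fix$INFO[hit]))
    out
  }
  caf <- info_field("AF")
  info <- info_field("R2")
  emp <- colMeans(D) / 2
  caf[is.na(caf)] <- emp[is.na(caf)]
  info[is.na(info)] <- 1
  variants <- data.frame(id = fix$ID, chr = fix$CHROM,
                         pos = as.numeric(fix$POS), coded = fix$ALT,
                         other = fix$REF, caf = caf, info = info,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(D, variants)
  attr(gm, "n_imputed") <- n_imputed
  gm
}

#' Write genotypes to a VCF file with DS dosages
#'
#' Emits a minimal VCFv4.2 file: one biallelic record per variant, `AF`
#' and `R2` INFO keys carrying the coded-allele frequency and info score,
#' and a `GT:DS` FORMAT with dosages rounded to 4 decimals (hard-call GT
#' derived by rounding the dosage).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  D <- genotypes$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Coded allele frequency\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(D)), collapse = "\t")), con)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1]
  for (j in seq_len(nrow(v))) {
    cells <- paste0(gt_of(D[, j]), ":", formatC(D[, j], digits = 4,
                                                format = "f"))
    writeLines(paste(c(v$chr[j], format(v$pos[j], scientific = FALSE),
                       v$id[j], v$other[j], v$coded[j], ".", "PASS",
                       sprintf("AF=%.6f;R2=%.4f", v$caf[j], v$info[j]),
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Published APOE e4 carrier counts by study and subgroup
#'
#' Carrier counts (people with at least one APOE e4 allele) and printed
#' percentages per cognitively defined subgroup, by study and overall, from
#' a published multi-study analysis of 3701 APOE-genotyped people with
#' late-onset Alzheimer's disease. Shipped as a plain-text fixture for
#' cross-checking the package's contingency machinery against published
#' table arithmetic.
#'
#' @return data frame: `study`, `n` (APOE-genotyped people), one
#'   `carriers_<subgroup>` count column per subgroup (NA where the study
#'   had no one in that subgroup), `carriers_overall`, and printed
#'   percentage columns `pct_<subgroup>`, `pct_overall`.
#' @export
apoe_reference_counts <- function() {
  read_tsv_file(system.file("extdata", "apoe_carriers_published.tsv",
                            package = "cogsub", mustWork = TRUE))
}
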