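#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistic table, tolerant of common
#' column-name synonyms: `SNP`/`ID`/`RSID`, `CHR`/`CHROM`, `BP`/`POS`,
#' `A1`/`EA`/`EFFECT_ALLELE`, `A2`/`OA`/`OTHER_ALLELE`,
#' `BETA`/`B`/`OR` (odds ratios are log-transformed), `SE`,
#' `P`/`PVAL`/`P_VALUE`. Case-insensitive.
#'
#' @param path Path to a tab- or comma-delimited file with a header.
#' @return A `gwas_summary` tibble with columns `snp`, `chr`, `bp`,
#'   `a1`, `a2`, `beta`, `se`, `p`.
#' @export
read_gwas_summary <- function(path) {
  raw <- readr::read_delim(path, show_col_types = FALSE)
  nm <- toupper(names(raw))
  pick <- function(...) {
    hit <- match(c(...), nm)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) return(NULL)
    raw[[hit[1]]]
  }
  snp <- pick("SNP", "ID", "RSID", "VARIANT_ID")
  beta <- pick("BETA", "B")
  or <- pick("OR")
  if (is.null(beta) && !is.null(or)) beta <- log(or)
  p <- pick("P", "PVAL", "P_VALUE", "PVALUE")
  a1 <- pick("A1", "EA", "EFFECT_ALLELE")
  a2 <- pick("A2", "OA", "OTHER_ALLELE")
  if (is.null(snp) || is.null(beta) || is.null(p) || is.null(a1) ||
      is.null(a2)) {
    abort("summary file must provide SNP, A1, A2, BETA (or OR) and P columns",
          class = "neuroprs_data_error")
  }
  out <- tibble::tibble(
    snp = as.character(snp),
    chr = as.character(pick("CHR", "CHROM") %||% NA_character_),
    bp = as.integer(pick("BP", "POS", "POSITION") %||% NA_integer_),
    a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
    beta = as.numeric(beta),
    se = as.numeric(pick("SE", "STDERR") %||% NA_real_),
    p = as.numeric(p))
  class(out) <- c("gwas_summary", class(out))
  out
}

#' Write GWAS summary statistics
#'
#' Tab-separated with header `SNP CHR BP A1 A2 BETA SE P`.
#'
#' @param summary A `gwas_summary` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(summary, path) {
  out <- tibble::tibble(SNP = summary$snp, CHR = summary$chr,
                        BP = summary$bp, A1 = summary$a1, A2 = summary$a2,
                        BETA = summary$beta, SE = summary$se,
                        P = summary$p)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a genotype panel as a dosage matrix TSV
#'
#' First columns are variant metadata (`variant_id`, `chrom`, `pos`,
#' `a1`, `a2`), then one dosage column per sample; missing calls are
#' written as `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(panel, path) {
  meta <- panel$variants[c("variant_id", "chrom", "pos", "a1", "a2")]
  dos <- tibble::as_tibble(t(panel$dosage), .name_repair = "minimal")
  names(dos) <- rownames(panel$dosage)
  readr::write_tsv(dplyr::bind_cols(meta, dos), path)
  invisible(path)
}

#' Read a dosage matrix TSV into a genotype panel
#'
#' @param path Path written by [write_dosage_tsv()] (or any TSV with the
#'   same layout).
#' @return A [genotype_panel()].
#' @export
read_dosage_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(meta_cols %in% names(raw))) {
    abort(paste("dosage TSV must start with columns",
                paste(meta_cols, collapse = ", ")),
          class = "neuroprs_data_error")
  }
  samples <- setdiff(names(raw), meta_cols)
  g <- t(as.matrix(raw[samples]))
  colnames(g) <- raw$variant_id
  variants <- raw[meta_cols]
  variants$chrom <- as.character(variants$chrom)
  variants$freq <- colMeans(g, na.rm = TRUE) / 2
  genotype_panel(g, variants)
}

#' Write a genotype panel as VCF
#'
#' Minimal VCFv4.2 with biallelic SNVs, `GT` genotypes (unphased;
#' missing as `./.`) and a `DS` dosage field. REF is the panel's `a2`
#' allele and ALT the counted `a1` allele, so the written dosage counts
#' ALT copies.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  g <- panel$dosage
  gt_map <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    dos <- g[, j]
    gt <- ifelse(is.na(dos), "./.", gt_map[dos + 1])
    ds <- ifelse(is.na(dos), ".", format(dos))
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$a2[j], v$a1[j],
            ".", "PASS", ".", "GT:DS", paste(gt, ds, sep = ":")),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=neuroprs",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage of ALT allele">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Reads biallelic SNVs from a VCF via the vcfR package, counting ALT
#' allele copies from the `GT` field (or the `DS` field when `GT` is
#' absent). Multi-allelic records are dropped with a message.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_panel()] whose counted allele `a1` is ALT.
#' @export
read_vcf_panel <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf)))
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    inform(sprintf("dropping %d multi-allelic record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, ]
  }
  if ("GT" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID ||
      any(grepl("GT", vcf@gt[, 1]))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(s) {
      ifelse(is.na(s) | s %in% c("./.", "."), NA_real_,
             stringr::str_count(s, "1"))
    }
    g <- apply(gt, 2, count_alt)
  } else {
    ds <- vcfR::extract.gt(vcf, element = "DS")
    g <- apply(ds, 2, as.numeric)
  }
  g <- t(g)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  colnames(g) <- ids
  variants <- tibble::tibble(variant_id = ids, chrom = fix$CHROM,
                             pos = as.integer(fix$POS), a1 = fix$ALT,
                             a2 = fix$REF,
                             freq = colMeans(g, na.rm = TRUE) / 2)
  genotype_panel(g, variants)
}

#' Write the cohort table
#'
#' Tab-separated, one row per sample; regional measure columns keep the
#' `<region>_<measure>` layout.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' Read a cohort table
#'
#' @param path Path to a TSV written by [write_cohort_tsv()].
#' @return A tibble.
#' @export
read_cohort_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write the simulation sidecar
#'
#' JSON record of the generator configuration and seed next to the
#' simulated files.
#'
#' @param cfg A [sim_config()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_sim_sidecar <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
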