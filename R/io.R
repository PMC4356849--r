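# Delimited-text and minimal-VCF round trip for cohorts.
#
# Header contract for the phenotype table: subject_id, pts_w1..pts_w3,
# optional cts_i1..cts_i6, cts_total, age, female, pc1, pc2, optional
# true_class. Missing waves are empty fields. Genotypes travel either as a
# dosage table (subject_id + one 0/1/2 column per SNP) or as a minimal VCF
# v4.2 with GT only, oriented so that ALT is the designated minor allele and
# dosage counts ALT copies.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

check_rectangular <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop("malformed rows in ", basename(path), " at line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (expected ", nf[1L], " fields)", call. = FALSE)
}

write_delim_full <- function(df, path, sep) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_full(out[[j]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE)
}

#' Write a cohort to delimited text (and optionally a minimal VCF)
#'
#' @param dataset A `pts_cohort`.
#' @param phenotype_path Path for the phenotype/covariate table.
#' @param genotype_path Optional path for the genotype export; when `NULL`
#'   the dosage columns stay inside the phenotype table.
#' @param genotype_format `"table"` for a dosage table, `"vcf"` for a
#'   minimal GT-only VCF in which ALT is the minor allele.
#' @param sep Field delimiter for delimited outputs.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, phenotype_path, genotype_path = NULL,
                          genotype_format = c("table", "vcf"), sep = ",") {
  genotype_format <- match.arg(genotype_format)
  snps <- attr(dataset, "snp_names")
  df <- as.data.frame(dataset)
  if (!is.null(genotype_path)) {
    dose_cols <- paste0("dosage_", snps)
    geno <- df[, c("subject_id", dose_cols), drop = FALSE]
    df <- df[, setdiff(names(df), dose_cols), drop = FALSE]
    if (genotype_format == "table") {
      write_delim_full(geno, genotype_path, sep)
    } else {
      write_minimal_vcf(geno, snps, genotype_path)
    }
  }
  write_delim_full(df, phenotype_path, sep)
  invisible(c(phenotype_path, genotype_path))
}

write_minimal_vcf <- function(geno, snps, path) {
  gt_code <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
  }
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$subject_id), collapse = "\t"))
  for (j in seq_along(snps)) {
    d <- geno[[paste0("dosage_", snps[j])]]
    lines <- c(lines,
               paste(c("15", as.character(j), snps[j], "A", "C", ".", "PASS",
                       ".", "GT", gt_code(d)), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

read_minimal_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage = number of ALT alleles; ALT is the minor allele by convention
  dose <- apply(gt, c(1L, 2L), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1L]]))
  })
  snps <- v@fix[, "ID"]
  out <- data.frame(subject_id = colnames(gt), stringsAsFactors = FALSE)
  for (j in seq_along(snps)) out[[paste0("dosage_", snps[j])]] <- dose[j, ]
  rownames(out) <- NULL
  out
}

#' Read a cohort from delimited text (and optionally genotypes)
#'
#' The delimiter (comma or tab) is auto-detected from the header line.
#' Ragged rows are reported with their line numbers.
#'
#' @inheritParams write_dataset
#' @return A `pts_cohort`.
#' @export
read_dataset <- function(phenotype_path, genotype_path = NULL,
                         genotype_format = c("table", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  sep <- detect_delim(phenotype_path)
  check_rectangular(phenotype_path, sep)
  df <- utils::read.table(phenotype_path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  if (!is.null(genotype_path)) {
    geno <- if (genotype_format == "table") {
      gsep <- detect_delim(genotype_path)
      check_rectangular(genotype_path, gsep)
      utils::read.table(genotype_path, header = TRUE, sep = gsep,
                        na.strings = c("", "NA"), stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
    } else {
      read_minimal_vcf(genotype_path)
    }
    if (!identical(geno$subject_id, df$subject_id)) {
      idx <- match(df$subject_id, geno$subject_id)
      if (anyNA(idx))
        stop("genotype file lacks subjects: ",
             paste(utils::head(df$subject_id[is.na(idx)], 5L),
                   collapse = ", "), call. = FALSE)
      geno <- geno[idx, , drop = FALSE]
    }
    for (nm in setdiff(names(geno), "subject_id")) df[[nm]] <- geno[[nm]]
  }
  # canonical column order, independent of whether genotypes travelled in a
  # separate file
  lead <- intersect(c("subject_id", "pts_w1", "pts_w2", "pts_w3",
                      paste0("cts_i", 1:6), "cts_total"), names(df))
  dose <- grep("^dosage_", names(df), value = TRUE)
  tail_cols <- intersect(c("age", "female", "pc1", "pc2", "true_class"),
                         names(df))
  rest <- setdiff(names(df), c(lead, dose, tail_cols))
  df <- df[, c(lead, dose, tail_cols, rest), drop = FALSE]
  as_pts_cohort(df)
}
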