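#' Read a dosage matrix from TSV
#'
#' Expected layout: header row of variant ids, first column the sample
#' id, remaining columns numeric dosages in \[0, 2\].
#'
#' @param path file path.
#' @param variants optional variant annotation data frame (id, chrom,
#'   pos) matched by id.
#' @return a [genotype_matrix].
#' @export
read_dosage_tsv <- function(path, variants = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  if (!is.null(variants)) {
    variants <- as.data.frame(variants)
    variants <- variants[match(colnames(dos), variants$id), , drop = FALSE]
  }
  genotype_matrix(dos, sample_ids = as.character(tab[[1]]),
                  variants = variants)
}

#' Write a dosage matrix to TSV
#'
#' @param gm a [genotype_matrix].
#' @param path output path.
#' @export
write_dosage_tsv <- function(gm, path) {
  tab <- data.frame(sample_id = gm$sample_ids, gm$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read dosages from a VCF file
#'
#' Per-sample dosage from the `DS` FORMAT field when present, otherwise
#' the sum of called `GT` alleles.  Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [genotype_matrix].
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0("var_", fix[is.na(ids) | ids == ".", "CHROM"], "_",
           fix[is.na(ids) | ids == ".", "POS"])
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), sample_ids = colnames(dos), variants = variants)
}

#' Write dosages to a minimal VCF with a DS FORMAT field
#'
#' VCF 4.2, one `DS` value per genotype, fixed at 3 decimals (reads back
#' to that precision).
#'
#' @param gm a [genotype_matrix].
#' @param path output path.
#' @export
write_dosage_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")), con)
  v <- gm$variants
  for (j in seq_len(ncol(gm$dosages))) {
    ds <- ifelse(is.na(gm$dosages[, j]), ".",
                 sprintf("%.3f", gm$dosages[, j]))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], "A", "G", ".",
                       "PASS", ".", "DS", ds), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype/covariate table from TSV
#'
#' Columns: `sample_id` plus any of `outcome`, `sbp`, `dbp`, `meds`,
#' `age`, `sex`, `q1`.  If `outcome` is absent it is derived from
#' sbp/dbp/meds via [derive_hypertension()].
#'
#' @param path file path.
#' @return a [phenotype_table].
#' @export
read_phenotype_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("phenotype TSV needs a sample_id column")
  getcol <- function(nm) if (nm %in% names(tab)) tab[[nm]] else NULL
  phenotype_table(sample_ids = tab$sample_id, outcome = getcol("outcome"),
                  age = getcol("age"), sex = getcol("sex"),
                  sbp = getcol("sbp"), dbp = getcol("dbp"),
                  meds = getcol("meds"), q1 = getcol("q1"))
}

#' Write a phenotype table to TSV
#'
#' @param pt a [phenotype_table].
#' @param path output path.
#' @export
write_phenotype_tsv <- function(pt, path) {
  write.table(as.data.frame(pt), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
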