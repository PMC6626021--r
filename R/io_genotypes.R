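#' Validate a genotype dosage table
#'
#' Dosages are stored sample-by-SNP (one row per sample, as in PLINK's
#' `.raw` export) with values 0/1/2 counting alt alleles; missing calls are
#' NA. Optional per-SNP allele labels live in the `alleles` attribute.
#'
#' @param g numeric matrix, samples in rows, SNPs in columns.
#' @param what label used in error messages.
#' @return `g` invisibly.
#' @export
validate_genotypes <- function(g, what = "genotype table") {
  if (!is.matrix(g) || !is.numeric(g))
    stop_fmt("%s must be a numeric matrix (samples x SNPs)", what)
  if (is.null(rownames(g)) || is.null(colnames(g)))
    stop_fmt("%s must have sample row names and SNP column names", what)
  if (anyDuplicated(colnames(g)))
    stop_fmt("%s has duplicate SNP ids", what)
  if (anyDuplicated(rownames(g)))
    stop_fmt("%s has duplicate sample ids", what)
  bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_fmt("%s has dosage %s (must be 0/1/2/NA) at sample '%s', SNP '%s'",
             what, format(g[bad[1, 1], bad[1, 2]]),
             rownames(g)[bad[1, 1]], colnames(g)[bad[1, 2]])
  invisible(g)
}

#' Read a genotype dosage table from TSV
#'
#' First column sample ids, header row SNP ids, cells 0/1/2/NA.
#'
#' @param path file path.
#' @return validated sample-by-SNP dosage matrix.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", "na"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- ids
  validate_genotypes(g, what = sprintf("'%s'", path))
  g
}

#' @rdname read_genotypes
#' @param g dosage matrix.
#' @export
write_genotypes <- function(g, path) {
  validate_genotypes(g)
  out <- data.frame(sample_id = rownames(g), g,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import genotypes from a VCF subset
#'
#' Convenience converter only: alt-allele dosage is read from the GT field
#' of a bi-allelic VCF (via the vcfR parser) and returned as the same
#' sample-by-SNP dosage matrix `read_genotypes()` produces. This is not a
#' general VCF implementation; multi-allelic records are rejected.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return sample-by-SNP dosage matrix.
#' @export
vcf_to_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_fmt("vcf import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop_fmt("multi-allelic records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(a == "1"), numeric(1)))
  }
  d <- apply(gt, 2, count_alt)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(rownames(gt), colnames(gt)))
  g <- t(d)
  colnames(g) <- rownames(gt)
  validate_genotypes(g, what = sprintf("'%s'", path))
  g
}
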