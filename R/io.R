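#' Read genotypes from a plain matrix file or a VCF
#'
#' The plain format is whitespace-delimited minor-allele counts with
#' subjects in rows and a header row of variant IDs.  VCF input (4.x,
#' parsed with VariantAnnotation) converts GT fields of biallelic SNVs to
#' ALT-allele dosages and then recodes any site where the ALT allele is
#' the major allele (sample frequency > 0.5) so that counts always refer
#' to the minor allele; a tie at 0.5 keeps ALT as the counted allele.
#' Missing genotypes are imputed to 0 (non-carrier) with a warning.
#'
#' @param path file path.
#' @param format `"matrix"` or `"vcf"`.
#' @param region_map optional grouping of variants into genes: a
#'   data.frame (or path to a two-column whitespace-delimited file) with
#'   columns `variant_id`, `gene_id`; or, for VCF input, a BED-like
#'   data.frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (0-based half-open intervals).  Without a map all variants form one
#'   set named `"all"`.
#' @param multiallelic `"error"` (default) or `"skip"` for VCF sites with
#'   more than one ALT allele.
#' @return A list of [variant_set] objects.
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf"),
                           region_map = NULL,
                           multiallelic = c("error", "skip")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    geno <- tryCatch(
      as.matrix(read.table(path, header = TRUE, check.names = FALSE)),
      error = function(e) stop("malformed genotype matrix file '", path,
                               "': ", conditionMessage(e)))
    chrom <- pos <- NULL
  } else {
    g <- read_vcf_dosages(path, multiallelic)
    geno <- g$geno; chrom <- g$chrom; pos <- g$pos
  }
  split_into_sets(geno, region_map, chrom, pos)
}

read_vcf_dosages <- function(path, multiallelic) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  nalt <- lengths(VariantAnnotation::alt(vcf))
  multi <- nalt > 1L
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic site(s) at: ",
           paste(utils::head(rownames(gt)[multi], 5), collapse = ", "),
           " (use multiallelic = 'skip' to drop them)")
    vcf <- vcf[!multi]
    gt <- gt[!multi, , drop = FALSE]
  }
  dose <- function(cell) {
    a <- strsplit(cell, "[/|]")[[1]]
    if (any(a == ".") || !length(a)) return(NA_real_)
    sum(a != "0")
  }
  geno <- apply(gt, c(1, 2), dose)
  geno <- t(geno)  # subjects in rows
  if (anyNA(geno)) {
    warning("missing genotypes imputed to 0 (non-carrier)")
    geno[is.na(geno)] <- 0
  }
  # orient to the minor allele per site
  altfreq <- colMeans(geno) / 2
  flip <- altfreq > 0.5
  if (any(flip)) geno[, flip] <- 2 - geno[, flip]
  rr <- SummarizedExperiment::rowRanges(vcf)
  list(geno = geno,
       chrom = as.character(GenomicRanges::seqnames(rr)),
       pos = GenomicRanges::start(rr))
}

split_into_sets <- function(geno, region_map, chrom = NULL, pos = NULL) {
  ids <- colnames(geno)
  if (is.null(ids)) ids <- colnames(geno) <- paste0("v", seq_len(ncol(geno)))
  if (is.null(region_map))
    return(list(variant_set(geno, ids, "all")))
  if (is.character(region_map) && length(region_map) == 1L) {
    region_map <- read.table(region_map, header = FALSE,
                             col.names = c("variant_id", "gene_id"),
                             stringsAsFactors = FALSE)
  }
  region_map <- as.data.frame(region_map)
  if (all(c("chrom", "start", "end", "gene_id") %in% names(region_map))) {
    if (is.null(chrom))
      stop("interval region_map requires VCF input (variant coordinates)")
    map <- do.call(rbind, lapply(seq_len(nrow(region_map)), function(i) {
      hit <- chrom == region_map$chrom[i] &
        pos > region_map$start[i] & pos <= region_map$end[i]
      if (!any(hit)) return(NULL)
      data.frame(variant_id = ids[hit], gene_id = region_map$gene_id[i])
    }))
    if (is.null(map)) return(list())
    region_map <- map
  }
  if (!all(c("variant_id", "gene_id") %in% names(region_map)))
    stop("region_map must have columns variant_id, gene_id")
  lapply(split(region_map$variant_id, region_map$gene_id), function(vv) {
    vv <- intersect(as.character(vv), ids)
    if (!length(vv)) return(NULL)
    variant_set(geno[, vv, drop = FALSE], vv,
                region_map$gene_id[match(vv[1], region_map$variant_id)])
  }) -> sets
  Filter(Negate(is.null), sets)
}

#' Write a genotype matrix file
#'
#' Inverse of [read_genotypes()] for the plain matrix format; the
#' round-trip reproduces genotype entries exactly.
#'
#' @param vs a [variant_set].
#' @param path output file path.
#' @export
write_matrix <- function(vs, path) {
  write.table(vs$geno, path, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a quantitative trait vector
#'
#' One-column whitespace-delimited file with a header line.
#' @param path file path.
#' @return numeric vector.
#' @export
read_phenotype <- function(path) {
  d <- read.table(path, header = TRUE)
  if (ncol(d) != 1L) stop("phenotype file must have exactly one column")
  y <- as.numeric(d[[1]])
  if (anyNA(y) || any(!is.finite(y))) stop("phenotype contains non-finite values")
  y
}

#' Read a covariate matrix
#'
#' Multi-column whitespace-delimited file with a header; no intercept
#' column (the intercept is implicit in the null model).
#' @param path file path.
#' @return numeric matrix (n x q).
#' @export
read_covariates <- function(path) {
  z <- as.matrix(read.table(path, header = TRUE))
  storage.mode(z) <- "double"
  if (anyNA(z)) stop("covariates contain missing values")
  if (ncol(z) >= 1L && qr(cbind(1, z))$rank < ncol(z) + 1L)
    stop("covariate matrix is rank deficient (with implicit intercept)")
  z
}
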