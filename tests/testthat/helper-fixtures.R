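# in-code fixtures shared across test files

toy_variant_set <- function() {
  variant_set(rbind(c(0, 1), c(2, 0), c(0, 0)),
              variant_ids = c("rs1", "rs2"), set_id = "toy")
}

# small random dataset with a fixed seed
random_dataset <- function(seed, n = 40, k = 4, maf = 0.1, covar = FALSE) {
  set.seed(seed)
  geno <- matrix(rbinom(n * k, 2, maf), n, k)
  geno[1, colSums(geno) == 0] <- 1  # ensure polymorphic
  x <- variant_set(geno, set_id = "rand")
  z <- if (covar) matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n) + if (covar) z %*% c(1, -1) else 0
  list(x = x, y = as.numeric(y), z = z)
}

write_temp_matrix <- function(geno, ids = colnames(geno)) {
  f <- tempfile(fileext = ".txt")
  colnames(geno) <- ids
  write.table(geno, f, quote = FALSE, row.names = FALSE)
  f
}

# minimal single-sample-block VCF text fixture
write_temp_vcf <- function(rows, samples = c("s1", "s2", "s3")) {
  f <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=1000000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), f)
  f
}

vcf_row <- function(pos, id, gts, ref = "A", alt = "T") {
  paste(c("1", pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
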