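#' Variant set container
#'
#' A `variant_set` holds the genotype matrix of one gene or region as
#' minor-allele counts (0, 1, or 2) for `n` subjects by `k` variants,
#' together with per-variant minor-allele counts (MAC, the column sums)
#' and sample minor-allele frequencies (MAF = MAC / 2n).
#'
#' @param geno integer-valued matrix, subjects in rows, variants in columns;
#'   every entry must be 0, 1 or 2.
#' @param variant_ids optional character vector of variant names (defaults to
#'   the matrix column names or `v1..vk`).
#' @param set_id name of the gene/region.
#' @return An object of class `variant_set` with elements `geno`,
#'   `variant_ids`, `macs`, `mafs`, `set_id`.
#' @examples
#' vs <- variant_set(rbind(c(0, 1), c(2, 0), c(0, 0)))
#' vs$macs  # 2 1
#' @export
variant_set <- function(geno, variant_ids = NULL, set_id = "set1") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (nrow(geno) < 2L) stop("a variant set needs at least 2 subjects")
  if (ncol(geno) < 1L) stop("a variant set needs at least 1 variant")
  if (anyNA(geno)) {
    warning("missing genotypes imputed to 0 (non-carrier)")
    geno[is.na(geno)] <- 0
  }
  if (!all(geno %in% c(0, 1, 2)))
    stop("genotypes must be minor-allele counts in {0, 1, 2}")
  if (is.null(variant_ids)) {
    variant_ids <- colnames(geno)
    if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(geno)))
  }
  if (length(variant_ids) != ncol(geno))
    stop("variant_ids length must match the number of genotype columns")
  colnames(geno) <- variant_ids
  macs <- colSums(geno)
  structure(
    list(geno = geno, variant_ids = variant_ids, macs = macs,
         mafs = macs / (2 * nrow(geno)), set_id = as.character(set_id)),
    class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set '%s': %d subjects x %d variants, cumulative MAC %d\n",
              x$set_id, nrow(x$geno), ncol(x$geno), as.integer(sum(x$macs))))
  invisible(x)
}

#' @export
dim.variant_set <- function(x) dim(x$geno)

#' Drop monomorphic variants from a set
#'
#' Variants with MAC = 0 carry no information for any score-based test
#' (their score component is identically zero); they are removed before
#' testing.  Returns `NULL` when no polymorphic variant remains.
#'
#' @param vs a [variant_set].
#' @param quiet suppress the warning about dropped columns.
#' @return A reduced `variant_set`, or `NULL` if all variants are monomorphic.
#' @export
drop_monomorphic <- function(vs, quiet = FALSE) {
  keep <- vs$macs > 0
  if (all(keep)) return(vs)
  if (!any(keep)) {
    if (!quiet) warning(sprintf("set '%s': all variants monomorphic; set skipped",
                                vs$set_id))
    return(NULL)
  }
  if (!quiet)
    warning(sprintf("set '%s': dropped %d monomorphic variant(s)",
                    vs$set_id, sum(!keep)))
  variant_set(vs$geno[, keep, drop = FALSE], vs$variant_ids[keep], vs$set_id)
}

#' Filter variant sets by MAF and cumulative MAC
#'
#' Two-stage rare-variant filter used for gene-based testing: within each
#' set, variants with sample MAF above `variant_maf_max` are removed
#' (default 1%, the usual "rare" cutoff); then sets whose remaining
#' cumulative MAC falls below `set_mac_min` (default 5) are dropped
#' entirely, since a handful of minor alleles cannot support a set test.
#'
#' @param sets a list of [variant_set] objects (a single `variant_set` is
#'   accepted and wrapped).
#' @param variant_maf_max per-variant MAF ceiling (fraction).
#' @param set_mac_min minimum cumulative minor-allele count per set.
#' @return The surviving list of `variant_set` objects (possibly empty).
#' @export
filter_by_mac <- function(sets, variant_maf_max = 0.01, set_mac_min = 5) {
  if (inherits(sets, "variant_set")) sets <- list(sets)
  out <- list()
  for (vs in sets) {
    keep <- vs$mafs <= variant_maf_max
    if (!any(keep)) next
    vs2 <- variant_set(vs$geno[, keep, drop = FALSE],
                       vs$variant_ids[keep], vs$set_id)
    if (sum(vs2$macs) >= set_mac_min) out[[length(out) + 1L]] <- vs2
  }
  out
}
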