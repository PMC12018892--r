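#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes for a set of samples as a samples x sites
#' matrix of minor/alternate allele dosages: 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate), `NA` (missing call).
#' Optionally carries a matching read-depth matrix and a population label
#' per sample.
#'
#' @param geno integer matrix, samples in rows (rownames are sample ids),
#'   sites in columns, values in `{0, 1, 2, NA}`.
#' @param sites data frame with one row per site and columns `chrom`, `pos`,
#'   `ref`, `alt`; sites must be biallelic SNPs (single, distinct bases) and
#'   unique per `(chrom, pos)`.
#' @param depth optional integer matrix of per-genotype read depths with the
#'   same dimensions as `geno`.
#' @param pops optional character vector of population labels, one per
#'   sample (named by sample id or in sample order).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, depth = NULL, pops = NULL) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) {
    stop("'geno' must have sample ids as rownames")
  }
  if (!is.data.frame(sites)) {
    stop("'sites' must be a data frame")
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("'sites' needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(sites) != ncol(geno)) {
    stop("dimension mismatch: ", ncol(geno), " genotype columns vs ",
         nrow(sites), " site rows")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases)) {
    stop("sites must be SNPs with single-base ref and alt")
  }
  if (any(sites$ref == sites$alt)) {
    stop("ref and alt alleles must differ at every site")
  }
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    stop("duplicated (chrom, pos) in 'sites'")
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (!is.null(depth)) {
    if (!is.matrix(depth)) depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(geno))) {
      stop("'depth' must have the same dimensions as 'geno'")
    }
    if (any(depth < 0L, na.rm = TRUE)) stop("depths must be non-negative")
    rownames(depth) <- rownames(geno)
  }
  if (!is.null(pops)) {
    if (is.null(names(pops))) {
      if (length(pops) != nrow(geno)) {
        stop("'pops' must have one label per sample")
      }
      names(pops) <- rownames(geno)
    }
    pops <- pops[rownames(geno)]
    if (anyNA(names(pops))) stop("'pops' names must match sample ids")
  }
  rownames(sites) <- NULL
  structure(
    list(geno = geno, sites = sites, depth = depth, pops = pops),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Sample identifiers of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return Character vector of sample ids.
#' @export
gm_samples <- function(gm) rownames(gm$geno)

#' Number of sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return Integer count of sites.
#' @export
gm_n_sites <- function(gm) ncol(gm$geno)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (ids, logical or integer).
#' @param j site index (logical or integer).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the selected samples and sites.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genotype_matrix(
    x$geno[i, j, drop = FALSE],
    x$sites[j, , drop = FALSE],
    depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
    pops = if (!is.null(x$pops)) x$pops[i]
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno)) * 100
  cat(sprintf(
    "<genotype_matrix> %d samples x %d biallelic SNP sites (%.1f%% missing)%s\n",
    nrow(x$geno), ncol(x$geno), miss,
    if (is.null(x$depth)) "" else ", with depths"
  ))
  invisible(x)
}
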