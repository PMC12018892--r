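#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF (v4.x) with `vcfR`, keeps only biallelic SNP records and
#' encodes genotypes as alternate-allele dosages (0/1/2, `NA` for missing).
#' Multi-allelic and non-SNP records (indels, spanning deletions) are dropped
#' and their count reported via a message. Per-genotype `DP` values are kept
#' when present.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param pops optional population labels passed through to
#'   [genotype_matrix()].
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, pops = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " non-biallelic or non-SNP record(s) dropped")
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  gt_chr <- gsub("|", "/", gt, fixed = TRUE)
  code[gt_chr %in% c("0/0")] <- 0L
  code[gt_chr %in% c("0/1", "1/0")] <- 1L
  code[gt_chr %in% c("1/1")] <- 2L

  depth <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    )
    depth <- t(dp)
  }

  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(code), sites, depth = depth, pops = pops)
}

#' Write a genotype matrix as plain-text VCF v4.2
#'
#' Emits GT (and DP when depths are present) fields; missing genotypes are
#' written as `./.`. The output round-trips through [read_vcf()] without loss
#' of genotype codes or depths.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_map <- c("0/0", "0/1", "1/1")
  g <- t(gm$geno) # sites x samples
  body <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  body[ok] <- gt_map[g[ok] + 1L]
  fmt <- "GT"
  if (!is.null(gm$depth)) {
    d <- t(gm$depth)
    d_chr <- ifelse(is.na(d), ".", as.character(d))
    body <- matrix(paste(body, d_chr, sep = ":"),
                   nrow = nrow(g), ncol = ncol(g))
    fmt <- "GT:DP"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nestkin",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(gm$depth))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm_samples(gm)), collapse = "\t")
  )
  lines <- paste(
    gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    ".", "PASS", ".", fmt,
    apply(body, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Site and genotype filter thresholds
#'
#' Defaults mirror a standard reduced-representation SNP cleaning recipe:
#' per-genotype and per-site mean depth within \[10, 120\] (inclusive), at
#' most 20% missing calls per site, locus genotyped in at least 60% of the
#' individuals of at least one population, and minor allele frequency of at
#' least 0.05.
#'
#' @param maf_min minimum minor allele frequency (keep sites with MAF >=
#'   `maf_min`); in `(0, 0.5]`.
#' @param max_missing maximum fraction of samples allowed missing per site;
#'   in `[0, 1)`.
#' @param dp_min,dp_max inclusive depth bounds applied both per genotype and
#'   to per-site mean depth. Use `NULL` for either to skip depth filtering.
#' @param locus_presence_r minimum fraction of individuals (within at least
#'   one population) a site must be genotyped in.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(maf_min = 0.05, max_missing = 0.2,
                        dp_min = 10, dp_max = 120,
                        locus_presence_r = 0.6) {
  if (!(maf_min > 0 && maf_min <= 0.5)) stop("'maf_min' must be in (0, 0.5]")
  if (!(max_missing >= 0 && max_missing < 1)) {
    stop("'max_missing' must be in [0, 1)")
  }
  if (!is.null(dp_min) && !is.null(dp_max) && dp_min > dp_max) {
    stop("'dp_min' must not exceed 'dp_max'")
  }
  if (!(locus_presence_r >= 0 && locus_presence_r <= 1)) {
    stop("'locus_presence_r' must be in [0, 1]")
  }
  structure(
    list(maf_min = maf_min, max_missing = max_missing,
         dp_min = dp_min, dp_max = dp_max,
         locus_presence_r = locus_presence_r),
    class = "filter_spec"
  )
}

#' Apply depth, missingness and allele-frequency filters
#'
#' The order of operations is fixed and matters: (1) genotypes whose depth
#' falls outside `[dp_min, dp_max]` are set missing; (2) sites whose mean
#' depth falls outside the same bounds are dropped; (3) sites failing the
#' locus-presence rule or exceeding the missingness ceiling are dropped;
#' (4) sites with minor allele frequency below `maf_min`, computed on the
#' calls remaining after depth masking, are dropped. Allele frequency is the
#' minor allele's, irrespective of ref/alt orientation.
#'
#' @param gm a [genotype_matrix()].
#' @param spec a [filter_spec()].
#' @return A list of class `filtered_genotypes` with elements `gm` (the
#'   filtered [genotype_matrix()]) and `report` (a `filter_report` data frame
#'   of per-step removal counts).
#' @export
apply_filters <- function(gm, spec = filter_spec()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "filter_spec"))
  use_depth <- !is.null(spec$dp_min) && !is.null(spec$dp_max)
  if (use_depth && is.null(gm$depth)) {
    stop("depth filters requested but 'gm' has no depth matrix")
  }
  geno <- gm$geno
  depth <- gm$depth
  n_in <- ncol(geno)

  # step 1: per-genotype depth masking
  masked <- 0L
  if (use_depth) {
    bad <- !is.na(geno) & !is.na(depth) &
      (depth < spec$dp_min | depth > spec$dp_max)
    masked <- sum(bad)
    geno[bad] <- NA_integer_
  }

  # step 2: site mean depth
  drop2 <- rep(FALSE, ncol(geno))
  if (use_depth) {
    mean_dp <- colMeans(depth, na.rm = TRUE)
    drop2 <- is.nan(mean_dp) | mean_dp < spec$dp_min | mean_dp > spec$dp_max
  }
  keep <- which(!drop2)
  geno <- geno[, keep, drop = FALSE]
  depth <- if (!is.null(depth)) depth[, keep, drop = FALSE]
  sites <- gm$sites[keep, , drop = FALSE]

  # step 3: locus presence and missingness
  present <- colMeans(!is.na(geno))
  pass_r <- if (is.null(gm$pops)) {
    present >= spec$locus_presence_r
  } else {
    pop_levels <- unique(gm$pops)
    pres_pop <- vapply(pop_levels, function(p) {
      colMeans(!is.na(geno[gm$pops == p, , drop = FALSE]))
    }, numeric(ncol(geno)))
    if (is.null(dim(pres_pop))) pres_pop <- matrix(pres_pop, nrow = 1)
    apply(pres_pop >= spec$locus_presence_r, 1L, any)
  }
  drop3 <- !(pass_r & (1 - present) <= spec$max_missing)
  keep <- which(!drop3)
  geno <- geno[, keep, drop = FALSE]
  depth <- if (!is.null(depth)) depth[, keep, drop = FALSE]
  sites <- sites[keep, , drop = FALSE]

  # step 4: minor allele frequency on remaining calls
  p_alt <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  drop4 <- is.nan(maf) | maf < spec$maf_min
  keep <- which(!drop4)
  geno <- geno[, keep, drop = FALSE]
  depth <- if (!is.null(depth)) depth[, keep, drop = FALSE]
  sites <- sites[keep, , drop = FALSE]

  if (ncol(geno) == 0L) warning("no sites survived filtering")
  report <- data.frame(
    step = c("genotype_depth_mask", "site_mean_depth", "presence_missingness",
             "minor_allele_frequency"),
    unit = c("genotypes", "sites", "sites", "sites"),
    removed = c(masked, sum(drop2), sum(drop3), sum(drop4)),
    stringsAsFactors = FALSE
  )
  attr(report, "sites_in") <- n_in
  attr(report, "sites_out") <- ncol(geno)
  class(report) <- c("filter_report", "data.frame")
  out <- genotype_matrix(geno, sites, depth = depth, pops = gm$pops)
  structure(list(gm = out, report = report), class = "filtered_genotypes")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d -> %d sites\n",
              attr(x, "sites_in"), attr(x, "sites_out")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-sample heterozygosity
#'
#' Fraction of heterozygous calls among a sample's non-missing calls,
#' reported as a percentage. Samples with no called genotypes get `NA` and a
#' warning.
#'
#' @param gm a [genotype_matrix()].
#' @return Named numeric vector of percentages, one per sample.
#' @export
sample_heterozygosity <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  called <- rowSums(!is.na(gm$geno))
  het <- rowSums(gm$geno == 1L, na.rm = TRUE)
  out <- 100 * het / called
  if (any(called == 0L)) {
    warning("sample(s) with no called genotypes: ",
            paste(gm_samples(gm)[called == 0L], collapse = ", "))
    out[called == 0L] <- NA_real_
  }
  setNames(out, gm_samples(gm))
}
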