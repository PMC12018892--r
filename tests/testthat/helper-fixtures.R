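# Small in-code fixtures shared across tests.

toy_gm <- function(geno, depth = NULL, pops = NULL) {
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%02d", seq_len(nrow(geno)))
  }
  sites <- data.frame(
    chrom = "chr1", pos = seq_len(ncol(geno)) * 10L,
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotype_matrix(geno, sites, depth = depth, pops = pops)
}

# a 20-site, 8-sample matrix with planted filter violations:
#   sites 1-2: site mean depth out of bounds (low / high)
#   sites 3-4: enough low-depth genotypes to fail presence after masking
#   sites 5-6: too many missing calls as given
#   sites 7-8: minor allele frequency below 0.05
#   sites 9-20: clean
planted_filter_gm <- function() {
  set.seed(7)
  n_s <- 8L
  n_j <- 20L
  geno <- matrix(sample(0:2, n_s * n_j, replace = TRUE), n_s, n_j)
  depth <- matrix(50L, n_s, n_j)
  depth[, 1] <- 5L
  depth[, 2] <- 150L
  depth[1:4, 3] <- 2L
  depth[1:4, 4] <- 200L
  geno[1:4, 5] <- NA
  geno[1:4, 6] <- NA
  geno[, 7] <- 0L
  geno[, 8] <- 2L
  geno[, 9:20] <- rep(c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L), 12) # MAF 0.5-ish
  rownames(geno) <- sprintf("S%02d", 1:n_s)
  toy_gm(geno, depth = depth)
}

# truth pair-relationship masks (full-sib / half-sib / unrelated) for a set
# of hatchling ids
truth_pair_masks <- function(truth, ids) {
  i <- match(ids, truth$hatchlings$sample_id)
  same_m <- outer(truth$hatchlings$mother_id[i], truth$hatchlings$mother_id[i],
                  "==")
  same_f <- outer(truth$hatchlings$father_id[i], truth$hatchlings$father_id[i],
                  "==")
  ut <- upper.tri(same_m)
  list(
    fs = same_m & same_f & ut,
    hs = xor(same_m, same_f) & ut,
    ur = !same_m & !same_f & ut
  )
}
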