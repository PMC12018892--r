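# Independent oracles used across tests. These deliberately re-derive
# quantities by exhaustive enumeration or plain loops, independent of the
# package's closed forms and vectorized implementations.

# E[per-site IBS | pair shares `state` alleles identical by descent] at
# allele frequency p, by enumeration over all 9 genotype-pair combinations
# weighted by Hardy-Weinberg proportions and Mendelian transmission.
enum_ibs_expectation <- function(p, state) {
  q <- 1 - p
  hwe <- c(q^2, 2 * p * q, p^2) # genotypes 0, 1, 2
  joint <- matrix(0, 3, 3)
  if (state == 0) {
    joint <- outer(hwe, hwe)
  } else if (state == 1) {
    for (a in 0:1) {
      for (b in 0:1) {
        for (cc in 0:1) {
          pr <- (if (a) p else q) * (if (b) p else q) * (if (cc) p else q)
          joint[a + b + 1, a + cc + 1] <- joint[a + b + 1, a + cc + 1] + pr
        }
      }
    }
  } else if (state == 2) {
    for (g in 0:2) joint[g + 1, g + 1] <- hwe[g + 1]
  } else {
    stop("state must be 0, 1 or 2")
  }
  score <- 1 - abs(outer(0:2, 0:2, "-")) / 2
  sum(joint * score)
}

# expected normalized IBS under Cotterman k = c(k0, k1, k2), built purely
# from the enumeration above (baseline = unrelated expectation)
enum_expected_normalized <- function(k, freqs) {
  e0 <- vapply(freqs, enum_ibs_expectation, numeric(1), state = 0)
  e1 <- vapply(freqs, enum_ibs_expectation, numeric(1), state = 1)
  e2 <- vapply(freqs, enum_ibs_expectation, numeric(1), state = 2)
  e_raw <- mean(k[1] * e0 + k[2] * e1 + k[3] * e2)
  (e_raw - mean(e0)) / (1 - mean(e0))
}

# brute-force re-implementation of the filtering order with plain loops
brute_filter_counts <- function(geno, depth, spec) {
  removed <- c(0L, 0L, 0L, 0L)
  for (i in seq_len(nrow(geno))) {
    for (j in seq_len(ncol(geno))) {
      if (!is.na(geno[i, j]) &&
          (depth[i, j] < spec$dp_min || depth[i, j] > spec$dp_max)) {
        geno[i, j] <- NA
        removed[1] <- removed[1] + 1L
      }
    }
  }
  keep <- rep(TRUE, ncol(geno))
  for (j in seq_len(ncol(geno))) {
    md <- mean(depth[, j])
    if (md < spec$dp_min || md > spec$dp_max) {
      keep[j] <- FALSE
      removed[2] <- removed[2] + 1L
    }
  }
  for (j in which(keep)) {
    pres <- mean(!is.na(geno[, j]))
    if (pres < spec$locus_presence_r || (1 - pres) > spec$max_missing) {
      keep[j] <- FALSE
      removed[3] <- removed[3] + 1L
    }
  }
  for (j in which(keep)) {
    calls <- geno[, j][!is.na(geno[, j])]
    p <- sum(calls) / (2 * length(calls))
    if (length(calls) == 0 || min(p, 1 - p) < spec$maf_min) {
      keep[j] <- FALSE
      removed[4] <- removed[4] + 1L
    }
  }
  list(surviving = sum(keep), removed = removed)
}
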