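#' Pairwise identity-by-state of two genotype vectors
#'
#' Per-site score: 1 when the two genotypes are identical (including
#' heterozygote vs heterozygote), 0.5 when they share one allele
#' (heterozygote vs either homozygote), 0 for opposite homozygotes. The IBS
#' of the pair is the mean score over sites where both calls are present.
#'
#' @param g1,g2 genotype vectors coded 0/1/2 with `NA` for missing.
#' @param min_overlap minimum number of jointly called sites required.
#' @return The raw IBS scalar in `[0, 1]`.
#' @export
ibs_pair <- function(g1, g2, min_overlap = 100L) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < min_overlap) {
    stop("insufficient overlap: ", n, " jointly called sites (need >= ",
         min_overlap, ")")
  }
  mean(1 - abs(g1[ok] - g2[ok]) / 2)
}

#' Raw IBS matrix over all sample pairs
#'
#' Computes the full symmetric pairwise IBS matrix with pairwise-complete
#' site sets (sites missing in either member of a pair are excluded for that
#' pair only) together with the per-pair overlap counts. Pairs with overlap
#' below `min_overlap` are masked `NA` with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @inheritParams ibs_pair
#' @return List with `raw` (samples x samples IBS matrix, unit diagonal) and
#'   `n_overlap` (matrix of jointly called site counts).
#' @export
ibs_matrix <- function(gm, min_overlap = 100L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  if (nrow(g) < 2L) stop("need at least 2 samples")
  h0 <- (!is.na(g) & g == 0L) * 1
  h1 <- (!is.na(g) & g == 1L) * 1
  h2 <- (!is.na(g) & g == 2L) * 1
  called <- h0 + h1 + h2
  same <- tcrossprod(h0) + tcrossprod(h1) + tcrossprod(h2)
  opp <- tcrossprod(h0, h2)
  opp <- opp + t(opp)
  n_ov <- tcrossprod(called)
  score <- same + 0.5 * (n_ov - same - opp)
  raw <- score / n_ov
  diag(raw) <- 1
  low <- n_ov < min_overlap
  diag(low) <- FALSE
  if (any(low)) {
    warning(sum(low) / 2, " pair(s) below the minimum overlap of ",
            min_overlap, " sites; masked NA")
    raw[low] <- NA_real_
  }
  ids <- gm_samples(gm)
  dimnames(raw) <- dimnames(n_ov) <- list(ids, ids)
  list(raw = raw, n_overlap = n_ov)
}

#' Baseline constant from the two most distinct groups
#'
#' For every unordered pair of groups (families or nests) computes the mean
#' raw IBS over all cross-group sample pairs and returns the smallest such
#' mean: the average identity between the two least related groups in the
#' dataset. Ties are broken by lexicographic group-label order and reported
#' via a message.
#'
#' @param raw symmetric raw IBS matrix with sample ids as dimnames.
#' @param groups group label per sample (named by sample id, or in matrix
#'   order).
#' @return List with `av_min`, `groups` (the chosen pair of labels) and
#'   `pair_means` (a data frame of all cross-group means).
#' @export
baseline_av_min <- function(raw, groups) {
  ids <- rownames(raw)
  if (!is.null(names(groups))) groups <- groups[ids]
  groups <- as.character(groups)
  if (length(groups) != nrow(raw) || anyNA(groups)) {
    stop("'groups' must label every sample in 'raw'")
  }
  levs <- sort(unique(groups))
  if (length(levs) < 2L) {
    stop("baseline requires >= 2 groups; supply 'av_min' explicitly instead")
  }
  pairs <- combn(levs, 2L)
  means <- apply(pairs, 2L, function(p) {
    mean(raw[groups == p[1L], groups == p[2L]], na.rm = TRUE)
  })
  pm <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], mean = means,
                   stringsAsFactors = FALSE)
  pm <- pm[order(pm$mean, pm$group1, pm$group2), ]
  if (sum(pm$mean == pm$mean[1L]) > 1L) {
    message("tie for least related group pair; broken lexicographically (",
            pm$group1[1L], ", ", pm$group2[1L], ")")
  }
  list(av_min = pm$mean[1L],
       groups = c(pm$group1[1L], pm$group2[1L]),
       pair_means = pm)
}

#' Rescale raw IBS to the normalized-IBS statistic
#'
#' Elementwise `(raw - av_min) / (1 - av_min)`, mapping the unrelated
#' baseline to 0 and identity to 1. Values below the baseline come out
#' negative and are deliberately not clipped.
#'
#' @param raw raw IBS matrix (or scalar/vector).
#' @param av_min baseline constant, strictly below 1.
#' @return Normalized values with the same shape as `raw`.
#' @export
normalize_ibs <- function(raw, av_min) {
  if (!is.numeric(av_min) || length(av_min) != 1L || is.na(av_min)) {
    stop("'av_min' must be a single number")
  }
  if (av_min >= 1) stop("degenerate baseline: av_min >= 1")
  (raw - av_min) / (1 - av_min)
}

#' Normalized-IBS analysis of a genotype matrix
#'
#' Convenience wrapper chaining [ibs_matrix()], [baseline_av_min()] and
#' [normalize_ibs()]. The baseline may be frozen by supplying `av_min`
#' explicitly (e.g. to compare values across dataset contexts).
#'
#' @param gm a [genotype_matrix()].
#' @param groups group label per sample (family or nest), used to choose the
#'   baseline pair; required unless `av_min` is given.
#' @param av_min optional explicit baseline constant.
#' @inheritParams ibs_pair
#' @return An object of class `normalized_ibs` with elements `raw`,
#'   `normalized`, `n_overlap`, `av_min`, `baseline_groups` and `groups`.
#' @export
normalized_ibs <- function(gm, groups = NULL, av_min = NULL,
                           min_overlap = 100L) {
  ib <- ibs_matrix(gm, min_overlap = min_overlap)
  baseline_groups <- NULL
  if (is.null(av_min)) {
    if (is.null(groups)) stop("supply 'groups' or an explicit 'av_min'")
    bl <- baseline_av_min(ib$raw, groups)
    av_min <- bl$av_min
    baseline_groups <- bl$groups
  }
  if (!is.null(groups) && !is.null(names(groups))) {
    groups <- groups[rownames(ib$raw)]
  }
  structure(
    list(raw = ib$raw, normalized = normalize_ibs(ib$raw, av_min),
         n_overlap = ib$n_overlap, av_min = av_min,
         baseline_groups = baseline_groups, groups = groups),
    class = "normalized_ibs"
  )
}

#' @export
print.normalized_ibs <- function(x, ...) {
  cat(sprintf("<normalized_ibs> %d samples, av.min = %.4f", nrow(x$raw),
              x$av_min))
  if (!is.null(x$baseline_groups)) {
    cat(" (baseline groups: ", paste(x$baseline_groups, collapse = " / "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Standard relationship models (Cotterman coefficients)
#'
#' @return Data frame with columns `name`, `k0`, `k1`, `k2`: probabilities of
#'   a pair sharing 0, 1 or 2 alleles identical by descent.
#' @export
relationship_models <- function() {
  data.frame(
    name = c("unrelated", "parent-offspring", "full-sib", "half-sib",
             "avuncular", "first-cousin"),
    k0 = c(1, 0, 0.25, 0.5, 0.5, 0.75),
    k1 = c(0, 1, 0.5, 0.5, 0.5, 0.25),
    k2 = c(0, 0, 0.25, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Expected normalized IBS under a relationship model
#'
#' Closed form derived from the per-site conditional expectations
#' `E[IBS | 2 IBD] = 1`, `E[IBS | 1 IBD] = 1 - pq` and
#' `E[IBS | 0 IBD] = 0.5 * (1 + (1 - 2pq)^2)` under Hardy-Weinberg
#' proportions, with the baseline taken as the unrelated expectation:
#' `k2 + k1 * nbar1`, where
#' `nbar1 = sum(pq (1 - 2pq)) / sum(2pq (1 - pq))` over sites.
#'
#' @param model either a model name from [relationship_models()] or a numeric
#'   vector `c(k0, k1, k2)` summing to 1.
#' @param freqs vector of per-site allele frequencies, all in `(0, 1)`.
#' @return Expected normalized-IBS scalar.
#' @export
expected_normalized_ibs <- function(model, freqs) {
  if (is.character(model)) {
    tab <- relationship_models()
    row <- match(model, tab$name)
    if (is.na(row)) stop("unknown relationship model: ", model)
    k <- c(tab$k0[row], tab$k1[row], tab$k2[row])
  } else {
    k <- as.numeric(model)
    if (length(k) != 3L || abs(sum(k) - 1) > 1e-9 || any(k < 0)) {
      stop("'model' must be c(k0, k1, k2) with k0 + k1 + k2 = 1")
    }
  }
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)")
  }
  pq <- freqs * (1 - freqs)
  nbar1 <- sum(pq * (1 - 2 * pq)) / sum(2 * pq * (1 - pq))
  unname(k[3L] + k[2L] * nbar1)
}

#' Kinship classification bands
#'
#' Default bands sit between the mean normalized-IBS values observed for the
#' kinship degrees in a calibration dataset of known families; there is no
#' universal threshold, so all three cut points are configurable.
#'
#' @param fs lower bound of the full-sibling band.
#' @param hs lower bound of the half-sibling band.
#' @param distant lower bound of the distant-kin band.
#' @param ambiguity_margin half-width around each boundary within which a
#'   value is flagged ambiguous.
#' @return An object of class `kinship_bands`.
#' @export
kinship_bands <- function(fs = 0.38, hs = 0.15, distant = 0.05,
                          ambiguity_margin = 0.03) {
  if (!(fs > hs && hs > distant)) {
    stop("bands must be ordered: fs > hs > distant")
  }
  structure(
    list(fs = fs, hs = hs, distant = distant,
         ambiguity_margin = ambiguity_margin),
    class = "kinship_bands"
  )
}

#' Classify normalized-IBS values into kinship bands
#'
#' @param x numeric vector of normalized-IBS values.
#' @param bands a [kinship_bands()].
#' @return Character vector of band labels (`"full-sib"`, `"half-sib"`,
#'   `"distant"`, `"unrelated"`) with an `"ambiguous"` logical attribute
#'   marking values within the ambiguity margin of a boundary.
#' @export
classify_kinship <- function(x, bands = kinship_bands()) {
  stopifnot(inherits(bands, "kinship_bands"))
  lab <- ifelse(x >= bands$fs, "full-sib",
         ifelse(x >= bands$hs, "half-sib",
         ifelse(x >= bands$distant, "distant", "unrelated")))
  cuts <- c(bands$fs, bands$hs, bands$distant)
  amb <- vapply(x, function(v) any(abs(v - cuts) < bands$ambiguity_margin),
                logical(1L))
  attr(lab, "ambiguous") <- amb
  lab
}

# mean of pairwise values over all within-group pairs (groups with >= 2
# members); 'idx_by_group' is a list of integer index vectors.
.within_group_mean <- function(mat, idx_by_group) {
  tot <- 0
  n <- 0
  for (idx in idx_by_group) {
    k <- length(idx)
    if (k < 2L) next
    sub <- mat[idx, idx]
    tot <- tot + (sum(sub) - sum(diag(sub))) / 2
    n <- n + k * (k - 1L) / 2
  }
  if (n == 0L) stop("no group has >= 2 members")
  tot / n
}

#' Permutation confidence interval for a within-group mean
#'
#' Pairwise kinship values are not independent, so significance of an
#' observed within-group mean is assessed by permutation: sample labels are
#' randomly reassigned to groups of the same sizes, the within-group mean is
#' recomputed for each permutation, and the empirical 2.5/97.5 percentiles of
#' the permuted means form a 95% confidence interval for the null of no
#' group structure.
#'
#' @param mat symmetric matrix of pairwise (normalized IBS) values.
#' @param groups group label per sample (named by sample id, or in matrix
#'   order); groups of size 1 contribute no pairs.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for reproducibility.
#' @param conf confidence level.
#' @return An object of class `permutation_ci` with the observed mean, the
#'   interval, the permuted means and a `significant` flag (observed outside
#'   the interval).
#' @export
permutation_ci <- function(mat, groups, n_perm = 1000L, seed = NULL,
                           conf = 0.95) {
  if (!is.null(names(groups))) groups <- groups[rownames(mat)]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(mat))
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  if (n_perm < 100L) warning("n_perm < 100: percentile estimates unstable")
  if (!is.null(seed)) set.seed(seed)
  split_idx <- split(seq_along(groups), groups)
  sizes <- lengths(split_idx)
  observed <- .within_group_mean(mat, split_idx)
  n <- length(groups)
  perm_means <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(n)
    off <- 0L
    idx <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      idx[[i]] <- perm[(off + 1L):(off + sizes[i])]
      off <- off + sizes[i]
    }
    .within_group_mean(mat, idx)
  }, numeric(1L))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(perm_means, c(alpha, 1 - alpha)))
  structure(
    list(observed = observed, ci_low = ci[1L], ci_high = ci[2L],
         significant = observed < ci[1L] || observed > ci[2L],
         n_perm = n_perm, seed = seed, perm_means = perm_means),
    class = "permutation_ci"
  )
}

#' @export
print.permutation_ci <- function(x, ...) {
  cat(sprintf(
    "<permutation_ci> observed %.4f, 95%% CI [%.4f, %.4f] (%d permutations)%s\n",
    x$observed, x$ci_low, x$ci_high, x$n_perm,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}
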