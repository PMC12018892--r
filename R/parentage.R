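# Hatchling-only reconstruction of mothers, fathers and mating events.
#
# Rule order (applied after sibship clustering):
#   R1  all hatchlings in one nest share the mother (one female per nest)
#   R2  a full-sib group spanning nests implies the same mother AND father
#       for those nests (the same female returning, sperm storage)
#   R3  a half-sib link within a nest implies the same mother and different
#       fathers (multiple paternity)
#   R4  a half-sib link across nests with the same mtDNA barcode and
#       compatible dates implies the same mother with different fathers
#       (default maternal reading; flagged, since a paternal explanation
#       exists)
#   R5  a half-sib link across nests with different barcodes implies a
#       father shared across two matrilines

#' Cluster hatchlings into full-sibling groups
#'
#' Builds a graph with an edge wherever a pair's normalized IBS reaches the
#' full-sibling threshold; connected components are candidate full-sib
#' groups. Components containing a within-pair below the threshold are
#' refined by average-linkage clustering cut at the threshold, so a group is
#' split only when the cross-cluster MEAN similarity falls below it —
#' isolated noisy pairs inside an otherwise cohesive group are flagged, not
#' split on. Half-sib links are recorded between groups whose cross-group
#' mean lies in the half-sib band.
#'
#' @param normalized symmetric normalized-IBS matrix over hatchlings (sample
#'   ids as dimnames), or a `normalized_ibs` object.
#' @param bands a [kinship_bands()].
#' @return An object of class `sib_partition`: `membership` (data frame
#'   `sample_id`, `group`), `links` (half-sib edges with provenance:
#'   cross-group mean, pair count, ambiguity flag), and `flagged_pairs`
#'   (within-group pairs below the full-sib threshold).
#' @export
cluster_full_sibs <- function(normalized, bands = kinship_bands()) {
  if (inherits(normalized, "normalized_ibs")) normalized <- normalized$normalized
  stopifnot(is.matrix(normalized), inherits(bands, "kinship_bands"))
  if (anyNA(normalized)) {
    stop("normalized matrix must be complete over hatchlings")
  }
  ids <- rownames(normalized)
  n <- nrow(normalized)
  adj <- normalized >= bands$fs
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  member <- integer(n)
  flagged <- list()
  next_grp <- 0L
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) == 1L) {
      next_grp <- next_grp + 1L
      member[idx] <- next_grp
      next
    }
    sub <- normalized[idx, idx]
    consistent <- all(sub[upper.tri(sub)] >= bands$fs)
    if (consistent) {
      next_grp <- next_grp + 1L
      member[idx] <- next_grp
    } else {
      hc <- hclust(as.dist(1 - sub), method = "average")
      cl <- cutree(hc, h = 1 - bands$fs)
      for (k in sort(unique(cl))) {
        next_grp <- next_grp + 1L
        member[idx[cl == k]] <- next_grp
      }
      # pairs kept together despite a below-threshold value
      bad <- which(sub < bands$fs & upper.tri(sub), arr.ind = TRUE)
      for (r in seq_len(nrow(bad))) {
        i <- bad[r, 1L]; j <- bad[r, 2L]
        if (cl[i] == cl[j]) {
          flagged[[length(flagged) + 1L]] <- data.frame(
            sample1 = ids[idx[i]], sample2 = ids[idx[j]],
            value = sub[i, j], stringsAsFactors = FALSE
          )
        }
      }
    }
  }

  groups <- split(seq_len(n), member)
  ng <- length(groups)
  links <- list()
  if (ng >= 2L) {
    for (a in 1:(ng - 1L)) {
      for (b in (a + 1L):ng) {
        cross <- normalized[groups[[a]], groups[[b]], drop = FALSE]
        m <- mean(cross)
        if (m >= bands$hs && m < bands$fs) {
          links[[length(links) + 1L]] <- data.frame(
            group1 = a, group2 = b, mean = m, n_pairs = length(cross),
            ambiguous = min(abs(m - c(bands$hs, bands$fs))) <
              bands$ambiguity_margin,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  structure(
    list(
      membership = data.frame(sample_id = ids, group = member,
                              stringsAsFactors = FALSE),
      links = if (length(links)) do.call(rbind, links) else
        data.frame(group1 = integer(0), group2 = integer(0),
                   mean = numeric(0), n_pairs = integer(0),
                   ambiguous = logical(0)),
      flagged_pairs = if (length(flagged)) do.call(rbind, flagged) else NULL,
      n_groups = ng,
      bands = bands
    ),
    class = "sib_partition"
  )
}

#' @export
print.sib_partition <- function(x, ...) {
  cat(sprintf("<sib_partition> %d hatchlings in %d full-sib groups, %d half-sib link(s)\n",
              nrow(x$membership), x$n_groups, nrow(x$links)))
  invisible(x)
}

# union-find helpers
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}
.uf_union <- function(uf, i, j) {
  ri <- .uf_find(uf, i)
  rj <- .uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

# are two nests' dates compatible with a single female laying both?
.dates_compatible <- function(d1, d2, same_season_max_days = 30) {
  if (is.na(d1) || is.na(d2)) return(NA)
  y1 <- as.integer(format(d1, "%Y"))
  y2 <- as.integer(format(d2, "%Y"))
  if (y1 == y2) {
    abs(as.numeric(d2 - d1)) <= same_season_max_days
  } else {
    TRUE # different seasons: any remigration gap of >= 1 year is plausible
  }
}

#' Assign mothers, fathers and mating events to a sibling partition
#'
#' Applies rules R1-R5 (see the package vignette): nests sharing a full-sib
#' group or a maternal half-sib link are merged into one mother; full-sib
#' groups sharing a paternal half-sib link (different matrilines) are merged
#' into one father. Mothers and fathers are enumerated minimally consistent
#' with the rules; mating events are the distinct (mother, father) pairs.
#'
#' @param partition a [cluster_full_sibs()] result.
#' @param nests data frame with one row per hatchling: `nest_id`,
#'   `sample_id`, and optionally `date` (used for R4 date compatibility).
#' @param haplotypes mtDNA barcode per hatchling: a named character vector or
#'   a data frame with `sample_id` and `barcode`. Missing barcodes are
#'   allowed and flagged.
#' @param same_season_max_days maximum day gap for two same-season nests to
#'   be attributable to one female (internesting plausibility).
#' @return An object of class `reconstruction`: per-hatchling assignments,
#'   mother and father tables, mating events, per-nest paternity, counts and
#'   an audit trail of ambiguous calls.
#' @export
assign_parents <- function(partition, nests, haplotypes = NULL,
                           same_season_max_days = 30) {
  stopifnot(inherits(partition, "sib_partition"))
  mem <- partition$membership
  if (!all(mem$sample_id %in% nests$sample_id)) {
    stop("every hatchling needs a nest record")
  }
  i <- match(mem$sample_id, nests$sample_id)
  mem$nest_id <- nests$nest_id[i]
  has_date <- "date" %in% names(nests)
  nest_ids <- sort(unique(mem$nest_id))
  nest_no <- setNames(seq_along(nest_ids), nest_ids)
  nest_date <- rep(as.Date(NA), length(nest_ids))
  if (has_date) {
    j <- match(nest_ids, nests$nest_id)
    nest_date <- as.Date(nests$date[j])
  }

  if (is.data.frame(haplotypes)) {
    haplotypes <- setNames(haplotypes$barcode, haplotypes$sample_id)
  }
  mem$barcode <- if (is.null(haplotypes)) NA_character_ else
    unname(haplotypes[mem$sample_id])

  ng <- partition$n_groups
  grp_rows <- split(seq_len(nrow(mem)), mem$group)

  # barcode per group; full sibs share the matriline
  grp_barcode <- vapply(grp_rows, function(r) {
    b <- unique(mem$barcode[r])
    b <- b[!is.na(b)]
    if (length(b) > 1L) {
      stop("integrity error: full-sib group with conflicting mtDNA barcodes (",
           paste(mem$sample_id[r], collapse = ", "), ")")
    }
    if (length(b)) b else NA_character_
  }, character(1L))
  grp_nests <- lapply(grp_rows, function(r) unique(mem$nest_id[r]))

  audit <- list()
  note <- function(rule, detail) {
    audit[[length(audit) + 1L]] <<- data.frame(rule = rule, detail = detail,
                                               stringsAsFactors = FALSE)
  }

  # R1 + R2: merge nests through shared mothers
  uf_nest <- .uf_new(length(nest_ids))
  for (gidx in seq_len(ng)) {
    nn <- grp_nests[[gidx]]
    if (length(nn) > 1L) {
      # R2, with the matriline integrity check
      bcs <- unique(mem$barcode[mem$group == gidx])
      bcs <- bcs[!is.na(bcs)]
      if (length(bcs) > 1L) {
        stop("integrity error: full-sib group spans nests with different ",
             "barcodes (samples ",
             paste(mem$sample_id[mem$group == gidx], collapse = ", "), ")")
      }
      for (k in 2:length(nn)) {
        uf_nest <- .uf_union(uf_nest, nest_no[nn[1L]], nest_no[nn[k]])
      }
    }
  }

  # half-sib links: R3 / R4 / R5
  uf_grp <- .uf_new(ng)
  links <- partition$links
  maternal_link <- rep(NA, nrow(links))
  if (nrow(links)) {
    for (r in seq_len(nrow(links))) {
      a <- links$group1[r]
      b <- links$group2[r]
      na_ <- grp_nests[[a]]
      nb_ <- grp_nests[[b]]
      if (length(intersect(na_, nb_))) {
        maternal_link[r] <- TRUE # R3: same nest, same mother by R1
        next
      }
      ba <- grp_barcode[a]
      bb <- grp_barcode[b]
      if (!is.na(ba) && !is.na(bb) && ba != bb) {
        # R5: different matrilines -> shared father
        uf_grp <- .uf_union(uf_grp, a, b)
        maternal_link[r] <- FALSE
        note("R5", paste0("groups ", a, "/", b,
                          ": shared father across matrilines ", ba, "/", bb))
        next
      }
      if (is.na(ba) || is.na(bb)) {
        note("R4", paste0("groups ", a, "/", b,
                          ": barcode missing; maternal reading by default"))
      }
      # same (or unknown) barcode: check date compatibility across nest pairs
      compat <- NA
      for (x in na_) {
        for (y in nb_) {
          c1 <- .dates_compatible(nest_date[nest_no[x]], nest_date[nest_no[y]],
                                  same_season_max_days)
          compat <- if (is.na(compat)) c1 else compat & c1
        }
      }
      if (isFALSE(compat)) {
        # maternal reading impossible on dates: read as paternal, flagged
        uf_grp <- .uf_union(uf_grp, a, b)
        maternal_link[r] <- FALSE
        note("R4", paste0("groups ", a, "/", b, ": same barcode but dates ",
                          "incompatible with one female; read as shared father"))
      } else {
        maternal_link[r] <- TRUE
        for (x in na_) {
          for (y in nb_) {
            uf_nest <- .uf_union(uf_nest, nest_no[x], nest_no[y])
          }
        }
        note("R4", paste0("groups ", a, "/", b, ": same-barcode cross-nest ",
                          "half-sibs read as one female with multiple mates ",
                          "(paternal alternative recorded)"))
      }
    }
  }

  # mother labels from nest components
  nest_root <- vapply(seq_along(nest_ids), function(i) .uf_find(uf_nest, i),
                      integer(1L))
  mother_of_nest <- setNames(
    sprintf("F%02d", match(nest_root, sort(unique(nest_root)))), nest_ids)
  # father labels from group components
  grp_root <- vapply(seq_len(ng), function(i) .uf_find(uf_grp, i), integer(1L))
  father_of_grp <- sprintf("M%02d", match(grp_root, sort(unique(grp_root))))

  mem$mother <- unname(mother_of_nest[mem$nest_id])
  mem$father <- father_of_grp[mem$group]

  # each full-sib group must map to exactly one mother
  grp_mother <- vapply(grp_rows, function(r) {
    m <- unique(mem$mother[r])
    if (length(m) != 1L) {
      stop("integrity error: full-sib group maps to several mothers")
    }
    m
  }, character(1L))

  # mother barcodes (merged nests must agree; R4 merges are same-barcode)
  mother_barcode <- vapply(split(grp_barcode, grp_mother), function(b) {
    b <- unique(b[!is.na(b)])
    if (length(b) > 1L) {
      stop("integrity error: one female linked to several matrilines")
    }
    if (length(b)) b else NA_character_
  }, character(1L))

  events <- unique(data.frame(mother = grp_mother, father = father_of_grp,
                              stringsAsFactors = FALSE))
  rownames(events) <- NULL
  events <- events[order(events$mother, events$father), , drop = FALSE]

  per_nest <- do.call(rbind, lapply(nest_ids, function(nid) {
    rows <- mem[mem$nest_id == nid, ]
    data.frame(
      nest_id = nid,
      mother = mother_of_nest[[nid]],
      n_sampled = nrow(rows),
      n_fathers = length(unique(rows$father)),
      fathers = paste(sort(unique(rows$father)), collapse = ";"),
      multiple_paternity = length(unique(rows$father)) > 1L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_nest) <- NULL

  mothers_tab <- do.call(rbind, lapply(sort(unique(mem$mother)), function(m) {
    data.frame(
      mother = m,
      barcode = if (m %in% names(mother_barcode)) mother_barcode[[m]] else NA,
      n_nests = length(unique(mem$nest_id[mem$mother == m])),
      n_hatchlings = sum(mem$mother == m),
      nests = paste(sort(unique(mem$nest_id[mem$mother == m])), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(mothers_tab) <- NULL

  structure(
    list(
      hatchlings = mem[, c("sample_id", "nest_id", "group", "mother",
                           "father", "barcode")],
      mothers = mothers_tab,
      fathers = data.frame(
        father = sort(unique(mem$father)),
        n_hatchlings = as.integer(table(mem$father)[sort(unique(mem$father))]),
        stringsAsFactors = FALSE
      ),
      mating_events = events,
      nests = per_nest,
      links = cbind(links, maternal = maternal_link),
      counts = list(
        n_mothers = length(unique(mem$mother)),
        n_fathers = length(unique(mem$father)),
        n_mating_events = nrow(events)
      ),
      audit = if (length(audit)) do.call(rbind, audit) else NULL,
      partition = partition
    ),
    class = "reconstruction"
  )
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf(
    "<reconstruction> %d mothers, %d fathers, %d mating events; %d/%d nests with multiple paternity\n",
    x$counts$n_mothers, x$counts$n_fathers, x$counts$n_mating_events,
    sum(x$nests$multiple_paternity), nrow(x$nests)
  ))
  invisible(x)
}

#' Multiple-paternity summary
#'
#' Counts nests sired by two or more detected fathers, overall and
#' restricted to well-sampled nests (more than `min_hatchlings` sampled
#' hatchlings).
#'
#' @param result a [assign_parents()] reconstruction.
#' @param min_hatchlings restriction threshold (strictly greater than).
#' @return List with the per-nest table, overall fraction, and the
#'   restricted table and fraction.
#' @export
multiple_paternity_report <- function(result, min_hatchlings = 5L) {
  stopifnot(inherits(result, "reconstruction"))
  tab <- result$nests
  big <- tab[tab$n_sampled > min_hatchlings, , drop = FALSE]
  list(
    nests = tab,
    n_mp = sum(tab$multiple_paternity),
    fraction = if (nrow(tab)) mean(tab$multiple_paternity) else NA_real_,
    restricted = big,
    n_mp_restricted = sum(big$multiple_paternity),
    fraction_restricted = if (nrow(big)) mean(big$multiple_paternity)
      else NA_real_,
    min_hatchlings = min_hatchlings
  )
}

#' Census arithmetic: minimum females, fathers and sex ratio
#'
#' The minimum number of nesting females is the number of reconstructed
#' mothers plus one female for each haplotype observed in nests but absent
#' from the genotyped sample. The father:mother ratio is formatted `"1:x.xx"`
#' with x truncated (not rounded) to two decimals.
#'
#' @param result a reconstruction, or `NULL` when passing counts directly.
#' @param extra_haplotype_count haplotypes known from nests but not sampled
#'   here, each implying at least one further female.
#' @param n_mothers,n_fathers explicit counts (used when `result` is `NULL`).
#' @return List with `min_females`, `n_mothers`, `n_fathers`, `ratio`.
#' @export
census_summary <- function(result = NULL, extra_haplotype_count = 0L,
                           n_mothers = NULL, n_fathers = NULL) {
  if (!is.null(result)) {
    stopifnot(inherits(result, "reconstruction"))
    n_mothers <- result$counts$n_mothers
    n_fathers <- result$counts$n_fathers
  }
  if (extra_haplotype_count < 0L) {
    stop("'extra_haplotype_count' must be >= 0")
  }
  if (is.null(n_mothers) || n_mothers == 0L) {
    stop("undefined ratio: no mothers")
  }
  ratio_x <- floor(n_fathers / n_mothers * 100 + 1e-9) / 100
  list(
    min_females = n_mothers + extra_haplotype_count,
    n_mothers = n_mothers,
    n_fathers = n_fathers,
    ratio = sprintf("1:%.2f", ratio_x)
  )
}

#' Full parentage reconstruction from genotypes and nest metadata
#'
#' Chains [normalized_ibs()] (baseline from the two most distinct nests),
#' [cluster_full_sibs()] and [assign_parents()].
#'
#' The baseline is searched only among nests with at least
#' `baseline_min_group` sampled hatchlings: the average raw IBS between the
#' two least related nests estimates the background identity level, and
#' minimizing it over thousands of single-hatchling nest pairs would select
#' on pair-level sampling noise and bias the baseline downward (inflating
#' every normalized value). With fewer than two such nests all nests are
#' used.
#'
#' @param gm hatchling [genotype_matrix()].
#' @param nests per-hatchling nest metadata (`nest_id`, `sample_id`,
#'   optional `date`).
#' @param haplotypes per-hatchling barcodes (named vector or data frame).
#' @param bands a [kinship_bands()].
#' @param av_min optional explicit baseline.
#' @param min_overlap minimum jointly called sites per pair.
#' @param baseline_min_group minimum nest size for baseline candidates.
#' @param same_season_max_days see [assign_parents()].
#' @return A `reconstruction` with the `normalized_ibs` object attached as
#'   `$kinship`.
#' @export
reconstruct_parentage <- function(gm, nests, haplotypes = NULL,
                                  bands = kinship_bands(), av_min = NULL,
                                  min_overlap = 100L, baseline_min_group = 2L,
                                  same_season_max_days = 30) {
  stopifnot(inherits(gm, "genotype_matrix"))
  groups <- setNames(nests$nest_id[match(gm_samples(gm), nests$sample_id)],
                     gm_samples(gm))
  if (anyNA(groups)) stop("every sample needs a nest record")
  if (is.null(av_min)) {
    sizes <- table(groups)
    eligible <- names(sizes)[sizes >= baseline_min_group]
    ib <- ibs_matrix(gm, min_overlap = min_overlap)
    bl_groups <- if (length(eligible) >= 2L) {
      replace(groups, !(groups %in% eligible), NA)
    } else groups
    keep <- !is.na(bl_groups)
    bl <- baseline_av_min(ib$raw[keep, keep, drop = FALSE], bl_groups[keep])
    nk <- structure(
      list(raw = ib$raw, normalized = normalize_ibs(ib$raw, bl$av_min),
           n_overlap = ib$n_overlap, av_min = bl$av_min,
           baseline_groups = bl$groups, groups = groups),
      class = "normalized_ibs"
    )
  } else {
    nk <- normalized_ibs(gm, groups = groups, av_min = av_min,
                         min_overlap = min_overlap)
  }
  part <- cluster_full_sibs(nk$normalized, bands = bands)
  res <- assign_parents(part, nests, haplotypes = haplotypes,
                        same_season_max_days = same_season_max_days)
  res$kinship <- nk
  res
}
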