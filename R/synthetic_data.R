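# Synthetic pedigree, genotype and nest-schedule generator. The default
# "nesting" scenario reproduces the structure of a two-decade hatchling
# survey: 35 nesting females in five matrilines, 59 fathers, 60 mating
# events across 84 nests, one father shared across two matrilines, sperm
# storage within seasons, and a third of the well-sampled nests (>5
# hatchlings) showing multiple paternity.

.rint <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

.pick <- function(x, k) x[sample.int(length(x), k)]

#' Simulation configuration
#'
#' @param n_snps number of unlinked biallelic SNP sites.
#' @param maf minor-allele-frequency spectrum: a single value, a
#'   `c(low, high)` range for uniform draws, or an explicit per-site vector;
#'   all values in `(0, 0.5]`.
#' @param n_mothers,n_fathers founder pool sizes (also the mother/father
#'   counts of the `"nesting"` scenario, where `n_fathers` must equal the
#'   count implied by the event structure).
#' @param n_nests,n_mating_events,n_big_nests,n_mp_nests,n_mp_big structure
#'   of the `"nesting"` scenario: total nests, total mating events, nests
#'   with more than 5 sampled hatchlings, multi-paternity nests overall and
#'   among the big nests.
#' @param scenario `"nesting"` (structured default), `"random"`
#'   (rate-driven), or `"plan"` (explicit nest plan in `plan`).
#' @param plan for `scenario = "plan"`: data frame with columns `nest_id`,
#'   `mother`, `season`, `clutch`, `fathers` (";"-joined father indices) and
#'   `eggs` (";"-joined sampled-hatchling counts per father).
#' @param polyandry_rate probability (per clutch with at least two sampled
#'   eggs, `"random"` scenario) of a second father.
#' @param sperm_storage if `TRUE`, a female's clutches within one season
#'   reuse the season's father set.
#' @param shared_father_events number of father-sharing events across two
#'   mothers of different matrilines.
#' @param clutches_per_season,eggs_per_nest,internesting_days,remigration_years
#'   integer ranges `c(low, high)`.
#' @param philopatry_sd_km Gaussian dispersal scale (km) of nests around a
#'   female's home beach.
#' @param longrange_prob,longrange_km probability of a rare long-range nest
#'   displacement and its distance range (km).
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean,depth_sd mean/sd of per-genotype read depth.
#' @param heteroplasmy_rate probability that a matriline carries a minor
#'   haplotype.
#' @param barcodes mtDNA barcodes recycled over mothers (`"random"`/`"plan"`
#'   scenarios).
#' @param barcode_counts named integer vector giving mothers per barcode
#'   (`"nesting"` scenario); must sum to `n_mothers`.
#' @param seed RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 12795L,
                       maf = c(0.05, 0.5),
                       n_mothers = 35L,
                       n_fathers = 59L,
                       n_nests = 84L,
                       n_mating_events = 60L,
                       n_big_nests = 18L,
                       n_mp_nests = 10L,
                       n_mp_big = 6L,
                       scenario = c("nesting", "random", "plan"),
                       plan = NULL,
                       polyandry_rate = 0.15,
                       sperm_storage = TRUE,
                       shared_father_events = 1L,
                       clutches_per_season = c(1L, 4L),
                       eggs_per_nest = c(1L, 8L),
                       internesting_days = c(8L, 23L),
                       remigration_years = c(3L, 4L),
                       philopatry_sd_km = 2,
                       longrange_prob = 0.03,
                       longrange_km = c(60, 90),
                       missing_rate = 0.05,
                       depth_mean = 40,
                       depth_sd = 17,
                       heteroplasmy_rate = 0.1,
                       barcodes = c("6-8-8-4", "6-8-9-4", "6-9-6-4", "8-7-7-4"),
                       barcode_counts = c("6-8-8-4" = 19L, "6-8-9-4" = 3L,
                                          "6-9-6-4" = 5L, "8-7-7-4" = 7L,
                                          "8-7-8-4" = 1L),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("'", nm, "' must be a probability in [0, 1]")
    }
  }
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1) {
      stop("'", nm, "' must be a count >= 1")
    }
  }
  chk_range <- function(x, nm, lo_min = 1) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1L] > x[2L] ||
        x[1L] < lo_min) {
      stop("'", nm, "' must be a range c(low, high) with low >= ", lo_min)
    }
  }
  chk_count(n_snps, "n_snps")
  chk_count(n_mothers, "n_mothers")
  chk_count(n_fathers, "n_fathers")
  if (!is.numeric(maf) || !length(maf) %in% c(1L, 2L, n_snps) ||
      any(maf <= 0 | maf > 0.5)) {
    stop("'maf' must be a value, a range or a per-site vector in (0, 0.5]")
  }
  if (length(maf) == 2L && maf[1L] > maf[2L]) {
    stop("'maf' range must have low <= high")
  }
  chk_prob(polyandry_rate, "polyandry_rate")
  chk_prob(longrange_prob, "longrange_prob")
  chk_prob(missing_rate, "missing_rate")
  chk_prob(heteroplasmy_rate, "heteroplasmy_rate")
  chk_range(clutches_per_season, "clutches_per_season")
  chk_range(eggs_per_nest, "eggs_per_nest")
  chk_range(internesting_days, "internesting_days")
  chk_range(remigration_years, "remigration_years")
  chk_range(longrange_km, "longrange_km", lo_min = 0)
  if (shared_father_events < 0 || shared_father_events > floor(n_mothers / 2)) {
    stop("'shared_father_events' must be between 0 and n_mothers/2")
  }
  if (philopatry_sd_km <= 0) stop("'philopatry_sd_km' must be positive")
  if (depth_mean < 0 || depth_sd < 0) stop("depth model must be non-negative")
  if (scenario == "nesting") {
    chk_count(n_nests, "n_nests")
    if (sum(barcode_counts) != n_mothers) {
      stop("'barcode_counts' must sum to n_mothers")
    }
    if (n_mp_big > n_mp_nests || n_mp_big > n_big_nests ||
        n_big_nests > n_nests || n_mp_nests > n_nests) {
      stop("inconsistent nest structure counts")
    }
  }
  if (scenario == "plan") {
    if (is.null(plan)) stop("scenario 'plan' requires a 'plan' data frame")
    need <- c("nest_id", "mother", "season", "clutch", "fathers", "eggs")
    if (!is.data.frame(plan) || !all(need %in% names(plan))) {
      stop("'plan' needs columns: ", paste(need, collapse = ", "))
    }
  }
  structure(
    list(n_snps = as.integer(n_snps), maf = maf,
         n_mothers = as.integer(n_mothers), n_fathers = as.integer(n_fathers),
         n_nests = as.integer(n_nests),
         n_mating_events = as.integer(n_mating_events),
         n_big_nests = as.integer(n_big_nests),
         n_mp_nests = as.integer(n_mp_nests), n_mp_big = as.integer(n_mp_big),
         scenario = scenario, plan = plan,
         polyandry_rate = polyandry_rate, sperm_storage = sperm_storage,
         shared_father_events = as.integer(shared_father_events),
         clutches_per_season = as.integer(clutches_per_season),
         eggs_per_nest = as.integer(eggs_per_nest),
         internesting_days = as.integer(internesting_days),
         remigration_years = as.integer(remigration_years),
         philopatry_sd_km = philopatry_sd_km,
         longrange_prob = longrange_prob, longrange_km = longrange_km,
         missing_rate = missing_rate,
         depth_mean = depth_mean, depth_sd = depth_sd,
         heteroplasmy_rate = heteroplasmy_rate,
         barcodes = barcodes, barcode_counts = barcode_counts,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> scenario '%s': %d SNPs, %d mothers, %d fathers, seed %d\n",
    x$scenario, x$n_snps, x$n_mothers, x$n_fathers, x$seed
  ))
  invisible(x)
}

#' Simulate unrelated founders under Hardy-Weinberg proportions
#'
#' Draws one allele frequency per site from the configured spectrum, then
#' genotypes for `n_mothers + n_fathers` mutually unrelated founders as
#' binomial(2, p) dosages.
#'
#' @param config a [sim_config()].
#' @return An object of class `founder_set`: founder genotype matrix
#'   (mothers `F..` then fathers `M..`), the allele-frequency vector, and
#'   the site table.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_snps
  freq <- switch(as.character(length(config$maf)),
    "1" = rep(config$maf, ns),
    "2" = runif(ns, config$maf[1L], config$maf[2L]),
    config$maf
  )
  mothers <- sprintf("F%02d", seq_len(config$n_mothers))
  fathers <- sprintf("M%02d", seq_len(config$n_fathers))
  nf <- length(mothers) + length(fathers)
  geno <- matrix(rbinom(nf * ns, 2L, rep(freq, each = nf)), nrow = nf,
                 dimnames = list(c(mothers, fathers), NULL))
  block <- ceiling(ns / 28)
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, ns, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, ns, replace = TRUE)) %% 4L + 1L
  sites <- data.frame(
    chrom = paste0("chr", (seq_len(ns) - 1L) %/% block + 1L),
    pos = ((seq_len(ns) - 1L) %% block + 1L) * 500L,
    ref = bases[ref_i],
    alt = bases[alt_i],
    stringsAsFactors = FALSE
  )
  structure(
    list(genotypes = geno, freq = freq, sites = sites,
         mothers = mothers, fathers = fathers),
    class = "founder_set"
  )
}

# structured default scenario: deterministic counts, seeded sizes
.plan_nesting <- function(config) {
  nm <- config$n_mothers
  barcode_of <- rep(names(config$barcode_counts), config$barcode_counts)

  # father-sharing pairs across different matrilines
  shared <- NULL
  if (config$shared_father_events > 0L) {
    main_bc <- names(which.max(config$barcode_counts))
    a_pool <- which(barcode_of == main_bc)
    b_pool <- which(barcode_of != main_bc)
    k <- config$shared_father_events
    if (k > length(a_pool) || k > length(b_pool)) {
      stop("not enough mothers in distinct matrilines for ",
           k, " shared-father event(s)")
    }
    shared <- data.frame(a = a_pool[seq_len(k)], b = rev(b_pool)[seq_len(k)])
  }

  n_second <- config$n_mating_events - nm - config$n_mp_nests
  if (n_second < 0L) {
    stop("n_mating_events too small for n_mothers + n_mp_nests")
  }
  eligible <- setdiff(seq_len(nm), c(shared$a, shared$b))
  if (n_second > length(eligible)) {
    stop("not enough mothers available for ", n_second, " second seasons")
  }
  second <- sort(.pick(eligible, n_second))

  ms <- rbind(
    data.frame(mother = seq_len(nm), season = 1L),
    if (n_second > 0L) data.frame(mother = second, season = 2L)
  )
  ms <- ms[order(ms$mother, ms$season), ]
  nms <- nrow(ms)
  if (config$n_mp_nests > nms) stop("more MP nests requested than seasons")
  mp_ms <- sort(.pick(seq_len(nms), config$n_mp_nests))

  # clutch counts: start at one, place extras under per-season caps
  # (MP seasons capped at 2 clutches so every same-season nest pair stays
  #  within one internesting interval)
  counts <- rep(1L, nms)
  cap <- ifelse(seq_len(nms) %in% mp_ms,
                pmin(2L, config$clutches_per_season[2L]),
                config$clutches_per_season[2L])
  extra <- config$n_nests - nms
  if (extra < 0L) stop("n_nests smaller than the number of mother-seasons")
  for (i in seq_len(extra)) {
    open <- which(counts < cap)
    if (!length(open)) stop("cannot place all clutches under the season caps")
    pick <- .pick(open, 1L)
    counts[pick] <- counts[pick] + 1L
  }

  nests <- data.frame(
    mother = rep(ms$mother, counts),
    season = rep(ms$season, counts),
    clutch = unlist(lapply(counts, seq_len)),
    ms_row = rep(seq_len(nms), counts)
  )
  nn <- nrow(nests)
  nests$nest_id <- sprintf("N%03d", seq_len(nn))
  mp_nest <- which(nests$ms_row %in% mp_ms & nests$clutch == 1L)

  # big nests: >5 sampled hatchlings
  big_mp <- .pick(mp_nest, config$n_mp_big)
  non_mp <- setdiff(seq_len(nn), mp_nest)
  if (config$n_big_nests - config$n_mp_big > length(non_mp)) {
    stop("not enough non-MP nests for the requested big-nest count")
  }
  big <- c(big_mp, .pick(non_mp, config$n_big_nests - config$n_mp_big))
  is_big <- seq_len(nn) %in% big
  is_mp <- seq_len(nn) %in% mp_nest

  eggs <- integer(nn)
  eggs[is_big] <- .rint(6L, 8L, sum(is_big))
  sm_mp <- which(is_mp & !is_big)
  eggs[sm_mp] <- sample(2:5, length(sm_mp), replace = TRUE,
                        prob = c(0.5, 0.3, 0.15, 0.05))
  sm <- which(!is_mp & !is_big)
  eggs[sm] <- sample(1:5, length(sm), replace = TRUE,
                     prob = c(0.45, 0.25, 0.15, 0.1, 0.05))

  # father ids: per-mother base fathers (shared pairs reuse), then
  # second-season fathers, then the extra MP fathers
  fc <- 0L
  base_f <- integer(nm)
  for (m in seq_len(nm)) {
    hit <- which(shared$b == m)
    if (length(hit)) {
      base_f[m] <- base_f[shared$a[hit]]
    } else {
      fc <- fc + 1L
      base_f[m] <- fc
    }
  }
  second_f <- setNames(integer(0L), character(0L))
  for (m in second) {
    fc <- fc + 1L
    second_f[as.character(m)] <- fc
  }
  mp_f <- setNames(integer(0L), character(0L))
  for (r in mp_ms) {
    fc <- fc + 1L
    mp_f[as.character(r)] <- fc
  }
  if (fc != config$n_fathers) {
    stop("structure implies ", fc, " fathers but n_fathers = ",
         config$n_fathers)
  }

  primary <- ifelse(nests$season == 1L, base_f[nests$mother],
                    second_f[as.character(nests$mother)])
  fathers <- as.character(primary)
  eggs_str <- as.character(eggs)
  for (i in mp_nest) {
    f2 <- mp_f[as.character(nests$ms_row[i])]
    n1 <- .pick(seq_len(eggs[i] - 1L), 1L)
    fathers[i] <- paste(primary[i], f2, sep = ";")
    eggs_str[i] <- paste(n1, eggs[i] - n1, sep = ";")
  }

  plan <- data.frame(
    nest_id = nests$nest_id, mother = nests$mother, season = nests$season,
    clutch = nests$clutch, fathers = fathers, eggs = eggs_str,
    stringsAsFactors = FALSE
  )
  attr(plan, "barcode_of") <- barcode_of
  attr(plan, "shared_pairs") <- shared
  plan
}

# rate-driven scenario for distributional checks
.plan_random <- function(config) {
  nm <- config$n_mothers
  rows <- list()
  fc <- 0L
  nid <- 0L
  for (m in seq_len(nm)) {
    ncl <- .rint(config$clutches_per_season[1L],
                 config$clutches_per_season[2L], 1L)
    season_father <- NA_integer_
    for (cl in seq_len(ncl)) {
      if (cl == 1L || !config$sperm_storage) {
        fc <- fc + 1L
        season_father <- fc
      }
      eggs <- .rint(config$eggs_per_nest[1L], config$eggs_per_nest[2L], 1L)
      f <- as.character(season_father)
      e <- as.character(eggs)
      if (eggs >= 2L && runif(1L) < config$polyandry_rate) {
        fc <- fc + 1L
        n1 <- .pick(seq_len(eggs - 1L), 1L)
        f <- paste(season_father, fc, sep = ";")
        e <- paste(n1, eggs - n1, sep = ";")
      }
      nid <- nid + 1L
      rows[[nid]] <- data.frame(
        nest_id = sprintf("N%03d", nid), mother = m, season = 1L,
        clutch = cl, fathers = f, eggs = e, stringsAsFactors = FALSE
      )
    }
  }
  if (fc > config$n_fathers) {
    stop("structure requires ", fc, " fathers but n_fathers = ",
         config$n_fathers, "; not enough founders")
  }
  plan <- do.call(rbind, rows)
  attr(plan, "barcode_of") <-
    rep(config$barcodes, length.out = nm)
  plan
}

.transmit <- function(g, k) {
  s <- length(g)
  out <- matrix(rep.int(as.integer(g == 2L), k), nrow = k, byrow = TRUE)
  het <- which(g == 1L)
  if (length(het)) {
    out[, het] <- matrix(rbinom(k * length(het), 1L, 0.5), nrow = k)
  }
  out
}

#' Simulate a pedigree of nest hatchlings by Mendelian transmission
#'
#' Builds the nest/mating structure for the configured scenario, draws each
#' hatchling's genotype site-by-site from its assigned parents, then applies
#' missingness and the read-depth model. One female per nest throughout;
#' multi-paternity nests carry at least one sampled hatchling per father.
#'
#' @param config a [sim_config()].
#' @param founders a `founder_set` from [simulate_founders()].
#' @return List with `truth` (a `pedigree_truth`: hatchling, nest, mating
#'   event, matriline and shared-father tables plus realized counts) and
#'   `genotypes` (the hatchling [genotype_matrix()]).
#' @export
simulate_pedigree <- function(config, founders) {
  stopifnot(inherits(config, "sim_config"), inherits(founders, "founder_set"))
  set.seed(config$seed + 1L)
  plan <- switch(config$scenario,
    nesting = .plan_nesting(config),
    random = .plan_random(config),
    plan = {
      p <- config$plan
      attr(p, "barcode_of") <- rep(config$barcodes,
                                   length.out = config$n_mothers)
      p
    }
  )
  f_idx <- lapply(strsplit(plan$fathers, ";", fixed = TRUE), as.integer)
  e_cnt <- lapply(strsplit(plan$eggs, ";", fixed = TRUE), as.integer)
  if (any(vapply(f_idx, length, 1L) != vapply(e_cnt, length, 1L))) {
    stop("plan 'fathers' and 'eggs' entries must align")
  }
  all_f <- unlist(f_idx)
  if (max(plan$mother) > config$n_mothers || max(all_f) > config$n_fathers) {
    stop("plan requires more founders than available")
  }

  mothers <- founders$mothers
  fathers <- founders$fathers
  hrows <- list()
  geno_blocks <- list()
  hn <- 0L
  for (i in seq_len(nrow(plan))) {
    gm_mom <- founders$genotypes[mothers[plan$mother[i]], ]
    for (j in seq_along(f_idx[[i]])) {
      k <- e_cnt[[i]][j]
      if (k < 1L) stop("every father in a nest needs >= 1 sampled hatchling")
      gm_dad <- founders$genotypes[fathers[f_idx[[i]][j]], ]
      child <- .transmit(gm_mom, k) + .transmit(gm_dad, k)
      ids <- sprintf("H%03d", hn + seq_len(k))
      hn <- hn + k
      rownames(child) <- ids
      geno_blocks[[length(geno_blocks) + 1L]] <- child
      hrows[[length(hrows) + 1L]] <- data.frame(
        sample_id = ids,
        mother_id = mothers[plan$mother[i]],
        father_id = fathers[f_idx[[i]][j]],
        nest_id = plan$nest_id[i],
        stringsAsFactors = FALSE
      )
    }
  }
  hatchlings <- do.call(rbind, hrows)
  geno <- do.call(rbind, geno_blocks)

  miss <- matrix(runif(length(geno)) < config$missing_rate, nrow = nrow(geno))
  geno[miss] <- NA_integer_
  depth <- matrix(
    pmax(0L, as.integer(round(rnorm(length(geno), config$depth_mean,
                                    config$depth_sd)))),
    nrow = nrow(geno), dimnames = dimnames(geno)
  )

  barcode_of <- attr(plan, "barcode_of")
  het <- runif(config$n_mothers) < config$heteroplasmy_rate
  minor <- vapply(barcode_of, function(b) {
    cts <- parse_barcode(b)
    cts[3L] <- cts[3L] + 1L
    mtstr_barcode(cts)
  }, character(1L))
  matrilines <- data.frame(
    mother_id = mothers[seq_len(config$n_mothers)],
    barcode = barcode_of,
    heteroplasmic = het,
    minor_barcode = ifelse(het, minor, NA_character_),
    stringsAsFactors = FALSE
  )

  nests <- data.frame(
    nest_id = plan$nest_id,
    mother_id = mothers[plan$mother],
    season = plan$season,
    clutch = plan$clutch,
    fathers = vapply(f_idx, function(f) paste(fathers[f], collapse = ";"),
                     character(1L)),
    n_sampled = vapply(e_cnt, sum, integer(1L)),
    multiple_paternity = lengths(f_idx) > 1L,
    stringsAsFactors = FALSE
  )
  events <- unique(hatchlings[, c("mother_id", "father_id")])
  rownames(events) <- NULL
  shared <- attr(plan, "shared_pairs")
  truth <- structure(
    list(
      hatchlings = hatchlings,
      nests = nests,
      mating_events = events,
      matrilines = matrilines,
      shared_pairs = if (!is.null(shared)) {
        data.frame(mother_a = mothers[shared$a], mother_b = mothers[shared$b],
                   stringsAsFactors = FALSE)
      },
      counts = list(
        n_mothers = length(unique(hatchlings$mother_id)),
        n_fathers = length(unique(hatchlings$father_id)),
        n_mating_events = nrow(events),
        n_nests = nrow(nests),
        n_hatchlings = nrow(hatchlings)
      )
    ),
    class = "pedigree_truth"
  )
  gm <- genotype_matrix(geno, founders$sites, depth = depth)
  list(truth = truth, genotypes = gm)
}

#' @export
print.pedigree_truth <- function(x, ...) {
  cat(sprintf(
    "<pedigree_truth> %d hatchlings in %d nests; %d mothers, %d fathers, %d mating events\n",
    x$counts$n_hatchlings, x$counts$n_nests, x$counts$n_mothers,
    x$counts$n_fathers, x$counts$n_mating_events
  ))
  invisible(x)
}

#' Simulate nest dates and coordinates
#'
#' Seasons get calendar years; a female's second season follows her first
#' after a remigration interval drawn from `remigration_years`. Within a
#' season, consecutive clutch dates are separated by draws from
#' `internesting_days`. Nest coordinates are the female's home beach plus
#' Gaussian displacement (`philopatry_sd_km`), replaced with probability
#' `longrange_prob` by a long-range displacement drawn from `longrange_km`.
#' Mothers of a shared-father event nest one remigration interval apart.
#'
#' @param config a [sim_config()].
#' @param truth a `pedigree_truth` from [simulate_pedigree()].
#' @return Data frame with `nest_id`, `year`, `date`, `lat`, `lon`.
#' @export
simulate_nest_schedule <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "pedigree_truth"))
  set.seed(config$seed + 2L)
  nests <- truth$nests
  mothers <- unique(nests$mother_id)
  km_per_deg <- pi / 180 * 6371

  home_lat <- setNames(runif(length(mothers), 31.60, 32.90), mothers)
  home_lon <- setNames(34.78 + (home_lat - 31.60) * 0.22, mothers)

  year1 <- setNames(.rint(2004L, 2018L, length(mothers)), mothers)
  if (!is.null(truth$shared_pairs)) {
    for (i in seq_len(nrow(truth$shared_pairs))) {
      a <- truth$shared_pairs$mother_a[i]
      b <- truth$shared_pairs$mother_b[i]
      year1[b] <- year1[a] + .rint(config$remigration_years[1L],
                                   config$remigration_years[2L], 1L)
    }
  }

  out <- nests[, c("nest_id", "mother_id", "season", "clutch")]
  out$year <- NA_integer_
  out$date <- as.Date(NA)
  for (m in mothers) {
    for (s in sort(unique(out$season[out$mother_id == m]))) {
      rows <- which(out$mother_id == m & out$season == s)
      rows <- rows[order(out$clutch[rows])]
      yr <- year1[m]
      if (s > 1L) {
        yr <- yr + sum(.rint(config$remigration_years[1L],
                             config$remigration_years[2L], s - 1L))
      }
      start <- as.Date(sprintf("%d-06-01", yr)) + .rint(0L, 25L, 1L)
      gaps <- .rint(config$internesting_days[1L],
                    config$internesting_days[2L], length(rows) - 1L)
      out$year[rows] <- yr
      out$date[rows] <- start + c(0L, cumsum(gaps))
    }
  }

  n <- nrow(out)
  d_north <- rnorm(n, 0, config$philopatry_sd_km)
  d_east <- rnorm(n, 0, config$philopatry_sd_km)
  lr <- runif(n) < config$longrange_prob
  if (any(lr)) {
    d_north[lr] <- sample(c(-1, 1), sum(lr), replace = TRUE) *
      runif(sum(lr), config$longrange_km[1L], config$longrange_km[2L])
    d_east[lr] <- 0
  }
  lat0 <- home_lat[out$mother_id]
  out$lat <- unname(lat0 + d_north / km_per_deg)
  out$lon <- unname(home_lon[out$mother_id] +
                      d_east / (km_per_deg * cos(lat0 * pi / 180)))
  out[, c("nest_id", "year", "date", "lat", "lon")]
}

#' Write a simulated dataset to disk
#'
#' Emits `genotypes.vcf` (GT + DP), `nests.csv` (one row per sampled
#' hatchling: nest id, sample id, date, coordinates, mtDNA barcode),
#' `haplotypes.csv`, `truth.json` and `config.yaml`. All tables are checked
#' for id consistency before anything is written.
#'
#' @param truth a `pedigree_truth`.
#' @param genotypes the hatchling [genotype_matrix()].
#' @param schedule the nest schedule from [simulate_nest_schedule()].
#' @param outdir output directory (created if needed).
#' @param config the [sim_config()] used (echoed as YAML); optional.
#' @return Invisibly, a named vector of the file paths written.
#' @export
write_dataset <- function(truth, genotypes, schedule, outdir, config = NULL) {
  stopifnot(inherits(truth, "pedigree_truth"),
            inherits(genotypes, "genotype_matrix"))
  if (!setequal(truth$hatchlings$sample_id, gm_samples(genotypes)) ||
      !setequal(truth$hatchlings$nest_id, schedule$nest_id) ||
      !setequal(truth$nests$nest_id, schedule$nest_id)) {
    stop("integrity error: sample/nest ids disagree across tables")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(outdir, "genotypes.vcf"),
    nests = file.path(outdir, "nests.csv"),
    haplotypes = file.path(outdir, "haplotypes.csv"),
    truth = file.path(outdir, "truth.json"),
    config = file.path(outdir, "config.yaml")
  )
  write_vcf(genotypes, paths[["vcf"]])
  nests_csv <- nest_table(truth, schedule)
  write.csv(nests_csv, paths[["nests"]], row.names = FALSE)
  write.csv(haplotype_table(truth), paths[["haplotypes"]], row.names = FALSE)
  tr <- truth
  tr$nests$fathers <- as.character(tr$nests$fathers)
  jsonlite::write_json(unclass(tr), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$plan <- NULL
    yaml::write_yaml(cfg, paths[["config"]])
  } else {
    yaml::write_yaml(list(), paths[["config"]])
  }
  invisible(paths)
}

#' Per-hatchling nest metadata table
#'
#' @param truth a `pedigree_truth`.
#' @param schedule a nest schedule (or `NULL` for structure-only output).
#' @return Data frame with `nest_id`, `sample_id`, `date`, `lat`, `lon`,
#'   `mt_haplotype`.
#' @export
nest_table <- function(truth, schedule = NULL) {
  h <- truth$hatchlings
  bc <- setNames(truth$matrilines$barcode, truth$matrilines$mother_id)
  out <- data.frame(
    nest_id = h$nest_id,
    sample_id = h$sample_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(schedule)) {
    i <- match(h$nest_id, schedule$nest_id)
    out$date <- schedule$date[i]
    out$lat <- schedule$lat[i]
    out$lon <- schedule$lon[i]
  }
  out$mt_haplotype <- unname(bc[h$mother_id])
  out
}

#' Per-hatchling mtDNA haplotype table
#' @param truth a `pedigree_truth`.
#' @return Data frame with `sample_id`, `barcode`, `heteroplasmic`,
#'   `minor_barcode`.
#' @export
haplotype_table <- function(truth) {
  h <- truth$hatchlings
  i <- match(h$mother_id, truth$matrilines$mother_id)
  data.frame(
    sample_id = h$sample_id,
    barcode = truth$matrilines$barcode[i],
    heteroplasmic = truth$matrilines$heteroplasmic[i],
    minor_barcode = truth$matrilines$minor_barcode[i],
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete dataset
#'
#' Runs [simulate_founders()], [simulate_pedigree()] and
#' [simulate_nest_schedule()] and optionally writes everything with
#' [write_dataset()].
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return List with `founders`, `truth`, `genotypes`, `schedule`, `nests`
#'   (per-hatchling metadata) and `haplotypes`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  founders <- simulate_founders(config)
  ped <- simulate_pedigree(config, founders)
  schedule <- simulate_nest_schedule(config, ped$truth)
  if (!is.null(outdir)) {
    write_dataset(ped$truth, ped$genotypes, schedule, outdir, config = config)
  }
  list(
    founders = founders,
    truth = ped$truth,
    genotypes = ped$genotypes,
    schedule = schedule,
    nests = nest_table(ped$truth, schedule),
    haplotypes = haplotype_table(ped$truth)
  )
}

#' Configuration for a two-family captive-breeding-stock scenario
#'
#' One family of 11 full siblings (one mother, one father) and a second
#' family of 10 hatchlings from one nest split 5 + 5 between two fathers, so
#' the dataset contains full-sibling, half-sibling and unrelated pairs with
#' known structure: three mating events in total.
#'
#' @param n_snps number of SNP sites.
#' @param seed RNG seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A [sim_config()] using the `"plan"` scenario.
#' @export
breeding_stock_config <- function(n_snps = 2000L, seed = 1L, ...) {
  plan <- data.frame(
    nest_id = c("N001", "N002"),
    mother = c(1L, 2L),
    season = 1L,
    clutch = 1L,
    fathers = c("1", "2;3"),
    eggs = c("11", "5;5"),
    stringsAsFactors = FALSE
  )
  sim_config(n_snps = n_snps, scenario = "plan", plan = plan,
             n_mothers = 2L, n_fathers = 3L, n_nests = 2L,
             shared_father_events = 0L, seed = seed, ...)
}
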