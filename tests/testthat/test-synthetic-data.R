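test_that("configuration bounds are enforced", {
  expect_error(sim_config(maf = 0), "maf")
  expect_error(sim_config(maf = c(0.6, 0.7)), "maf")
  expect_error(sim_config(maf = c(0.3, 0.1)), "low <= high")
  expect_error(sim_config(polyandry_rate = 1.5), "probability")
  expect_error(sim_config(n_snps = 0), "count")
  expect_error(sim_config(shared_father_events = 30), "shared_father_events")
  expect_error(sim_config(internesting_days = c(23, 8)), "range")
  expect_error(sim_config(scenario = "plan"), "requires a 'plan'")
  expect_error(sim_config(barcode_counts = c("6-8-8-4" = 3)), "sum to")
})

test_that("founders are Hardy-Weinberg draws at the configured frequencies", {
  # binomial oracle: 10,000 founders at MAF 0.2
  cfg <- sim_config(n_snps = 2, maf = 0.2, n_mothers = 5000, n_fathers = 5000,
                    scenario = "random", seed = 4)
  f <- simulate_founders(cfg)
  se <- sqrt(0.2 * 0.8 / (2 * 10000))
  expect_true(all(abs(colMeans(f$genotypes) / 2 - 0.2) < 3 * se))

  # HWE genotype proportions at p = 0.5
  cfg2 <- sim_config(n_snps = 1, maf = 0.5, n_mothers = 2000, n_fathers = 2000,
                     scenario = "random", seed = 5)
  g <- simulate_founders(cfg2)$genotypes[, 1]
  se2 <- sqrt(0.5 * 0.5 / 4000)
  expect_lt(abs(mean(g == 0) - 0.25), 3 * se2)
  expect_lt(abs(mean(g == 1) - 0.50), 3 * se2)
  expect_lt(abs(mean(g == 2) - 0.25), 3 * se2)
})

test_that("hatchling genotypes are Mendelian-consistent with their true parents", {
  cfg <- sim_config(n_snps = 400, seed = 6)
  f <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg, f)
  h <- ped$truth$hatchlings
  ok <- vapply(seq_len(nrow(h)), function(i) {
    child <- ped$genotypes$geno[h$sample_id[i], ]
    gm <- f$genotypes[h$mother_id[i], ]
    gf <- f$genotypes[h$father_id[i], ]
    called <- !is.na(child)
    lo <- (gm == 2) + (gf == 2)
    hi <- (gm >= 1) + (gf >= 1)
    all(child[called] >= lo[called] & child[called] <= hi[called])
  }, logical(1))
  expect_true(all(ok))
})

test_that("the default scenario reproduces the published population structure", {
  cfg <- sim_config(n_snps = 200, seed = 3)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  expect_equal(tr$counts$n_nests, 84L)
  expect_equal(tr$counts$n_mothers, 35L)
  expect_equal(tr$counts$n_fathers, 59L)
  expect_equal(tr$counts$n_mating_events, 60L)
  # mating events are the distinct (mother, father) pairs
  expect_equal(nrow(unique(tr$hatchlings[, c("mother_id", "father_id")])),
               tr$counts$n_mating_events)
  # one female per nest
  per_nest <- tapply(tr$hatchlings$mother_id, tr$hatchlings$nest_id,
                     function(x) length(unique(x)))
  expect_true(all(per_nest == 1L))
  # every hatchling's mother equals its nest's mother
  i <- match(tr$hatchlings$nest_id, tr$nests$nest_id)
  expect_equal(tr$hatchlings$mother_id, tr$nests$mother_id[i])
  # 18 well-sampled nests, 6 of them multi-paternal; 10 MP nests overall
  expect_equal(sum(tr$nests$n_sampled > 5), 18L)
  expect_equal(sum(tr$nests$n_sampled > 5 & tr$nests$multiple_paternity), 6L)
  expect_equal(sum(tr$nests$multiple_paternity), 10L)
  # the shared father links two mothers of different matrilines
  expect_equal(nrow(tr$shared_pairs), 1L)
  bca <- tr$matrilines$barcode[match(tr$shared_pairs$mother_a,
                                     tr$matrilines$mother_id)]
  bcb <- tr$matrilines$barcode[match(tr$shared_pairs$mother_b,
                                     tr$matrilines$mother_id)]
  expect_true(bca != bcb)
  shared_fathers <- intersect(
    tr$hatchlings$father_id[tr$hatchlings$mother_id == tr$shared_pairs$mother_a],
    tr$hatchlings$father_id[tr$hatchlings$mother_id == tr$shared_pairs$mother_b])
  expect_equal(length(shared_fathers), 1L)
  # matriline sizes follow the configured barcode spectrum
  expect_equal(unname(table(tr$matrilines$barcode)[names(cfg$barcode_counts)]),
               unname(cfg$barcode_counts), ignore_attr = TRUE)
})

test_that("polyandry is off at rate 0 and calibrated at positive rates", {
  cfg0 <- sim_config(n_snps = 50, scenario = "random", polyandry_rate = 0,
                     n_mothers = 30, n_fathers = 60, seed = 7)
  tr0 <- simulate_pedigree(cfg0, simulate_founders(cfg0))$truth
  expect_true(all(!tr0$nests$multiple_paternity))

  # empirical MP fraction within the binomial 95% CI of the rate
  rate <- 0.3
  cfg1 <- sim_config(n_snps = 50, scenario = "random", polyandry_rate = rate,
                     n_mothers = 150, n_fathers = 400,
                     clutches_per_season = c(1, 1), eggs_per_nest = c(2, 4),
                     seed = 8)
  tr1 <- simulate_pedigree(cfg1, simulate_founders(cfg1))$truth
  n <- nrow(tr1$nests)
  phat <- mean(tr1$nests$multiple_paternity)
  expect_lt(abs(phat - rate), 1.96 * sqrt(rate * (1 - rate) / n))
})

test_that("nest schedules respect internesting and remigration ranges", {
  # fixed 14-day interval: clutches at d, d+14, d+28
  cfg <- sim_config(n_snps = 50, scenario = "random",
                    internesting_days = c(14, 14),
                    clutches_per_season = c(3, 3), eggs_per_nest = c(1, 2),
                    n_mothers = 4, n_fathers = 10, polyandry_rate = 0,
                    seed = 9)
  ped <- simulate_pedigree(cfg, simulate_founders(cfg))
  sch <- simulate_nest_schedule(cfg, ped$truth)
  i <- match(ped$truth$nests$nest_id, sch$nest_id)
  for (m in unique(ped$truth$nests$mother_id)) {
    d <- sort(sch$date[i][ped$truth$nests$mother_id == m])
    expect_equal(as.numeric(diff(d)), c(14, 14))
  }

  # default range: all gaps within 8-23 days
  cfg2 <- sim_config(n_snps = 50, seed = 10)
  ped2 <- simulate_pedigree(cfg2, simulate_founders(cfg2))
  sch2 <- simulate_nest_schedule(cfg2, ped2$truth)
  key <- paste(ped2$truth$nests$mother_id[match(sch2$nest_id,
                                                ped2$truth$nests$nest_id)],
               sch2$year)
  gaps <- unlist(lapply(split(sch2$date, key), function(d) diff(sort(d))))
  expect_true(all(gaps >= 8 & gaps <= 23))

  # remigration fixed at 4 years: consecutive seasons 4 years apart
  cfg3 <- sim_config(n_snps = 50, remigration_years = c(4, 4), seed = 11)
  ped3 <- simulate_pedigree(cfg3, simulate_founders(cfg3))
  sch3 <- simulate_nest_schedule(cfg3, ped3$truth)
  mo <- ped3$truth$nests$mother_id[match(sch3$nest_id,
                                         ped3$truth$nests$nest_id)]
  yr_gaps <- unlist(lapply(split(sch3$year, mo), function(y) {
    diff(sort(unique(y)))
  }))
  expect_true(all(yr_gaps == 4))

  # no long-range displacement: a female's nests stay within 6 sd of home,
  # so any two of her nests are within 12 sd of each other
  cfg4 <- sim_config(n_snps = 50, longrange_prob = 0, philopatry_sd_km = 2,
                     seed = 12)
  ped4 <- simulate_pedigree(cfg4, simulate_founders(cfg4))
  sch4 <- simulate_nest_schedule(cfg4, ped4$truth)
  mo4 <- ped4$truth$nests$mother_id[match(sch4$nest_id,
                                          ped4$truth$nests$nest_id)]
  for (m in unique(mo4)) {
    d <- sch4[mo4 == m, ]
    if (nrow(d) < 2) next
    idx <- combn(nrow(d), 2)
    dd <- nest_distance(d$lat[idx[1, ]], d$lon[idx[1, ]],
                        d$lat[idx[2, ]], d$lon[idx[2, ]])
    expect_true(all(dd <= 12 * 2))
  }
})

test_that("identical config and seed give byte-identical datasets that round-trip", {
  cfg <- sim_config(n_snps = 150, scenario = "random", n_mothers = 5,
                    n_fathers = 12, eggs_per_nest = c(2, 4), seed = 13)
  d1 <- tempfile()
  d2 <- tempfile()
  sim1 <- simulate_dataset(cfg, outdir = d1)
  sim2 <- simulate_dataset(cfg, outdir = d2)
  expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                   readLines(file.path(d2, "genotypes.vcf")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))

  back <- read_vcf(file.path(d1, "genotypes.vcf"))
  expect_identical(unname(back$geno), unname(sim1$genotypes$geno))
  expect_identical(rownames(back$geno), rownames(sim1$genotypes$geno))

  # truth JSON carries the mating-event count implied by the parent pairs
  tj <- jsonlite::read_json(file.path(d1, "truth.json"), simplifyVector = TRUE)
  expect_equal(tj$counts$n_mating_events, nrow(unique(tj$mating_events)))

  # id mismatch across tables is an integrity error
  bad_sched <- sim1$schedule
  bad_sched$nest_id[1] <- "NXXX"
  expect_error(write_dataset(sim1$truth, sim1$genotypes, bad_sched, tempfile()),
               "integrity")
})

test_that("the two-family plan builds 11 full sibs plus a 5+5 split nest", {
  cfg <- breeding_stock_config(n_snps = 60, seed = 14)
  tr <- simulate_pedigree(cfg, simulate_founders(cfg))$truth
  expect_equal(tr$counts$n_mating_events, 3L)
  expect_equal(tr$counts$n_hatchlings, 21L)
  expect_equal(sort(tr$nests$n_sampled), c(10L, 11L))
  fam2 <- tr$hatchlings[tr$hatchlings$mother_id == "F02", ]
  expect_equal(as.integer(table(fam2$father_id)), c(5L, 5L))
})
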