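#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (optional) -> filter ->
#' normalized IBS -> parentage reconstruction -> breeding habits. Inputs can
#' come either from a [sim_config()] (a synthetic dataset is generated and
#' written under `outdir/data`) or from files on disk (`vcf`, `nests_csv`,
#' `haplotypes_csv`). A manifest with seeds, stage status and output digests
#' is written to `outdir/manifest.json`; a stage failure halts the run with
#' the failing stage named, keeping earlier outputs.
#'
#' @param outdir output directory.
#' @param config a [sim_config()] for simulated input, or `NULL`.
#' @param vcf,nests_csv,haplotypes_csv input files, used when `config` is
#'   `NULL`.
#' @param filter a [filter_spec()], or `NULL` to skip filtering.
#' @param bands a [kinship_bands()].
#' @param n_perm permutations for the within-nest significance check.
#' @param seed seed for the permutation stage.
#' @param min_overlap minimum jointly called sites per pair.
#' @return Invisibly, a list with the stage results (`genotypes`, `filtered`,
#'   `kinship`, `reconstruction`, `habits`, `permtest`, `manifest`).
#' @export
run_pipeline <- function(outdir, config = NULL, vcf = NULL, nests_csv = NULL,
                         haplotypes_csv = NULL, filter = filter_spec(),
                         bands = kinship_bands(), n_perm = 1000L, seed = 1L,
                         min_overlap = 100L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  if (!is.null(config)) {
    sim <- run_stage("simulate", {
      simulate_dataset(config, outdir = file.path(outdir, "data"))
    })
    gm <- sim$genotypes
    nests <- sim$nests
    haps <- sim$haplotypes
  } else {
    sim <- NULL
    gm <- run_stage("read", {
      if (is.null(vcf) || !file.exists(vcf)) {
        stop("input VCF not found: ", if (is.null(vcf)) "<missing>" else vcf)
      }
      read_vcf(vcf)
    })
    nests <- run_stage("read", {
      if (is.null(nests_csv) || !file.exists(nests_csv)) {
        stop("nests CSV not found: ",
             if (is.null(nests_csv)) "<missing>" else nests_csv)
      }
      read.csv(nests_csv, stringsAsFactors = FALSE)
    })
    haps <- if (!is.null(haplotypes_csv)) {
      run_stage("read", read.csv(haplotypes_csv, stringsAsFactors = FALSE))
    }
  }

  filtered <- run_stage("filter", {
    if (is.null(filter)) list(gm = gm, report = NULL) else
      apply_filters(gm, filter)
  })
  if (!is.null(filtered$report)) {
    write_filter_report(filtered$report, file.path(outdir, "filter_report.tsv"))
  }

  recon <- run_stage("reconstruct", {
    reconstruct_parentage(filtered$gm, nests, haplotypes = haps,
                          bands = bands, min_overlap = min_overlap)
  })
  utils::write.table(
    round(recon$kinship$normalized, 6), file.path(outdir, "normalized_ibs.tsv"),
    sep = "\t", quote = FALSE
  )
  jsonlite::write_json(
    list(counts = recon$counts, mothers = recon$mothers,
         fathers = recon$fathers, mating_events = recon$mating_events,
         nests = recon$nests),
    file.path(outdir, "reconstruction.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )

  permtest <- run_stage("permtest", {
    groups <- setNames(
      nests$nest_id[match(gm_samples(filtered$gm), nests$sample_id)],
      gm_samples(filtered$gm)
    )
    sizes <- table(groups)
    if (any(sizes >= 2)) {
      permutation_ci(recon$kinship$normalized, groups, n_perm = n_perm,
                     seed = seed)
    }
  })

  habits <- run_stage("habits", breeding_habits(recon, nests))
  utils::write.table(habits$internesting,
                     file.path(outdir, "internesting_intervals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(habits$distances, file.path(outdir, "nest_distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("nestkin")),
    seed = seed,
    sim_seed = if (!is.null(config)) config$seed,
    stages = stages,
    counts = recon$counts,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    sim = sim, genotypes = gm, filtered = filtered, kinship = recon$kinship,
    reconstruction = recon, habits = habits, permtest = permtest,
    manifest = manifest
  ))
}
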