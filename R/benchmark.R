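#' Configure an end-to-end benchmark run
#'
#' Bundles the simulation and analysis parameters for
#' [run_benchmark()]. Coverage levels must be positive and strictly
#' descending (the down-sampling ladder).
#'
#' @param seed master seed; every stage derives its own stream from it
#' @param n_samples cohort size
#' @param n_markers markers on the simulated chromosome
#' @param chrom_length_bp chromosome length
#' @param n_gen outbreeding generation
#' @param coverages descending coverage ladder (the first level is "full")
#' @param array_fraction fraction of panel markers on the simulated array
#' @param base_error sequencing per-read error
#' @param call_error array per-call error
#' @param ibd_spec optional engineered founder IBD blocks (see
#'   [simulate_founder_panel()])
#' @param min_snps adaptive-filter retention target (scaled to the
#'   synthetic chromosome)
#' @param out_dir output directory
#' @return a `benchmark_config` list
#' @export
benchmark_config <- function(seed = 1, n_samples = 4, n_markers = 400,
                             chrom_length_bp = 50e6, n_gen = 41,
                             coverages = c(1, 0.1, 0.01),
                             array_fraction = 0.2,
                             base_error = 0.001, call_error = 0.002,
                             ibd_spec = NULL, min_snps = 50,
                             out_dir = tempfile("dobench_")) {
  if (any(coverages <= 0) || any(diff(coverages) >= 0)) {
    stop("`coverages` must be positive and strictly descending")
  }
  structure(as.list(environment()), class = "benchmark_config")
}

#' Run the simulate-impute-reconstruct-compare benchmark
#'
#' Simulates a DO cohort with known truth, sequences it at the top of the
#' coverage ladder, thins depth down the ladder, reconstructs haplotypes
#' from sequencing (via the diplotype HMM) and from array calls, and
#' tabulates per-coverage concordance, imputation accuracy against truth,
#' crossover counts, and IBD classification of discordant regions. All
#' stage outputs are written under `config$out_dir` as plain text together
#' with a JSON manifest and summary.
#'
#' @param config a `benchmark_config`
#' @return list of class `benchmark_run`: `summary` (per-coverage tibble),
#'   `discordance`, `run_dir`, `manifest`
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, 8)

  panel <- simulate_founder_panel(config$n_markers, config$chrom_length_bp,
                                  ibd_spec = config$ibd_spec, seed = seeds[1])
  write_panel_tsv(panel, file.path(config$out_dir, "panel.tsv"))
  mosaics <- simulate_do_diplotypes(panel, config$n_gen, config$n_samples,
                                    seed = seeds[2])
  write_mosaics_bed(mosaics, file.path(config$out_dir, "mosaics.bed"))
  truth_dose <- t(vapply(mosaics, mosaic_doses, integer(nrow(panel$map)),
                         panel = panel))
  depths_full <- simulate_reads(mosaics, panel, config$coverages[1],
                                config$base_error, seed = seeds[3])
  array_idx <- select_grid(panel, max(2, round(config$array_fraction *
                                                 nrow(panel$map))))
  calls <- simulate_array_calls(mosaics, panel, array_idx,
                                config$call_error, seed = seeds[4])
  recon_array <- reconstruct_cohort(calls, panel, config$n_gen,
                                    array_error = config$call_error)

  per_cov <- list()
  discord <- NULL
  ibd <- find_ibd_segments(panel)
  for (ci in seq_along(config$coverages)) {
    cov <- config$coverages[ci]
    depths <- if (ci == 1) depths_full else {
      downsample_depths(depths_full, cov, seed = seeds[5] + ci)
    }
    write_depths_tsv(depths, file.path(config$out_dir, sprintf("depths_%g", cov)))
    recon <- reconstruct_cohort(depths, panel, config$n_gen)
    write_matrix_tsv(recon$dosage,
                     file.path(config$out_dir, sprintf("dosage_%g.tsv", cov)))
    flt <- adaptive_info_filter(
      recon$info,
      hwe_pvalue(colSums(recon$hard_call == 0), colSums(recon$hard_call == 1),
                 colSums(recon$hard_call == 2)),
      min_snps = min(config$min_snps, nrow(panel$map) - 1), chrom = panel$chrom)
    xo <- count_crossovers(recon)
    cos_means <- numeric(config$n_samples)
    n_regions <- 0
    n_explained <- 0
    for (i in seq_len(config$n_samples)) {
      pg <- interpolate_probs(matrix(recon_array$alleleprob[i, , ], ncol = 8),
                              recon_array$map, recon$map)
      pq <- matrix(recon$alleleprob[i, , ], ncol = 8)
      track <- concordance_track(pg, pq, recon$map)
      cos_means[i] <- attr(track, "mean_cosine")
      regions <- flag_discordant_regions(track)
      if (nrow(regions)) {
        cls <- classify_discordance_ibd(regions, ibd, pg, pq)
        n_regions <- n_regions + nrow(cls)
        n_explained <- n_explained + sum(cls$ibd_explained)
        if (ci == 1) {
          discord <- dplyr::bind_rows(discord,
                                      dplyr::mutate(cls, sample = i, .before = 1))
        }
      }
    }
    per_cov[[ci]] <- tibble::tibble(
      coverage = cov,
      mean_concordance = mean(cos_means),
      hard_call_accuracy = mean(recon$hard_call == truth_dose),
      dosage_rmse = sqrt(mean((recon$dosage - truth_dose)^2)),
      mean_info = mean(recon$info),
      final_info_cutoff = flt$report$final_info_cutoff,
      n_retained = flt$report$n_retained,
      mean_crossovers = mean(xo$n_crossovers),
      n_discordant_regions = n_regions,
      frac_ibd_explained = ifelse(n_regions > 0, n_explained / n_regions, NA_real_)
    )
  }
  summary <- dplyr::bind_rows(per_cov)
  utils::write.table(as.data.frame(summary),
                     file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dohaplo")),
    seed = config$seed,
    config = config[setdiff(names(config), "ibd_spec")],
    expected_crossovers_genomewide = expected_crossovers(config$n_gen),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(summary = summary, discordance = discord,
                 run_dir = config$out_dir, manifest = manifest),
            class = "benchmark_run")
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat("<benchmark_run>", x$run_dir, "\n")
  print(x$summary)
  invisible(x)
}

#' Validate the outputs of a benchmark run
#'
#' Re-reads the files written by [run_benchmark()] and checks structural
#' invariants: the manifest exists, the panel is binary/strictly ordered,
#' mosaic segments tile without gaps, dosage values lie in [0, 2] and the
#' summary's concordance column is within [0, 1]. Violations are listed,
#' not thrown; unreadable files are reported as violations.
#'
#' @param run_dir directory of a completed run
#' @return tibble with `check`, `file`, `ok`, `detail`
#' @export
validate_outputs <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json"))) {
    stop("missing manifest.json in ", run_dir)
  }
  checks <- list()
  add <- function(check, file, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(check = check, file = file,
                                                    ok = ok, detail = detail)
  }
  try_read <- function(check, file, fn) {
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error")) {
      add(check, file, FALSE, paste("read error:", conditionMessage(out)))
      NULL
    } else out
  }
  pf <- file.path(run_dir, "panel.tsv")
  panel <- try_read("panel", "panel.tsv", function() read_panel_tsv(pf))
  if (!is.null(panel)) {
    ok <- !inherits(tryCatch(validate_panel(panel), error = identity), "error")
    add("panel invariants", "panel.tsv", ok)
  }
  mb <- file.path(run_dir, "mosaics.bed")
  seg <- try_read("mosaics", "mosaics.bed", function() {
    read.table(mb, header = TRUE, sep = "\t", comment.char = "#")
  })
  if (!is.null(seg)) {
    tiles <- seg |>
      dplyr::group_by(sample, homolog) |>
      dplyr::arrange(start_bp, .by_group = TRUE) |>
      dplyr::summarise(ok = all(abs(start_bp[-1] - end_bp[-dplyr::n()]) < 1e-6),
                       .groups = "drop")
    add("mosaic tiling", "mosaics.bed", all(tiles$ok))
  }
  for (f in list.files(run_dir, pattern = "^dosage_.*\\.tsv$")) {
    m <- try_read("dosage", f, function() read_matrix_tsv(file.path(run_dir, f)))
    if (!is.null(m)) {
      add("dosage range", f, all(m >= -1e-9 & m <= 2 + 1e-9))
    }
  }
  sm <- try_read("summary", "summary.tsv", function() {
    read.table(file.path(run_dir, "summary.tsv"), header = TRUE, sep = "\t")
  })
  if (!is.null(sm)) {
    add("concordance range", "summary.tsv",
        all(sm$mean_concordance >= 0 & sm$mean_concordance <= 1))
  }
  dplyr::bind_rows(checks)
}
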