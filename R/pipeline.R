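## End-to-end orchestration: a demo synthetic cohort written to disk, a
## manifest schema, and per-modality runs that combine the analysis modules
## with the group-statistics decision rule.

GENOTYPES <- c("WT", "Het", "Hom")

#' Default analysis configuration
#'
#' All thresholds live here with their conventional defaults: the 8 um
#' plaque-diameter filter, the 30 um plaque-centered radius, DEG cuts FDR
#' 0.05 and |log2FC| 0.25, soft power 12, minimum module size 40, eigengene
#' merge cut 0.4, QC bands, and the small-sample cutoff of the statistical
#' decision rule.
#' @export
default_config <- function() {
  list(
    ephys = list(fv_window_ms = c(0.5, 2), fepsp_search_window_ms = c(2, 12)),
    clearance = list(paper_constants = FALSE, include_t0 = FALSE),
    histo = list(plaque_threshold = 0.5, soma_threshold = 0.8,
                 min_plaque_diameter_um = 8, radius_um = 30),
    assay = list(reference_group = "WT"),
    transcript = list(min_gene_count_pct = 50, strandness_band = c(0.7, 1.0),
                      min_count = 10, min_samples = 4,
                      fdr_cut = 0.05, lfc_cut = 0.25,
                      beta = 12, min_module_size = 40, merge_cut = 0.4),
    stats = list(large_n = 7, alpha_var = 0.05)
  )
}

#' Validate a cohort manifest
#'
#' A manifest is a data.frame with columns \code{animal_id, genotype,
#' modality, file}; genotypes must come from WT/Het/Hom and files must exist.
#' Violations are reported with their row numbers.
#' @export
validate_manifest <- function(manifest, check_files = TRUE) {
  req <- c("animal_id", "genotype", "modality", "file")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!manifest$genotype %in% GENOTYPES)
  if (length(bad)) {
    stop(sprintf("manifest row %d: unknown genotype '%s'",
                 bad[1], manifest$genotype[bad[1]]), call. = FALSE)
  }
  if (check_files) {
    gone <- which(!file.exists(manifest$file))
    if (length(gone)) {
      stop(sprintf("manifest row %d: file not found '%s'",
                   gone[1], manifest$file[gone[1]]), call. = FALSE)
    }
  }
  invisible(manifest)
}

#' Generate a full synthetic demo cohort on disk
#'
#' Writes, per animal and modality, the portable files every analysis module
#' reads (fraction CSVs, LTP session CSVs, TIFF planes with YAML sidecars, a
#' PRM manifest, a count TSV + metadata CSV), a manifest CSV, and the ground
#' truth JSON. Homozygous animals carry the planted effects: faster
#' interstitial-fluid clearance (higher Ke), higher soluble TREM2, and lower
#' plaque burden.
#'
#' @param dir output directory (created).
#' @param seed master seed; per-animal seeds derive from it.
#' @param n_per_group animals per genotype group (WT and Hom).
#' @param hom_ke_factor planted Hom/WT ratio of the elimination rate.
#' @param hom_strem2_factor planted Hom/WT ratio of soluble TREM2.
#' @param hom_plaque_factor planted Hom/WT ratio of plaque count.
#' @param ltp_minutes if not NULL, c(baseline, post) minutes for a reduced
#'   ephys session (NULL = the conventional 20/60).
#' @return the manifest data.frame (invisibly written to
#'   \code{dir/manifest.csv}).
#' @export
make_demo_cohort <- function(dir, seed = 1, n_per_group = 3,
                             hom_ke_factor = 2.0, hom_strem2_factor = 1.6,
                             hom_plaque_factor = 0.5, ltp_minutes = c(5, 10)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("clearance", "ephys", "histo", "assay", "transcript")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  animals <- data.frame(
    animal_id = sprintf("m%02d", seq_len(2 * n_per_group)),
    genotype = rep(c("WT", "Hom"), each = n_per_group)
  )
  rows <- list(); truths <- list()
  prm_all <- list()
  for (i in seq_len(nrow(animals))) {
    id <- animals$animal_id[i]; gt <- animals$genotype[i]
    aseed <- (seed * 1000 + i) %% .Machine$integer.max
    hom <- gt == "Hom"

    ## microdialysis
    ke <- 0.4 * if (hom) hom_ke_factor else 1
    g <- gen_dialysis_series(baseline_conc = 120, Ke_per_h = ke,
                             noise_cv = 0.08, seed = aseed, animal_id = id)
    f <- file.path(dir, "clearance", paste0(id, ".csv"))
    write_series_csv(g$series, f)
    truths[[paste0(id, "_clearance")]] <- unclass(g$truth)
    rows[[length(rows) + 1]] <- data.frame(animal_id = id, genotype = gt,
                                           modality = "clearance", file = f)

    ## LTP session (reduced length by default; structure unchanged)
    ltp <- gen_ltp_session(baseline_slope = -1.5,
                           potentiation_factor = if (hom) 1.55 else 1.35,
                           n_baseline_min = ltp_minutes[1],
                           n_post_min = ltp_minutes[2],
                           noise = 0.05, seed = aseed)
    f <- file.path(dir, "ephys", paste0(id, "_ltp.csv"))
    write_session_csv(ltp$session, f)
    truths[[paste0(id, "_ltp")]] <- unclass(ltp$truth)
    rows[[length(rows) + 1]] <- data.frame(animal_id = id, genotype = gt,
                                           modality = "ephys_ltp", file = f)

    ## histology scene
    n_plaques <- round(10 * if (hom) hom_plaque_factor else 1)
    sc_seed <- aseed + 7
    scene <- with_seed(sc_seed, {
      pl <- data.frame(x_um = runif(n_plaques, 25, 175),
                       y_um = runif(n_plaques, 25, 175),
                       diameter_um = runif(n_plaques, 10, 20))
      mg <- lapply(seq_len(6), function(k) {
        microglion_star(c(runif(1, 30, 170), runif(1, 30, 170)),
                        n_arms = 4, lengths_um = 15)
      })
      gen_scene(roi_size_um = 200, pixel_size_um = 0.8, plaques = pl,
                microglia = mg, seed = sc_seed)
    })
    f <- file.path(dir, "histo", paste0(id, "_plaque.tif"))
    write_plane_tiff(scene$planes$plaque, f)
    write_plane_tiff(scene$planes$microglia,
                     file.path(dir, "histo", paste0(id, "_microglia.tif")))
    truths[[paste0(id, "_scene")]] <- unclass(scene$truth)["params"]
    rows[[length(rows) + 1]] <- data.frame(animal_id = id, genotype = gt,
                                           modality = "histo", file = f)

    ## PRM
    s_amt <- 2.0 * if (hom) hom_strem2_factor else 1
    prm <- gen_prm_run(c(`sTREM2-WT` = if (hom) 0 else s_amt,
                         `flTREM2-WT` = if (hom) 0 else 3.0,
                         `sTREM2-H157Y` = if (hom) s_amt else 0,
                         `flTREM2-H157Y` = if (hom) 3.0 else 0),
                       noise_cv = 0.08, sample_id = id, genotype = gt,
                       seed = aseed + 13)
    prm_all[[i]] <- prm$measurements
    truths[[paste0(id, "_prm")]] <- unclass(prm$truth)
  }
  f <- file.path(dir, "assay", "prm.csv")
  write_prm_csv(do.call(rbind, prm_all), f)
  for (i in seq_len(nrow(animals))) {
    rows[[length(rows) + 1]] <- data.frame(animal_id = animals$animal_id[i],
                                           genotype = animals$genotype[i],
                                           modality = "assay", file = f)
  }

  ## transcript: one cohort-level count matrix with a planted immune module
  cg <- gen_counts(n_genes = 1000,
                   groups = rep(c("WT", "Hom"), each = max(5, n_per_group)),
                   de_genes = setNames(rep(2, 30), as.character(1:30)),
                   module_genes = 101:160, seed = seed + 99)
  fc <- file.path(dir, "transcript", "counts.tsv")
  write_counts_tsv(cg$counts, fc)
  utils::write.csv(cg$meta, file.path(dir, "transcript", "meta.csv"),
                   row.names = FALSE)
  truths[["transcript"]] <- unclass(cg$truth)["params"]
  rows[[length(rows) + 1]] <- data.frame(animal_id = "cohort", genotype = "WT",
                                         modality = "transcript", file = fc)

  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = seed, truths = truths),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Run one modality of a cohort end-to-end
#'
#' Reads the files listed in the manifest for the modality, extracts
#' per-sample metrics, and compares genotype groups with the statistical
#' decision rule.
#'
#' @param manifest a validated cohort manifest (see
#'   \code{\link{validate_manifest}}).
#' @param modality one of \code{"clearance"}, \code{"ephys_ltp"},
#'   \code{"histo"}, \code{"assay"}, \code{"transcript"}.
#' @param config configuration list (see \code{\link{default_config}}).
#' @return list with \code{metrics} (per-sample data.frame), \code{comparison}
#'   (group test results, where applicable) and \code{config} echo.
#' @export
run_modality <- function(manifest, modality, config = default_config()) {
  validate_manifest(manifest)
  rows <- manifest[manifest$modality == modality, , drop = FALSE]
  if (nrow(rows) == 0) stop("manifest has no rows for modality ", modality, call. = FALSE)

  compare_groups <- function(metrics, value_col) {
    grps <- split(metrics[[value_col]], metrics$genotype)
    grps <- grps[vapply(grps, length, 1L) >= 2]
    if (length(grps) < 2) return(NULL)
    sizes <- vapply(grps, length, 1L)
    fp <- if (length(grps) == 2) f_test_var(grps[[1]], grps[[2]])$p_value else NA_real_
    if (length(grps) == 2 && is.na(fp)) fp <- 1
    plan <- choose_test(sizes, n_groups = length(grps), variance_f_test_p = fp,
                        alpha_var = config$stats$alpha_var,
                        large_n = config$stats$large_n)
    res <- apply_test_plan(plan, grps)
    list(plan = plan, p_value = res$p_value, statistic = res$statistic,
         group_means = vapply(grps, mean, numeric(1)))
  }

  if (modality == "clearance") {
    metrics <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      fit <- fit_elimination(read_series_csv(rows$file[i]),
                             paper_constants = config$clearance$paper_constants)
      data.frame(animal_id = rows$animal_id[i], genotype = rows$genotype[i],
                 Ke_per_h = fit$Ke_per_h, half_life_h = fit$half_life_h,
                 r2 = fit$r2)
    }))
    cmp <- compare_groups(metrics, "half_life_h")
  } else if (modality == "ephys_ltp") {
    metrics <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      prof <- ltp_profile(read_session_csv(rows$file[i]),
                          fv_window_ms = config$ephys$fv_window_ms,
                          fepsp_search_window_ms = config$ephys$fepsp_search_window_ms)
      data.frame(animal_id = rows$animal_id[i], genotype = rows$genotype[i],
                 last5_mean_pct = attr(prof, "last5_mean"))
    }))
    cmp <- compare_groups(metrics, "last5_mean_pct")
  } else if (modality == "histo") {
    metrics <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      plane <- read_plane_tiff(rows$file[i])
      det <- detect_particles(plane, threshold = config$histo$plaque_threshold,
                              min_diameter_um = config$histo$min_plaque_diameter_um)
      data.frame(animal_id = rows$animal_id[i], genotype = rows$genotype[i],
                 plaque_count = det$count,
                 plaque_density_per_mm2 = det$density_per_mm2,
                 area_pct = area_fraction(plane,
                                          threshold = config$histo$plaque_threshold))
    }))
    cmp <- compare_groups(metrics, "plaque_density_per_mm2")
  } else if (modality == "assay") {
    meas <- read_prm_csv(rows$file[1])
    quant <- trem2_summary(meas)
    gt <- meas$genotype[match(quant$sample_id, meas$sample_id)]
    metrics <- data.frame(animal_id = quant$sample_id, genotype = gt,
                          s_total_fmol = quant$s_total_fmol,
                          fl_total_fmol = quant$fl_total_fmol,
                          s_fl_ratio = quant$s_fl_ratio)
    cmp <- compare_groups(metrics, "s_total_fmol")
  } else if (modality == "transcript") {
    counts <- read_counts_tsv(rows$file[1])
    meta <- utils::read.csv(file.path(dirname(rows$file[1]), "meta.csv"))
    qc <- sample_qc(counts, meta,
                    min_gene_count_pct = config$transcript$min_gene_count_pct,
                    strandness_band = config$transcript$strandness_band)
    filt <- filter_genes(qc$counts, config$transcript$min_count,
                         config$transcript$min_samples)
    fac <- tmm_factors(filt)
    de <- genewise_de_test(filt, fac, qc$meta$group)
    de$fdr <- bh_adjust(de$p_value)
    de <- classify_deg(de, config$transcript$fdr_cut, config$transcript$lfc_cut)
    metrics <- de
    cmp <- list(n_up = sum(de$status == "up"), n_down = sum(de$status == "down"))
  } else {
    stop("unknown modality: ", modality, call. = FALSE)
  }
  list(metrics = metrics, comparison = cmp, config = config[[sub("_.*", "", modality)]])
}
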