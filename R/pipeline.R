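# End-to-end orchestration: phantom generation -> image quantification ->
# eye-table assembly -> DME exclusion -> phenotyping -> statistics, with a
# JSON provenance record sufficient to reproduce every output.

#' Pipeline configuration
#'
#' Nested key/value configuration with defaults anchored to the published
#' analysis constants (2.5-mm annulus with 0.6-mm exclusion, SSI gate at
#' 40, 275-um DME exclusion, 1.96-SD phenotype band, alpha = 0.05).
#' Unknown keys are errors.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param output_dir where `run_pipeline` writes results.
#' @param overrides nested named list overriding any default key, e.g.
#'   `list(octa = list(min_ssi = 45))`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, output_dir = tempfile("octaphen_"),
                            overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    output_dir = output_dir,
    cohort = list(csv = NULL),          # optional external cohort table
    imaging = list(n_demo_eyes = 2L,    # eyes quantified from images
                   bscan_noise_sd = 0.02, angiogram_noise_sd = 0.02),
    oct = list(sigma = 1.5, margin = 3, thin_margin = 2, axial_pitch = 3.0),
    octa = list(outer_diameter_mm = 2.5, inner_exclusion_diameter_mm = 0.6,
                grid_size = 1024L, min_ssi = 40, closing_radius_px = 2),
    phenotyping = list(z = 1.96),
    dme = list(threshold_um = 275),
    stats = list(alpha = 0.05, percent_digits = 1, p_digits = 3)
  )
  merge_checked <- function(base, over, path = "") {
    for (k in names(over)) {
      if (!k %in% names(base)) {
        stop("unknown configuration key: ", path, k, call. = FALSE)
      }
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_checked(base[[k]], over[[k]],
                                   paste0(path, k, "."))
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  structure(merge_checked(cfg, overrides), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' The file holds the same nested keys as [pipeline_config()]; unknown
#' keys are errors.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- raw$seed %||% 1L
  outdir <- raw$output_dir %||% tempfile("octaphen_")
  raw$seed <- NULL; raw$output_dir <- NULL
  pipeline_config(seed = seed, output_dir = outdir, overrides = raw)
}

# 31-bit polynomial string hash for provenance fingerprints (no hashing
# package in the dependency set; collision resistance is not a goal).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "[", stage, "] ", ...)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, quantifies phantom images for a subset of
#' eyes to demonstrate the imaging chain, applies the quality gate and the
#' DME exclusion, classifies phenotypes against the control reference, and
#' runs the statistical chain. All outputs are CSV/JSON in
#' `config$output_dir`; a rerun with an identical config reproduces them
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `records`, `flags`, `summary`,
#'   `univariate`, `multivariate`, `interaction`, `roc`, `imaging_qc`,
#'   and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # -- cohort ---------------------------------------------------------------
  records <- run_stage("cohort", {
    if (!is.null(config$cohort$csv)) {
      log_stage("cohort", "reading ", config$cohort$csv)
      read_cohort_csv(config$cohort$csv)
    } else {
      log_stage("cohort", "generating synthetic cohort")
      generate_cohort(cohort_spec(seed = derive_seed(seed, 1)))$records
    }
  })

  # -- imaging demo: quantify phantom images for the first k DR eyes -------
  imaging_qc <- run_stage("imaging", {
    k <- min(config$imaging$n_demo_eyes,
             sum(records$group != "control"))
    qc <- list()
    if (k > 0) {
      dr_idx <- which(records$group != "control")[seq_len(k)]
      for (j in seq_along(dr_idx)) {
        i <- dr_idx[j]
        log_stage("imaging", "eye ", records$subject_id[i], "/",
                  records$eye[i])
        bs <- generate_bscan(bscan_phantom_spec(
          layer_thicknesses = c(records$rnfl_um[i], records$gcl_ipl_um[i],
                                records$inl_um[i], records$opl_um[i],
                                110.93),
          noise_sd = config$imaging$bscan_noise_sd,
          axial_pitch = config$oct$axial_pitch,
          seed = derive_seed(seed, 100 + j)))
        seg <- segment_layers(bs$bscan, sigma = config$oct$sigma,
                              margin = config$oct$margin,
                              thin_margin = config$oct$thin_margin)
        th <- compute_thicknesses(seg)
        an <- generate_angiogram(angiogram_phantom_spec(
          target_skeleton_density = records$vd_drcp[i],
          noise_sd = config$imaging$angiogram_noise_sd,
          ssi = 60, seed = derive_seed(seed, 200 + j)))
        geom <- annulus_geometry(
          outer_diameter_mm = config$octa$outer_diameter_mm,
          inner_exclusion_diameter_mm =
            config$octa$inner_exclusion_diameter_mm,
          scan_width_mm = an$angiogram$scan_width_mm,
          grid_size = config$octa$grid_size)
        qm <- quantify_angiogram(an$angiogram, geom,
                                 min_ssi = config$octa$min_ssi)
        if (!qm$ssi_pass) next  # gated scans contribute no measurements
        # measured values replace the generated ones for these eyes
        records$rnfl_um[i] <- th$rnfl_um
        records$gcl_ipl_um[i] <- th$gcl_ipl_um
        records$inl_um[i] <- th$inl_um
        records$opl_um[i] <- th$opl_um
        records$total_um[i] <- th$total_um
        records$vd_drcp[i] <- qm$vd
        records$faz_area_mm2[i] <- qm$faz_area_mm2
        qc[[j]] <- list(
          row = i, subject_id = records$subject_id[i],
          thickness = unclass(th), vd = qm$vd,
          faz_area_mm2 = qm$faz_area_mm2,
          truth_vd = an$truth$skeleton_density,
          truth_faz = an$truth$faz_area_mm2, ssi_pass = qm$ssi_pass)
      }
    }
    qc
  })

  # -- DME exclusion --------------------------------------------------------
  records <- run_stage("dme_exclusion", {
    keep <- records$total_um < config$dme$threshold_um
    log_stage("dme_exclusion", sum(!keep), " eye(s) excluded at >= ",
              config$dme$threshold_um, " um")
    records[keep, , drop = FALSE]
  })

  # -- phenotyping ----------------------------------------------------------
  pheno <- run_stage("phenotyping", {
    controls <- records[records$group == "control", ]
    ref <- fit_normative_reference(controls)
    dr <- records[records$group != "control", ]
    flags <- classify_cohort(dr, ref)
    strata <- ifelse(dr$bcva_logmar > 0, "decreased_bcva", "normal_bcva")
    list(reference = ref, flags = flags, dr = dr,
         summary = phenotype_summary(flags, strata))
  })

  # -- statistics -----------------------------------------------------------
  stats_out <- run_stage("statistics", {
    dr <- pheno$dr
    uni <- univariate_screen(dr)
    sel <- uni$predictor[uni$significant]
    if (length(sel) == 0) sel <- c("age", "vd_drcp", "gcl_ipl_um")
    multi <- multivariate_model(dr, sel)
    inter <- interaction_model(dr)
    roc <- lapply(c("vd_drcp", "gcl_ipl_um"), function(p)
      roc_cutoff(dr, p))
    list(univariate = uni, multivariate = multi, interaction = inter,
         roc = roc)
  })

  # -- outputs --------------------------------------------------------------
  paths <- run_stage("write_outputs", {
    out <- function(f) file.path(config$output_dir, f)
    write_cohort_csv(records, out("cohort.csv"))
    utils::write.csv(cbind(pheno$dr[, c("subject_id", "eye", "group")],
                           pheno$flags),
                     out("flags.csv"), row.names = FALSE)
    utils::write.csv(pheno$summary, out("table2.csv"), row.names = FALSE)
    utils::write.csv(stats_out$univariate, out("univariate.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_out$multivariate$coefficients,
                     out("multivariate.csv"), row.names = FALSE)
    utils::write.csv(stats_out$interaction$coefficients,
                     out("interaction.csv"), row.names = FALSE)
    roc_df <- do.call(rbind, lapply(stats_out$roc, function(r)
      data.frame(parameter = r$parameter, auc = r$auc, cutoff = r$cutoff,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 direction = r$direction)))
    utils::write.csv(roc_df, out("roc.csv"), row.names = FALSE)
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA, null = "null")
    jsonlite::write_json(list(
      config = unclass(config), config_hash = fnv1a(as.character(cfg_json)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("octaphen")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      imaging_qc = imaging_qc
    ), out("provenance.json"), auto_unbox = TRUE, digits = NA,
      null = "null", pretty = TRUE)
    list(dir = config$output_dir)
  })

  invisible(list(records = records, flags = pheno$flags,
                 summary = pheno$summary,
                 univariate = stats_out$univariate,
                 multivariate = stats_out$multivariate,
                 interaction = stats_out$interaction,
                 roc = stats_out$roc, imaging_qc = imaging_qc,
                 paths = paths))
}

#' Write the versioned test/demo fixture set
#'
#' Three B-scan phantoms, three angiograms, one cohort CSV, ground-truth
#' JSON sidecars and a manifest. Byte-identical on rerun with the same
#' seed.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return `dir`, invisibly; the manifest is `manifest.json`.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("octaphen_fixtures_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, bscans = list(), angiograms = list(),
                   cohort = "cohort.csv")
  for (j in 1:3) {
    bs <- generate_bscan(bscan_phantom_spec(
      n_columns = 128, noise_sd = c(0, 0.02, 0.05)[j],
      seed = derive_seed(seed, 10 + j)))
    f <- sprintf("bscan_%d.pgm", j)
    write_pgm(bs$bscan$intensity, file.path(dir, f))
    jsonlite::write_json(
      list(axial_pitch = bs$bscan$axial_pitch,
           lateral_pitch = bs$bscan$lateral_pitch,
           boundaries_px = bs$truth$boundaries_px),
      file.path(dir, sprintf("bscan_%d_truth.json", j)),
      digits = NA, auto_unbox = TRUE)
    manifest$bscans[[j]] <- f
  }
  for (j in 1:3) {
    an <- generate_angiogram(angiogram_phantom_spec(
      target_skeleton_density = c(0.052, 0.062, 0.072)[j],
      seed = derive_seed(seed, 20 + j)))
    f <- sprintf("angio_%d.pgm", j)
    write_pgm(an$angiogram$intensity, file.path(dir, f))
    jsonlite::write_json(
      list(scan_width_mm = an$angiogram$scan_width_mm,
           skeleton_density = an$truth$skeleton_density,
           faz_area_mm2 = an$truth$faz_area_mm2),
      file.path(dir, sprintf("angio_%d_truth.json", j)),
      digits = NA, auto_unbox = TRUE)
    manifest$angiograms[[j]] <- f
  }
  ch <- generate_cohort(cohort_spec(seed = derive_seed(seed, 30)))
  write_cohort_csv(ch$records, file.path(dir, "cohort.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
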