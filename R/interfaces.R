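# I/O, configuration and dataset assembly shared by all stages: NIfTI
# loaders, behavioral TSV round-tripping with explicit column mappings, and
# a provenance-stamped pipeline driver.

#' Load a BOLD run from NIfTI
#'
#' Reads a 4D image and one or more label masks on the same grid, restricts
#' the voxel x time matrix to the union of the masks, and attaches region /
#' compartment labels per voxel. Voxels containing NaN are dropped with a
#' logged count.
#'
#' @param path 4D NIfTI file.
#' @param mask_paths Named character vector of label NIfTI files; each name
#'   becomes the compartment for that mask's nonzero voxels. Distinct
#'   nonzero label values within a mask become `"<name><value>"` regions
#'   (a single value keeps the plain name).
#' @param tr_seconds TR; default read from the NIfTI header (pixdim 4).
#' @param participant_id Identifier stored on the run.
#' @return A `bold_run`.
#' @export
load_bold <- function(path, mask_paths, tr_seconds = NULL,
                      participant_id = 1L) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) abort("expected a 4D NIfTI image")
  dims <- dim(img)[1:3]
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_seconds) || tr_seconds <= 0) tr_seconds <- 1.5
  }
  vox_list <- purrr::imap(mask_paths, function(mp, nm) {
    m <- RNifti::readNifti(mp)
    mdim <- c(dim(m), 1L, 1L)[1:3]
    dim(m) <- mdim
    if (!identical(mdim, dims)) {
      abort(sprintf("grid mismatch for mask '%s': %s vs %s", nm,
                    paste(mdim, collapse = "x"),
                    paste(dims, collapse = "x")))
    }
    idx <- which(m != 0)
    if (length(idx) == 0) abort(sprintf("mask '%s' selects 0 voxels", nm))
    vals <- as.integer(m[idx])
    roi <- if (dplyr::n_distinct(vals) > 1) paste0(nm, vals) else nm
    tibble(lin = idx, roi = roi, compartment = nm)
  })
  vox <- bind_rows(vox_list) %>% distinct(.data$lin, .keep_all = TRUE)
  flat <- matrix(img, prod(dims), dim(img)[4])
  data <- flat[vox$lin, , drop = FALSE]
  bad <- rowSums(!is.finite(data)) > 0
  if (any(bad)) {
    inform(sprintf("dropped %d voxel(s) containing NaN", sum(bad)))
    vox <- vox[!bad, ]
    data <- data[!bad, , drop = FALSE]
  }
  coords <- arrayInd(vox$lin, dims)
  structure(list(
    participant_id = participant_id, data = data, tr_seconds = tr_seconds,
    voxels = tibble(voxel = seq_len(nrow(vox)), roi = vox$roi,
                    compartment = vox$compartment, high_sd = FALSE,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    latent = NULL
  ), class = "bold_run")
}

#' Write a synthetic run as NIfTI
#'
#' Lays the run's voxels along the first axis (`V x 1 x 1 x T`) and writes
#' one label volume per compartment, so [load_bold()] round-trips the data.
#'
#' @param run A `bold_run`.
#' @param dir Output directory.
#' @param prefix File prefix.
#' @return Invisibly, the written file paths.
#' @export
write_bold_nifti <- function(run, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  V <- nrow(run$data); T_ <- ncol(run$data)
  img <- array(run$data, c(V, 1, 1, T_))
  nii <- RNifti::asNifti(img, pixdim = c(1, 1, 1, run$tr_seconds))
  bold_path <- file.path(dir, sprintf("%s_bold.nii.gz", prefix))
  RNifti::writeNifti(nii, bold_path)
  mask_paths <- purrr::imap_chr(
    split(run$voxels, run$voxels$compartment),
    function(df, comp) {
      lab <- array(0L, c(V, 1, 1))
      lab[df$voxel] <- as.integer(factor(df$roi))
      p <- file.path(dir, sprintf("%s_mask_%s.nii.gz", prefix, comp))
      RNifti::writeNifti(RNifti::asNifti(lab), p)
      p
    })
  invisible(c(bold = bold_path, mask_paths))
}

#' Read a behavioral table with an explicit column mapping
#'
#' @param path TSV or CSV file.
#' @param mapping Named character vector mapping required schema names
#'   (`participant_id`, `interval_id`, `estimate_s`, optionally
#'   `confidence`, `true_gap_s`, `clip_id`) to the file's column names;
#'   identity by default.
#' @param estimate_unit `"s"` or `"min"`; minutes are converted to seconds.
#' @param n_expected Optional declared row count; a mismatch (silent
#'   truncation) is an error.
#' @return Tibble in the package schema.
#' @export
load_behavior <- function(path, mapping = NULL, estimate_unit = "s",
                          n_expected = NULL) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  mapping <- mapping %||%
    setNames(intersect(c("participant_id", "interval_id", "estimate_s",
                         "confidence", "true_gap_s", "clip_id"),
                       names(raw)),
             intersect(c("participant_id", "interval_id", "estimate_s",
                         "confidence", "true_gap_s", "clip_id"),
                       names(raw)))
  missing_cols <- setdiff(unname(mapping), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste("missing required column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  out <- raw[unname(mapping)]
  names(out) <- names(mapping)
  req <- c("participant_id", "interval_id", "estimate_s")
  miss <- setdiff(req, names(out))
  if (length(miss) > 0) {
    abort(paste("mapping lacks required column(s):",
                paste(miss, collapse = ", ")))
  }
  bad <- which(is.na(suppressWarnings(as.numeric(out$estimate_s))) &
                 !is.na(out$estimate_s))
  if (length(bad) > 0) {
    abort(sprintf("unparseable estimate at row %s",
                  paste(bad, collapse = ", ")))
  }
  out$estimate_s <- as.numeric(out$estimate_s)
  if (estimate_unit == "min") out$estimate_s <- out$estimate_s * 60
  if (!is.null(n_expected) && nrow(out) != n_expected) {
    abort(sprintf("expected %d rows, found %d (truncated file?)",
                  n_expected, nrow(out)))
  }
  as_tibble(out)
}

#' Write behavioral tables and the clip schedule as TSV
#'
#' @param reports Reports tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_behavior <- function(reports, path) {
  readr::write_tsv(reports, path)
  invisible(path)
}

#' @rdname write_behavior
#' @param schedule A `clip_schedule`.
#' @param clips_path,intervals_path Output files.
#' @export
write_schedule <- function(schedule, clips_path, intervals_path) {
  readr::write_tsv(schedule$clips, clips_path)
  readr::write_tsv(schedule$intervals, intervals_path)
  invisible(c(clips_path, intervals_path))
}

#' Read a schedule written by [write_schedule()]
#'
#' @param clips_path,intervals_path TSV files.
#' @param tr_seconds,n_trs Run geometry to attach.
#' @return A `clip_schedule`.
#' @export
read_schedule <- function(clips_path, intervals_path, tr_seconds = 1.5,
                          n_trs = NULL) {
  clips <- readr::read_tsv(clips_path, show_col_types = FALSE)
  ints <- readr::read_tsv(intervals_path, show_col_types = FALSE)
  n_trs <- n_trs %||%
    as.integer(ceiling(max(clips$onset_s + clips$duration_s) / tr_seconds))
  structure(list(clips = clips, intervals = ints, tr_seconds = tr_seconds,
                 n_trs = n_trs), class = "clip_schedule")
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes the selected stages in dependency order (synthesize ->
#' preprocess -> drift statistics -> behavior -> timescale), writes the
#' result tables to `out_dir` and a machine-readable manifest recording the
#' seed, configuration, package version and every stage's outputs. A stage
#' failure marks the bundle partial and skips downstream stages that depend
#' on it.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("preprocess", "drift", "behavior", "timescale")`.
#' @param cutoff_s High-pass cutoff (s); `"auto"` runs [select_cutoff()].
#' @param n_surrogates Surrogates per participant/region.
#' @param rois Regions for the drift analysis; default grey-matter regions.
#' @return List with the stage results and the manifest (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("preprocess", "drift", "behavior",
                                    "timescale"),
                         cutoff_s = 480, n_surrogates = 1000,
                         rois = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("contextdrift")),
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), "roi_specs")],
    stages = list(), outputs = character(), partial = FALSE
  )
  results <- list()
  ds <- synth_dataset(cfg)
  rois <- rois %||%
    cfg$roi_specs$label[cfg$roi_specs$compartment == "grey"]
  emit <- function(tbl, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p)
    manifest$outputs <<- c(manifest$outputs, basename(p))
    p
  }
  run_stage <- function(name, deps, fn) {
    failed_dep <- any(vapply(deps, function(d) {
      identical(manifest$stages[[d]], "failed") ||
        identical(manifest$stages[[d]], "skipped")
    }, logical(1)))
    if (!(name %in% stages)) {
      manifest$stages[[name]] <<- "disabled"
      return(invisible(NULL))
    }
    if (failed_dep) {
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- "failed"
      manifest$partial <<- TRUE
      inform(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      manifest$stages[[name]] <<- "ok"
      results[[name]] <<- res
    }
    invisible(res)
  }
  manifest$stages[["synth"]] <- "ok"
  emit(ds$reports, "reports")
  emit(ds$schedule$intervals, "intervals")

  run_stage("preprocess", character(), function() {
    spec <- if (identical(cutoff_s, "auto")) {
      select_cutoff(ds$runs, grey_rois = rois)
    } else {
      filter_spec(cutoff_s)
    }
    runs <- purrr::map(ds$runs, function(r) {
      nuisance_residualize(highpass_run(despike_run(r), spec))
    })
    ds$runs <<- runs
    list(cutoff_s = spec$cutoff_s)
  })
  run_stage("drift", "preprocess", function() {
    conf <- confidence_filter(interval_confidence(ds$clip_confidence,
                                                  ds$schedule))
    two_min <- ds$schedule$intervals$interval_id[
      ds$schedule$intervals$true_gap_s == 120]
    z_tbl <- purrr::map_dfr(ds$runs, function(run) {
      keep <- conf %>%
        filter(.data$participant_id == run$participant_id,
               .data$retained, .data$interval_id %in% two_min)
      rep_p <- ds$reports %>%
        filter(.data$participant_id == run$participant_id)
      purrr::map_dfr(rois, function(roi) {
        z <- tryCatch(
          surrogate_z(run, roi, ds$schedule, rep_p, keep$interval_id,
                      n = n_surrogates,
                      seed = substream_seed(cfg$seed, 77,
                                            run$participant_id,
                                            match(roi, rois)))$z,
          error = function(e) NA_real_)
        tibble(roi = roi, participant_id = run$participant_id, z = z)
      })
    })
    list(z_table = z_tbl,
         roi_test = {
           tab <- group_roi_test(z_tbl)
           emit(tab, "roi_test")
           tab
         })
  })
  run_stage("behavior", character(), function() {
    res <- list(
      gap_ttest = gap_means_ttest(ds$reports, ds$schedule),
      split_half = split_half_reliability(ds$reports, gap_s = 120,
                                          schedule = ds$schedule,
                                          n_splits = 200,
                                          seed = substream_seed(cfg$seed, 88)),
      time_order = time_order_effect(ds$reports, ds$schedule)
    )
    emit(res$gap_ttest, "gap_ttest")
    res
  })
  run_stage("timescale", "preprocess", function() {
    sm <- purrr::map(ds$runs, smooth_run)
    tab <- fwhm_table(sm, rois, method = "univariate", max_lag = 40)
    emit(tab, "fwhm")
    tab
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  results
}
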