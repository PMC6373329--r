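#' Write a TAC table to CSV
#'
#' One row per region and frame with the fixed header
#' `region,frame_start_s,frame_end_s,value_kbq_ml`.  Times are written in
#' seconds; values at full double precision so a read round-trips losslessly.
#'
#' @param x A `tac_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(x, path) {
  stopifnot(inherits(x, "tac_table"))
  df <- as.data.frame(x)
  df$value_kbq_ml <- sprintf("%.17g", df$value_kbq_ml)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TAC table from CSV
#'
#' Validates the header, numeric parsing (errors name the offending row),
#' schedule consistency across regions, and frame contiguity.  Hemispheric
#' regions follow the `"_l"`/`"_r"` suffix convention.
#'
#' @param path CSV path written by [write_tac_table()] (or matching its
#'   layout).
#' @return A `tac_table`.
#' @export
read_tac_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region = "character"))
  need <- c("region", "frame_start_s", "frame_end_s", "value_kbq_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TAC table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in need[-1L]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric %s in row %d of '%s'", col, bad[1L], path),
           call. = FALSE)
    df[[col]] <- v
  }
  regions <- unique(df$region)
  first <- df[df$region == regions[1L], , drop = FALSE]
  tryCatch(validate_schedule_frames(first$frame_start_s, first$frame_end_s),
           error = function(e)
             stop(sprintf("invalid schedule in '%s': %s", path,
                          conditionMessage(e)), call. = FALSE))
  sched <- as_frame_schedule(data.frame(start_s = first$frame_start_s,
                                        end_s = first$frame_end_s))
  for (r in regions[-1L]) {
    rows <- df[df$region == r, , drop = FALSE]
    if (nrow(rows) != nrow(sched) ||
        any(abs(rows$frame_start_s - sched$start_s) > 1e-9) ||
        any(abs(rows$frame_end_s - sched$end_s) > 1e-9)) {
      off <- which(df$region == r)[1L]
      stop(sprintf(
        "inconsistent schedule for region '%s' starting at row %d of '%s'",
        r, off, path), call. = FALSE)
    }
  }
  tac_table(lapply(regions, function(r)
    new_tac(r, sched, df$value_kbq_ml[df$region == r])))
}

#' Write a cohort to a directory
#'
#' One TAC CSV per subject (`<id>_tac.csv`), a `ground_truth.csv`, a
#' `clinical.csv` and a JSON `manifest.json` recording the generation config,
#' seed and schedule spec.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (s in cohort$subjects) {
    write_tac_table(s$tacs, file.path(dir, paste0(s$id, "_tac.csv")))
    tr <- s$truth
    tr$subject <- s$id
    truth[[length(truth) + 1L]] <- tr
  }
  truth <- do.call(rbind, truth)
  num <- vapply(truth, is.numeric, logical(1))
  truth[num] <- lapply(truth[num], function(v) sprintf("%.17g", v))
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `pet_cohort` (ground truth and clinical restored).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(cohort_config, manifest[names(formals(cohort_config))[
    names(formals(cohort_config)) %in% names(manifest)]])
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                           stringsAsFactors = FALSE)
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  ids <- unique(truth$subject)
  subjects <- lapply(ids, function(id) {
    tt <- read_tac_table(file.path(dir, paste0(id, "_tac.csv")))
    tr <- truth[truth$subject == id, setdiff(names(truth), "subject"),
                drop = FALSE]
    rownames(tr) <- NULL
    list(id = id, k2p = tr$k2p[1L], tacs = tt, truth = tr)
  })
  structure(list(schedule = build_schedule(cfg$schedule_spec),
                 config = cfg, clinical = clinical, subjects = subjects),
            class = "pet_cohort")
}

#' Extract region TACs from a 4D image and a label map
#'
#' Label-map averaging: for every labelled region the mean voxel value per
#' frame.  This is the direct route from dynamic image data into the
#' package's TAC representation; registration and atlas handling are up to
#' the caller.
#'
#' @param image A 4D array or a NIfTI file path ([RNifti::readNifti()] is
#'   used for paths); the 4th dimension must match the schedule's frame
#'   count.
#' @param labels A 3D integer array or NIfTI path of the same spatial grid.
#' @param schedule A `frame_schedule` (or spec string).
#' @param legend Optional named integer vector mapping region names to label
#'   values (e.g. `c(occipital = 1, thalamus_l = 2)`); default all non-zero
#'   labels as `region_<value>`.
#' @return A `tac_table`.
#' @export
extract_tacs_from_image <- function(image, labels, schedule, legend = NULL) {
  if (is.character(image)) image <- RNifti::readNifti(image)
  if (is.character(labels)) labels <- RNifti::readNifti(labels)
  image <- unclass(image); labels <- unclass(labels)
  di <- dim(image); dl <- dim(labels)
  if (length(di) != 4L)
    stop("image must be 4D (x, y, z, frame)", call. = FALSE)
  if (length(dl) != 3L || any(di[1:3] != dl))
    stop("label map grid does not match the image grid", call. = FALSE)
  schedule <- as_frame_schedule(schedule)
  if (di[4L] != nrow(schedule))
    stop(sprintf("image has %d frames but schedule has %d",
                 di[4L], nrow(schedule)), call. = FALSE)
  if (is.null(legend)) {
    vals <- sort(unique(as.integer(labels)))
    vals <- vals[vals != 0L]
    legend <- stats::setNames(vals, sprintf("region_%d", vals))
  }
  frames <- matrix(image, ncol = di[4L])
  lab <- as.integer(labels)
  tacs <- lapply(names(legend), function(nm) {
    vox <- which(lab == legend[[nm]])
    if (!length(vox))
      stop(sprintf("label '%s' (value %d) has no voxels", nm, legend[[nm]]),
           call. = FALSE)
    new_tac(nm, schedule, colMeans(frames[vox, , drop = FALSE]))
  })
  tac_table(tacs)
}
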