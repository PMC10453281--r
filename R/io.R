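# Case-level disk I/O. NIfTI is the canonical format; each case directory
# holds label_map.nii.gz, t2w.nii.gz, optional dwi.nii.gz (4D) and
# dce.nii.gz (4D), and a sidecar JSON with b-values, dynamic times, the AIF
# samples and (for phantoms) the ground truth.

#' Write a case to a directory
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wn <- function(img, name)
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = c(case$spacing, 1)),
                       file.path(dir, paste0(name, ".nii.gz")))
  wn(case$label_map + 0L, "label_map")
  wn(case$t2w, "t2w")
  meta <- list(patient_id = case$patient_id %||% NA,
               spacing = case$spacing)
  if (!is.null(case$dwi)) {
    wn(case$dwi$signal, "dwi")
    meta$b_values <- case$dwi$b_values
  }
  if (!is.null(case$dce)) {
    wn(case$dce$signal, "dce")
    meta$dce_times_s <- case$dce$times_s
    meta$n_baseline <- case$dce$n_baseline
    meta$aif <- list(times = case$dce$aif$times,
                     concentrations = case$dce$aif$concentrations,
                     source = case$dce$aif$source)
    meta$conversion_scale <- case$config$conversion_scale %||% 1
  }
  if (!is.null(case$truth)) meta$truth <- case$truth
  jsonlite::write_json(meta, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a case from a directory
#'
#' Loads the volumes written by [write_case()] (or an equivalently laid-out
#' real case), validates that all volumes share the grid, and attaches
#' b-values / dynamic times / AIF from the sidecar JSON. A missing DWI or
#' DCE file yields a case with that modality absent; an unknown label code
#' is an error.
#'
#' @param dir Case directory.
#' @return A `phantom_case`-shaped list.
#' @export
read_case <- function(dir) {
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) return(NULL)
    img <- RNifti::readNifti(f)
    array(as.numeric(img), dim(img))
  }
  meta <- jsonlite::read_json(file.path(dir, "case.json"),
                              simplifyVector = TRUE)
  lab <- rd("label_map")
  t2w <- rd("t2w")
  if (is.null(lab) || is.null(t2w)) stop("case in ", dir,
                                         " lacks label_map or t2w")
  lab <- array(as.integer(round(lab)), dim(lab))
  bad <- setdiff(unique(as.vector(lab)), 0:3)
  if (length(bad))
    stop("label map contains unknown code(s): ", paste(bad, collapse = ", "))
  dm <- dim(lab)
  check_grid <- function(x, name) {
    if (!is.null(x) && !identical(dim(x)[1:3], dm))
      stop("grid mismatch for volume: ", name)
  }
  check_grid(t2w, "t2w")
  dwi <- rd("dwi"); check_grid(dwi, "dwi")
  dce <- rd("dce"); check_grid(dce, "dce")
  spacing <- as.numeric(meta$spacing)
  case <- list(label_map = lab, t2w = t2w,
               dwi = if (!is.null(dwi))
                 list(b_values = as.numeric(meta$b_values), signal = dwi),
               dce = if (!is.null(dce))
                 list(times_s = as.numeric(meta$dce_times_s), signal = dce,
                      aif = aif_curve(meta$aif$times, meta$aif$concentrations,
                                      meta$aif$source),
                      n_baseline = as.integer(meta$n_baseline %||% 1L)),
               spacing = spacing,
               truth = meta$truth,
               clinical = NULL,
               patient_id = if (is.null(meta$patient_id) ||
                                is.na(meta$patient_id)) NULL
                            else meta$patient_id,
               config = list(conversion_scale = meta$conversion_scale %||% 1))
  class(case) <- "phantom_case"
  case
}

#' Write a cohort (cases + clinical CSV) to a directory
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory; one subdirectory per patient plus
#'   `clinical.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort$cases)
    write_case(case, file.path(dir, case$patient_id))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir Directory written by [write_cohort()]. Per-case failures are
#'   isolated: a failing case is skipped with a warning and the cohort run
#'   continues.
#' @return A `phantom_cohort`-shaped list.
#' @export
read_cohort <- function(dir) {
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"))
  cases <- list()
  for (pid in clinical$patient_id) {
    case <- tryCatch(read_case(file.path(dir, pid)),
                     error = function(e) {
                       warning("skipping case ", pid, ": ",
                               conditionMessage(e))
                       NULL
                     })
    if (!is.null(case)) {
      case$patient_id <- pid
      cases[[pid]] <- case
    }
  }
  clinical <- clinical[clinical$patient_id %in% names(cases), ]
  structure(list(cases = unname(cases), clinical = clinical, config = NULL),
            class = "phantom_cohort")
}
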