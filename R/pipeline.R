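#' Batch feature extraction over a set of masks
#'
#' Reads every mask, resamples anisotropic inputs to isotropic voxels,
#' extracts fractal and shape features, and (optionally) writes the feature
#' table. Per-subject failures are logged and reported while the run
#' continues, since cohort analyses tolerate missing subjects; the status
#' is \code{"ok"} when all masks succeed, \code{"partial"} when some fail,
#' and an error is raised only when no mask is readable.
#'
#' @param masks character vector of NIfTI paths, a directory containing
#'   \code{.nii}/\code{.nii.gz} files, or a list of \code{voxel_mask}
#'   objects.
#' @param out optional output CSV path for the feature table.
#' @param config a \code{\link{feature_config}}.
#' @param threshold binarisation threshold passed to \code{\link{read_mask}}.
#' @return A list with \code{table} (feature data frame), \code{failures}
#'   (data frame of subject/message), \code{status}.
#' @export
run_features <- function(masks, out = NULL, config = feature_config(),
                         threshold = 0) {
  if (is.character(masks) && length(masks) == 1L && dir.exists(masks))
    masks <- sort(list.files(masks, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(masks)) stop("no masks to process", call. = FALSE)
  feats <- list()
  failures <- data.frame(subject = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    id <- if (inherits(m, "voxel_mask")) m$subject_id else
      sub("\\.nii(\\.gz)?$", "", basename(m))
    res <- tryCatch({
      vm <- if (inherits(m, "voxel_mask")) m else read_mask(m, threshold = threshold)
      if (!is_isotropic(vm)) vm <- resample_isotropic(vm)
      extract_features(vm, config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(subject = id,
                                             message = conditionMessage(res),
                                             stringsAsFactors = FALSE))
    } else {
      feats[[length(feats) + 1L]] <- res
    }
  }
  if (!length(feats))
    stop("no mask could be processed; first failure: ", failures$message[1],
         call. = FALSE)
  tab <- features_as_table(feats)
  if (!is.null(out)) write_feature_table(tab, out)
  list(table = tab, failures = failures,
       status = if (nrow(failures)) "partial" else "ok")
}

#' End-to-end cohort analysis
#'
#' Runs the full statistical pipeline on a cohort table in the published
#' order: per-variable two-group comparisons (normality-routed continuous
#' tests, expected-count-routed categorical tests), a univariable logistic
#' screen, multivariable modelling with backward likelihood-ratio
#' elimination and VIF reporting, and ROC analysis of the final model's
#' fitted probabilities. Every threshold and seed used is echoed in the
#' report for auditability.
#'
#' @param cohort a cohort data frame (see \code{\link{generate_cohort}}) or
#'   a CSV path.
#' @param outcome binary outcome column name.
#' @param continuous_vars,binary_vars variables to compare and screen;
#'   defaults cover the standard cohort schema columns present in the data.
#' @param p_enter,p_stay selection thresholds (see
#'   \code{\link{backward_eliminate}}).
#' @param n_boot bootstrap replicates for the ROC CI.
#' @param seed integer seed for the bootstrap.
#' @param out optional output directory; when given, comparison and model
#'   tables are written as CSV and the report as JSON, and the ROC curve as
#'   SVG.
#' @return A list of class \code{vf_report}: \code{comparisons} (data
#'   frame), \code{selection} (a \code{vf_selection}), \code{roc} (a
#'   \code{vf_roc}, or NULL for an empty final model), \code{config}.
#' @export
run_analysis <- function(cohort, outcome = "mutant",
                         continuous_vars = NULL, binary_vars = NULL,
                         p_enter = 0.05, p_stay = 0.05,
                         n_boot = 2000, seed = 1, out = NULL) {
  if (is.character(cohort)) cohort <- read_feature_table(cohort)
  y <- binary_outcome(cohort, outcome)
  default_cont <- c("age", "mitosis_count", "ki67", "max_diameter_cm",
                    "fd", "lacunarity", "sphericity", "volume_mm3")
  default_bin <- c("female", "recurrent", "skull_base",
                   "heterogeneous_enhancement", "capsular_enhancement",
                   "necrosis", "cystic_change", "hyperostosis", "skull_invasion")
  if (is.null(continuous_vars))
    continuous_vars <- intersect(default_cont, names(cohort))
  if (is.null(binary_vars))
    binary_vars <- intersect(default_bin, names(cohort))
  comparisons <- list()
  for (v in continuous_vars) {
    res <- tryCatch(
      compare_continuous(cohort[[v]][y == 0], cohort[[v]][y == 1], variable = v),
      error = function(e) e)
    comparisons[[v]] <- comparison_row(v, "continuous", res)
  }
  for (v in binary_vars) {
    tab <- table(factor(cohort[[v]], levels = 0:1), factor(y, levels = 0:1))
    res <- tryCatch(compare_categorical(as.matrix(tab), variable = v),
                    error = function(e) e)
    comparisons[[v]] <- comparison_row(v, "binary", res)
  }
  comparisons <- do.call(rbind, comparisons)
  selection <- backward_eliminate(cohort, outcome,
                                  candidate_terms = c(continuous_vars, binary_vars),
                                  p_enter = p_enter, p_stay = p_stay)
  roc <- NULL
  if (!is.null(selection$final)) {
    scores <- predict(selection$final$fit, type = "response")
    roc <- roc_analysis(scores, y, n_boot = n_boot, seed = seed)
  }
  config <- list(outcome = outcome, continuous_vars = continuous_vars,
                 binary_vars = binary_vars, p_enter = p_enter,
                 p_stay = p_stay, n_boot = n_boot, seed = seed,
                 alpha_normality = 0.05)
  report <- structure(list(comparisons = comparisons, selection = selection,
                           roc = roc, config = config),
                      class = "vf_report")
  if (!is.null(out)) write_report(report, out)
  report
}

comparison_row <- function(v, type, res) {
  if (inherits(res, "error")) {
    data.frame(variable = v, type = type, test_used = NA_character_,
               statistic = NA_real_, p_value = NA_real_,
               note = conditionMessage(res), stringsAsFactors = FALSE)
  } else {
    data.frame(variable = v, type = type, test_used = res$test_used,
               statistic = res$statistic, p_value = res$p_value,
               note = "", stringsAsFactors = FALSE)
  }
}

write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$comparisons, file.path(out, "comparisons.csv"),
            row.names = FALSE)
  write.csv(report$selection$univariable, file.path(out, "univariable.csv"),
            row.names = FALSE)
  if (!is.null(report$selection$final))
    write.csv(report$selection$final$table,
              file.path(out, "multivariable.csv"), row.names = FALSE)
  js <- list(config = report$config,
             candidates = report$selection$candidates,
             vif = as.list(report$selection$vif),
             elimination_trace = report$selection$elimination_trace,
             final_terms = report$selection$final_terms)
  if (!is.null(report$roc)) {
    js$roc <- report$roc[c("auc", "auc_ci", "threshold", "sensitivity",
                           "specificity", "accuracy", "n_boot", "seed")]
    grDevices::svg(file.path(out, "roc.svg"), width = 5, height = 5)
    plot(report$roc)
    grDevices::dev.off()
  }
  jsonlite::write_json(js, file.path(out, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.vf_report <- function(x, ...) {
  cat("<analysis report>\n-- group comparisons --\n")
  print(x$comparisons, digits = 4)
  cat("-- model selection --\n")
  print(x$selection)
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}

#' Generate synthetic fixtures from a YAML specification
#'
#' Drives the synthetic-data generators from a declarative spec and writes
#' the outputs with a manifest (parameters, seeds and MD5 checksums), so a
#' simulated dataset can be regenerated and verified byte-for-byte.
#'
#' The YAML schema has two optional top-level keys:
#' \describe{
#'   \item{\code{phantoms}}{list of entries with \code{kind} (one of
#'     \code{cube}, \code{slab}, \code{line}, \code{ball}, \code{menger},
#'     \code{blob}) plus that generator's arguments and an optional
#'     \code{name}.}
#'   \item{\code{cohort}}{arguments for \code{\link{cohort_spec}}
#'     (\code{n_total}, \code{n_mutant}, \code{seed},
#'     \code{fd_lac_correlation}).}
#' }
#'
#' @param spec YAML path, or an equivalent nested list.
#' @param out output directory.
#' @return A list with \code{files} (written paths) and \code{manifest}
#'   (also written to \code{manifest.json}).
#' @export
run_simulate <- function(spec, out) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  if (!is.list(spec)) stop("`spec` must be a YAML path or a list", call. = FALSE)
  unknown <- setdiff(names(spec), c("phantoms", "cohort"))
  if (length(unknown))
    stop("unknown spec fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  entries <- list()
  for (ph in spec$phantoms) {
    if (is.null(ph$kind))
      stop("phantom entry missing `kind` field", call. = FALSE)
    mask <- switch(as.character(ph$kind),
      cube = , slab = , line = , ball =
        make_primitive(ph$kind, size = ph$size,
                       spacing = ph$spacing %||% 1),
      menger = make_menger_sponge(ph$level, spacing = ph$spacing %||% 1),
      blob = make_blob(radius_mm = ph$radius_mm,
                       irregularity = ph$irregularity %||% 0,
                       gap_fraction = ph$gap_fraction %||% 0,
                       gap_size_vox = ph$gap_size_vox %||% 3,
                       seed = ph$seed %||% 1,
                       spacing = ph$spacing %||% 1),
      stop(sprintf("phantoms[]: unknown kind '%s'", ph$kind), call. = FALSE))
    name <- ph$name %||% mask$subject_id
    path <- file.path(out, paste0(name, ".nii.gz"))
    write_mask(mask, path)
    files <- c(files, path)
    entries[[length(entries) + 1L]] <-
      list(type = "phantom", name = name, params = ph,
           n_foreground = n_foreground(mask),
           file = basename(path), md5 = unname(tools::md5sum(path)))
  }
  if (!is.null(spec$cohort)) {
    cs <- do.call(cohort_spec, spec$cohort)
    cohort <- generate_cohort(cs)
    path <- file.path(out, "cohort.csv")
    write.csv(cohort, path, row.names = FALSE)
    files <- c(files, path)
    entries[[length(entries) + 1L]] <-
      list(type = "cohort", params = spec$cohort, n = nrow(cohort),
           n_mutant = sum(cohort$mutant), file = basename(path),
           md5 = unname(tools::md5sum(path)))
  }
  manifest <- list(created = format(Sys.time(), tz = "UTC"), entries = entries)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = files, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
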