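# End-to-end orchestration: simulate -> extract image features -> fit,
# cross-validate, refine and validate the age models -> disease association.
# Every artifact is a plain CSV/JSON/PNG file and every stage is seeded, so
# a rerun under the same configuration reproduces byte-identical outputs.

#' Cohort-table CSV schema
#'
#' Column names, in order, of the cohort/feature CSV artifact.
#' @return character vector.
#' @export
cohort_schema <- function() {
  c("id", "age", "Wb", "Wu", "Wa", "Pb", "Pu", "Md", "Mw",
    paste0("D", 1:7), "sun_hours", "sunscreen_freq", "smoker")
}

#' Write a cohort table to CSV
#'
#' Writes the documented schema columns (the derived any-disease flag D0 is
#' not stored; it is recomputed on read).
#'
#' @param cohort cohort data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing <- setdiff(cohort_schema(), names(cohort))
  if (length(missing)) {
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(cohort[cohort_schema()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort table from CSV
#'
#' Enforces the [cohort_schema()] strictly: unknown or missing columns,
#' out-of-range feature scores (outside 0-100), non-binary disease flags and
#' non-positive ages are rejected with the offending column and data row
#' named. The any-disease flag `D0` is derived on read.
#'
#' @param path CSV file written by [write_cohort_csv()].
#' @return validated cohort data.frame including `D0`.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- cohort_schema()
  unknown <- setdiff(names(tab), schema)
  if (length(unknown)) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(schema, names(tab))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  feats <- feature_names()
  for (f in feats) {
    bad <- which(!is.finite(tab[[f]]) | tab[[f]] < 0 | tab[[f]] > 100)
    if (length(bad)) {
      stop("column ", f, " out of range [0, 100] at data row ", bad[1])
    }
  }
  for (dcol in paste0("D", 1:7)) {
    bad <- which(!tab[[dcol]] %in% c(0L, 1L))
    if (length(bad)) {
      stop("column ", dcol, " is not a 0/1 flag at data row ", bad[1])
    }
  }
  bad <- which(!is.finite(tab$age) | tab$age <= 0)
  if (length(bad)) stop("column age invalid at data row ", bad[1])
  tab$D0 <- as.integer(rowSums(tab[paste0("D", 1:7)]) > 0)
  tab
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters: the build and validation cohort designs,
#' the synthetic-image demonstration set, ridge/FFT parameters, and the
#' cross-validation setup. Serializes losslessly to JSON via
#' [write_run_config()] so a run can be reproduced from its config file
#' alone.
#'
#' @param stages character subset of
#'   `c("simulate", "extract", "fit", "associate")`.
#' @param n_per_decade_build,n_per_decade_validation per-decade cohort sizes.
#' @param n_images number of synthetic demonstration images.
#' @param image_canvas canvas size of those images.
#' @param ridge a [ridge_params()].
#' @param band an [fft_band()].
#' @param cv_k,cv_seed cross-validation folds and fold seed.
#' @param models model numbers (1-9) to run.
#' @param seed master seed; per-stage seeds are derived from it via
#'   [derive_seed()]-style hashing of the stage name, so stages can be rerun
#'   in isolation.
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "extract", "fit", "associate"),
                       n_per_decade_build = 400L,
                       n_per_decade_validation = 103L,
                       n_images = 8L,
                       image_canvas = 160L,
                       ridge = ridge_params(),
                       band = fft_band(),
                       cv_k = 10L,
                       cv_seed = 1L,
                       models = 1:9,
                       seed = 1L) {
  stages <- match.arg(stages, c("simulate", "extract", "fit", "associate"),
                      several.ok = TRUE)
  if (!all(models %in% 1:9)) stop("models must be numbers 1-9")
  structure(list(
    stages = stages,
    n_per_decade_build = as.integer(n_per_decade_build),
    n_per_decade_validation = as.integer(n_per_decade_validation),
    n_images = as.integer(n_images),
    image_canvas = as.integer(image_canvas),
    ridge = ridge, band = band,
    cv_k = as.integer(cv_k), cv_seed = as.integer(cv_seed),
    models = as.integer(models), seed = as.integer(seed)
  ), class = "run_config")
}

#' Serialize / deserialize a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   the reconstructed [run_config()] (round-trips exactly).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- rapply(unclass(config), function(x) x, how = "replace")
  obj$ridge <- unclass(config$ridge)
  obj$band <- unclass(config$band)
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    stages = obj$stages,
    n_per_decade_build = obj$n_per_decade_build,
    n_per_decade_validation = obj$n_per_decade_validation,
    n_images = obj$n_images,
    image_canvas = obj$image_canvas,
    ridge = ridge_params(obj$ridge$scales, obj$ridge$threshold, obj$ridge$beta),
    band = fft_band(obj$band$wavelengths, obj$band$percentile),
    cv_k = obj$cv_k, cv_seed = obj$cv_seed,
    models = obj$models, seed = obj$seed
  )
}

#' @keywords internal
#' @noRd
write_model_json <- function(model, path) {
  obj <- list(
    subset = model$subset,
    coefficients = as.list(stats::setNames(
      sprintf("%.17g", model$coefficients), names(model$coefficients))),
    sigma = sprintf("%.17g", model$sigma),
    refined = model$refined,
    removed = model$removed,
    training_id = model$training_id,
    n = model$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order under an output directory:
#' \describe{
#'   \item{simulate}{build (400/decade) and validation (103/decade) cohort
#'     CSVs, plus a small set of synthetic periorbital images with landmarks
#'     and ground-truth masks.}
#'   \item{extract}{runs the wrinkle pipeline (crop, grayscale, Hessian
#'     ridge, FFT enhancement, scoring) and the spot detector over the
#'     simulated images; writes an image-feature CSV.}
#'   \item{fit}{fits the requested models on the build cohort, 10-fold
#'     cross-validates them, refits final equations on the full build set,
#'     refines any with negative coefficients, and validates on the
#'     independent cohort; writes model JSONs and a performance report.}
#'   \item{associate}{computes the model-7 periorbital skin age on the
#'     validation cohort and writes the disease association table, the
#'     disease PCA loadings and the PC1 correlation.}
#' }
#' A manifest (JSON) records the config, derived stage seeds, and an MD5
#' checksum for every artifact; rerunning with the same config reproduces
#' all checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  seeds <- list()
  emit <- function(path) artifacts <<- c(artifacts, path)
  stage <- "none"
  run_stage <- function(name, body) {
    stage <<- name
    tryCatch(body(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cfg_path <- file.path(out_dir, "run_config.json")
  write_run_config(config, cfg_path)
  emit(cfg_path)

  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    seeds$simulate <<- derive_seed(config$seed, "simulate")
    build <- generate_cohort(cohort_config(
      n_per_decade = config$n_per_decade_build, seed = seeds$simulate))
    val <- generate_cohort(cohort_config(
      n_per_decade = config$n_per_decade_validation,
      seed = derive_seed(config$seed, "simulate-validation")), id_prefix = "V")
    emit(write_cohort_csv(build, file.path(out_dir, "cohort_build.csv")))
    emit(write_cohort_csv(val, file.path(out_dir, "cohort_validation.csv")))
    img_dir <- file.path(out_dir, "images")
    for (i in seq_len(config$n_images)) {
      spec <- face_image_spec(
        canvas = config$image_canvas,
        n_wrinkles = 1L + (i %% 5L),
        n_spots = 1L + (i %% 6L),
        seed = derive_seed(config$seed, paste0("image-", i)))
      for (p in save_periorbital_image(generate_periorbital_image(spec),
                                       img_dir, sprintf("img_%02d", i))) emit(p)
    }
  })

  if ("extract" %in% config$stages) run_stage("extract", function() {
    rows <- lapply(seq_len(config$n_images), function(i) {
      spec <- face_image_spec(
        canvas = config$image_canvas,
        n_wrinkles = 1L + (i %% 5L),
        n_spots = 1L + (i %% 6L),
        seed = derive_seed(config$seed, paste0("image-", i)))
      im <- generate_periorbital_image(spec)
      wp <- crop_periorbital_roi(im$image, im$landmarks, spec$wrinkle_region,
                                 margin = 2)
      resp <- hessian_ridge_response(to_grayscale(wp), config$ridge)
      enh <- fft_enhance(resp, config$band)
      sp <- crop_periorbital_roi(im$image, im$landmarks, spec$spot_region,
                                 margin = 2)
      data.frame(image = sprintf("img_%02d", i),
                 n_wrinkles_true = spec$n_wrinkles,
                 n_spots_true = spec$n_spots,
                 wrinkle_raw = wrinkle_raw_fraction(enh, config$ridge$threshold),
                 spot_raw = mean(detect_spots(sp)))
    })
    feats <- do.call(rbind, rows)
    path <- file.path(out_dir, "image_features.csv")
    utils::write.csv(feats, path, row.names = FALSE, quote = FALSE)
    emit(path)
  })

  fit_ctx <- NULL
  if ("fit" %in% config$stages || "associate" %in% config$stages) {
    build <- generate_cohort(cohort_config(
      n_per_decade = config$n_per_decade_build,
      seed = derive_seed(config$seed, "simulate")))
    val <- generate_cohort(cohort_config(
      n_per_decade = config$n_per_decade_validation,
      seed = derive_seed(config$seed, "simulate-validation")), id_prefix = "V")
    fit_ctx <- list(build = build, val = val)
  }

  final_models <- list()
  if ("fit" %in% config$stages) run_stage("fit", function() {
    catalog <- model_catalog()
    model_dir <- file.path(out_dir, "models")
    dir.create(model_dir, showWarnings = FALSE)
    report <- lapply(config$models, function(m) {
      subset <- catalog[[m]]
      cv <- cross_validate(fit_ctx$build, subset, k = config$cv_k,
                           seed = config$cv_seed)
      final <- fit_age_model(fit_ctx$build, subset, training_id = "build cohort")
      refined <- refine_model(final, fit_ctx$build)
      final_models[[paste0("m", m)]] <<- refined
      emit(write_model_json(final, file.path(model_dir,
                                             sprintf("model_%d.json", m))))
      if (length(refined$removed)) {
        emit(write_model_json(refined, file.path(
          model_dir, sprintf("model_%d_refined.json", m))))
      }
      data.frame(model = m,
                 features = paste(subset, collapse = "+"),
                 cv_mean_r = cv$mean_r,
                 validation_r = validate_model(refined, fit_ctx$val),
                 n_removed = length(refined$removed))
    })
    path <- file.path(out_dir, "model_performance.csv")
    utils::write.csv(do.call(rbind, report), path, row.names = FALSE,
                     quote = FALSE)
    emit(path)
  })

  if ("associate" %in% config$stages) run_stage("associate", function() {
    m7 <- final_models$m7
    if (is.null(m7)) {
      m7 <- refine_model(
        fit_age_model(fit_ctx$build, model_catalog()$m7,
                      training_id = "build cohort"), fit_ctx$build)
    }
    skin_age <- suppressWarnings(predict(m7, fit_ctx$val))
    assoc <- association_table(fit_ctx$val, skin_age)
    path <- file.path(out_dir, "association_table.csv")
    utils::write.csv(assoc, path, row.names = FALSE, quote = FALSE)
    emit(path)
    pca <- disease_pca(fit_ctx$val[paste0("D", 1:7)])
    lpath <- file.path(out_dir, "pca_loadings.csv")
    utils::write.csv(data.frame(disease = rownames(pca$loadings),
                                pc1 = pca$loadings[, 1]),
                     lpath, row.names = FALSE, quote = FALSE)
    emit(lpath)
    pc1 <- pc1_correlation(pca, skin_age)
    cpath <- file.path(out_dir, "pc1_correlation.json")
    jsonlite::write_json(pc1, cpath, auto_unbox = TRUE, digits = NA)
    emit(cpath)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("periskin")),
    seed = config$seed,
    stages = config$stages,
    config_md5 = unname(tools::md5sum(cfg_path)),
    timestamp = format(Sys.time(), tz = "UTC"),
    artifacts = lapply(stats::setNames(artifacts, sub(paste0("^", out_dir, "/?"),
                                                      "", artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
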