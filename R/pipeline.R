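#' Default pipeline configuration
#'
#' Settings for the end-to-end analysis: either a path to an input particle
#' CSV (`input`) or generator settings (`generate_n` particles from the
#' reference configuration), screening thresholds, the enumeration range,
#' BLRT replicates, random starts, a master seed and an output directory.
#' Stage seeds are derived from the master seed by fixed offsets, so a rerun
#' with the same configuration reproduces all numeric outputs.
#'
#' The bundled demo settings (`demo = TRUE`) are scaled to finish on one CPU
#' within minutes: 3000 particles, `K_max = 3`, `blrt_B = 20`, 6 starts.
#'
#' @param output_dir where stage outputs and the manifest are written.
#' @param input optional particle CSV path; when `NULL`, data are generated.
#' @param generate_n particles to generate when `input` is `NULL`.
#' @param K_max,blrt_B,n_starts enumeration settings per category.
#' @param zscore_threshold,maha_threshold screening cutoffs.
#' @param seed master seed.
#' @param demo use the scaled-down demo settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, input = NULL, generate_n = 6942,
                            K_max = 5, blrt_B = 100, n_starts = 20,
                            zscore_threshold = 3, maha_threshold = 13.82,
                            seed = 1, demo = FALSE) {
  if (demo) { generate_n <- 3000; K_max <- 3; blrt_B <- 20; n_starts <- 6 }
  structure(list(output_dir = output_dir, input = input,
                 generate_n = generate_n, K_max = K_max, blrt_B = blrt_B,
                 n_starts = n_starts, zscore_threshold = zscore_threshold,
                 maha_threshold = maha_threshold, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or generate a particle table, (2) outlier screening per
#' shape category, (3) class enumeration per category (univariate for lines,
#' bivariate equal-covariance for films and fragments), (4) the combined
#' six-class model with haul-clustered sandwich SEs, (5) auxiliary analyses
#' (three-step polymer tests, height correlations within the large-fragment
#' class). Every stage writes CSV outputs to the configured directory plus a
#' JSON manifest recording seeds, versions, stage runtimes and outputs. A
#' stage failure halts with the stage name after writing a partial manifest.
#'
#' @param config a [pipeline_config()] or the path to a JSON file with the
#'   same fields.
#' @return The manifest (invisibly a list), with fitted objects attached in
#'   `attr(, "objects")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, cfg[intersect(names(cfg),
                                                     names(formals(pipeline_config)))])
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(generate = config$seed + 101L, enumerate = config$seed + 202L,
                joint = config$seed + 303L)
  manifest <- list(package_version = as.character(utils::packageVersion("floatmix")),
                   r_version = R.version.string,
                   config = unclass(config), stage_seeds = seeds,
                   stages = list())
  objects <- list()
  out <- function(name) file.path(config$output_dir, name)
  write_manifest <- function() jsonlite::write_json(
    manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  table <- stage("data", {
    if (!is.null(config$input)) read_particles(config$input)
    else generate_particles(reference_config(), config$generate_n,
                            seed = seeds$generate)
  })
  write_particles(table, out("particles.csv"))

  scr <- stage("screen", screen_particles(table, config$zscore_threshold,
                                          config$maha_threshold))
  write_particles(scr$removed, out("screen_removed.csv"))
  utils::write.csv(scr$rules, out("screen_rules.csv"), row.names = FALSE)
  kept <- scr$kept

  enum_seeds <- derive_seeds(seeds$enumerate, 3L)
  reports <- stage("enumerate", {
    lapply(stats::setNames(seq_along(CATEGORIES), CATEGORIES), function(ci) {
      cat <- CATEGORIES[ci]
      x <- if (cat == "line") kept$length_mm[kept$category == "line"]
      else cbind(kept$length_mm, kept$width_mm)[kept$category == cat, ]
      rep <- enumerate_classes(x, K_max = config$K_max,
                               covariance = "equal",
                               n_starts = config$n_starts,
                               blrt_B = config$blrt_B,
                               seed = enum_seeds[[ci]])
      sel <- select_classes(rep)
      utils::write.csv(as.data.frame(rep),
                       out(sprintf("enumeration_%s.csv", cat)), row.names = FALSE)
      list(report = rep, selection = sel)
    })
  })
  manifest$chosen_K <- lapply(reports, function(r) r$selection$chosen_K)

  joint <- stage("joint", {
    if (config$K_max < 2) {
      warning("K_max < 2: joint stage degrades to three single-class fits")
      NULL
    } else {
      fit_joint(kept, n_starts = config$n_starts, seed = seeds$joint)
    }
  })
  if (!is.null(joint)) {
    utils::write.csv(data.frame(
      label = vapply(joint$params, `[[`, character(1), "label"),
      weight = vapply(joint$params, `[[`, numeric(1), "weight"),
      mean_length = vapply(joint$params, function(p) p$mean[["length"]], 0),
      mean_width = vapply(joint$params, function(p)
        if (length(p$mean) == 2) p$mean[["width"]] else NA_real_, 0),
      var_length = vapply(joint$params, function(p) p$var[["length"]], 0),
      var_width = vapply(joint$params, function(p)
        if (length(p$var) == 2) p$var[["width"]] else NA_real_, 0),
      r = vapply(joint$params, `[[`, numeric(1), "r")
    ), out("joint_params.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(joint$posterior), out("joint_posterior.csv"),
                     row.names = FALSE)
    if (!is.null(joint$se))
      utils::write.csv(joint$se, out("joint_se.csv"), row.names = FALSE)
    manifest$joint <- list(loglik = joint$loglik, AIC = joint$AIC,
                           BIC = joint$BIC, entropy = joint$entropy,
                           npar = joint$npar,
                           min_avepp = min_posterior_prob(joint$posterior))
  }

  aux <- stage("auxiliary", {
    if (is.null(joint)) NULL else {
      modal <- max.col(joint$posterior, ties.method = "first")
      D <- classification_error_matrix(joint$posterior)
      res <- list()
      if ("polymer" %in% names(kept)) {
        poly <- kept$polymer
        poly[poly == "unknown"] <- NA
        res$polymer <- distal_categorical_test(modal, D, poly)
        utils::write.csv(res$polymer$tests, out("polymer_tests.csv"),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(res$polymer$proportions),
                         out("polymer_by_class.csv"), row.names = TRUE)
      }
      if ("height_mm" %in% names(kept) && any(!is.na(kept$height_mm))) {
        res$height <- tryCatch(height_correlations(kept, modal, 6L),
                               error = function(e) conditionMessage(e))
        if (is.list(res$height))
          utils::write.csv(data.frame(r_length_height = res$height$r_length_height,
                                      r_width_height = res$height$r_width_height,
                                      n = res$height$n),
                           out("height_correlations.csv"), row.names = FALSE)
      }
      res
    }
  })

  write_manifest()
  objects <- list(table = table, screening = scr, enumeration = reports,
                  joint = joint, auxiliary = aux)
  invisible(structure(manifest, objects = objects))
}
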