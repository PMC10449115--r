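## End-to-end orchestration of the simulated study with a flat INI-style
## config, deterministic seeding and a reproducibility manifest.

.configSchema <- list(
  run = c("seed", "out_dir"),
  simulate = c("n_genes", "n_mixtures", "type_variation", "replicate_noise",
               "marker_fold", "cancer_noise_frac", "normal_noise_frac"),
  stage0 = c("p_threshold", "n_top", "use_pairwise"),
  transform = c("per_gene"),
  stage1 = c("k", "scan_min", "scan_max", "reps", "frac", "max_iter",
             "rss_tol"),
  stage2 = c("min_mean_proportion"),
  map = c("components"),
  response = c("enabled"))

.parseIniValue <- function(x) {
  x <- trimws(x)
  if (tolower(x) %in% c("true", "false")) return(tolower(x) == "true")
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) n else x
}

#' Read a flat INI-style pipeline configuration
#'
#' Sections in brackets (`[stage1]`), `key = value` pairs, `#` comments.
#' Unknown sections or keys are rejected so typos fail fast.
#'
#' @param path config file path.
#' @return nested named list of sections.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  cfg <- list(); section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(.configSchema))
        stop("unknown config section [", section, "]")
      cfg[[section]] <- cfg[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key outside any section: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (!key %in% .configSchema[[section]])
        stop("unknown key '", key, "' in section [", section, "]")
      cfg[[section]][[key]] <- .parseIniValue(paste(kv[-1], collapse = "="))
    } else stop("unparseable config line: ", ln)
  }
  cfg
}

.cfgGet <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

#' Run the simulated study end-to-end
#'
#' Executes simulate, stage0 (informative genes), transform, stage1
#' (fixed `k` or a stability scan), stage2 (on the inverse-transformed
#' mixtures) and the simplex map, writing every intermediate as TSV plus a
#' JSON manifest (seed, parameters, per-stage outputs with MD5 checksums,
#' RSS and explained variance) sufficient to reproduce the run bit for bit.
#' A stage failure aborts with a stage-tagged message; outputs of the failed
#' stage are kept with a `.partial` suffix.
#'
#' @param config path to an INI-style config file (see
#'   [readPipelineConfig()]) or an equivalent nested list.
#' @param overrides named list of `section$key` overrides applied on top of
#'   the file (CLI flags map here).
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
runPipeline <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) readPipelineConfig(config) else config
  for (sec in names(overrides))
    cfg[[sec]] <- modifyList(cfg[[sec]] %||% list(), overrides[[sec]])
  for (sec in names(cfg)) {
    if (!sec %in% names(.configSchema))
      stop("unknown config section [", sec, "]")
    bad <- setdiff(names(cfg[[sec]]), .configSchema[[sec]])
    if (length(bad))
      stop("unknown key '", bad[1], "' in section [", sec, "]")
  }
  seed <- as.integer(.cfgGet(cfg, "run", "seed", 1))
  out_dir <- .cfgGet(cfg, "run", "out_dir", tempfile("pipeline_run_"))
  k_fixed <- .cfgGet(cfg, "stage1", "k", NA)
  scan_min <- .cfgGet(cfg, "stage1", "scan_min", NA)
  scan_max <- .cfgGet(cfg, "stage1", "scan_max", NA)
  if (!is.na(k_fixed) && !is.na(scan_min) &&
      (k_fixed < scan_min || k_fixed > scan_max))
    stop("config error: fixed k lies outside the scan range")
  if (is.na(k_fixed) && is.na(scan_min)) k_fixed <- 4  # modelled types
  if (is.na(k_fixed) && is.na(scan_max))
    stop("config error: scan_min given without scan_max")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package = "DeconvoMap",
                   version = as.character(utils::packageVersion("DeconvoMap")),
                   seed = seed, config = cfg, stages = list())
  written <- character()
  stage <- function(name, fn) {
    stage_files <- character()
    emit <- function(path) { stage_files <<- c(stage_files, path); path }
    res <- tryCatch(fn(emit), error = function(e) {
      for (f in stage_files)
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
    written <<- c(written, stage_files)
    manifest$stages[[name]] <<- c(
      list(status = "completed",
           outputs = as.list(unname(tools::md5sum(stage_files)))),
      res)
    invisible(res)
  }

  env <- new.env()
  stage("simulate", function(emit) {
    env$sim <- simulateMixtureStudy(
      seed = seed,
      nGenes = .cfgGet(cfg, "simulate", "n_genes", 2000),
      n = .cfgGet(cfg, "simulate", "n_mixtures", 100),
      typeVariation = .cfgGet(cfg, "simulate", "type_variation", 0.8),
      replicateNoise = .cfgGet(cfg, "simulate", "replicate_noise", 0.15))
    writeExpressionMatrix(env$sim$mixtures,
                          emit(file.path(out_dir, "mixtures.tsv")))
    writeExpressionMatrix(env$sim$truth@trueProfiles,
                          emit(file.path(out_dir, "truth_profiles.tsv")))
    write.table(t(env$sim$truth@trueProportions),
                emit(file.path(out_dir, "truth_proportions.tsv")),
                sep = "\t", quote = FALSE)
    write.table(data.frame(sample_id = colnames(env$sim$mixtures@values),
                           purity_class = env$sim$truth@purityClass),
                emit(file.path(out_dir, "classes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_mixtures = ncol(env$sim$mixtures@values))
  })

  stage("stage0", function(emit) {
    roles <- env$sim$roles
    pw <- if (isTRUE(.cfgGet(cfg, "stage0", "use_pairwise", TRUE)))
      list(list(classA = roles[["cancer"]], classB = roles[["stroma"]]),
           list(classA = roles[["normal"]], classB = roles[["stroma"]]))
    else list()
    env$genes <- selectInformativeGenes(
      env$sim$refs,
      pThreshold = .cfgGet(cfg, "stage0", "p_threshold", 1e-4),
      nTop = .cfgGet(cfg, "stage0", "n_top", 25),
      pairwise = pw)
    writeLines(env$genes@geneIds, emit(file.path(out_dir, "genes.txt")))
    write.table(env$genes@source,
                emit(file.path(out_dir, "gene_provenance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_genes = env$genes@nTotal)
  })

  stage("transform", function(emit) {
    mx <- env$sim$mixtures
    keep <- intersect(env$genes@geneIds, rownames(mx@values))
    env$tmix <- new("TransformedMatrix",
                    values = mx@values[keep, , drop = FALSE],
                    scaleA = mx@scaleA, perGene = mx@perGene)
    writeExpressionMatrix(env$tmix,
                          emit(file.path(out_dir, "transformed.tsv")))
    jsonlite::write_json(list(scale_a = mx@scaleA, n_genes = length(keep)),
                         emit(file.path(out_dir, "transform_scale.json")),
                         auto_unbox = TRUE, digits = NA)
    list(scale_a = mx@scaleA, n_genes = length(keep))
  })

  stage("stage1", function(emit) {
    extra <- list()
    if (is.na(k_fixed)) {
      stab <- estimateStability(
        env$tmix, kRange = seq(scan_min, scan_max),
        nReps = .cfgGet(cfg, "stage1", "reps", 3),
        subsampleFrac = .cfgGet(cfg, "stage1", "frac", 0.8),
        seed = .deriveSeed(seed, 11))
      write.table(stab@table, emit(file.path(out_dir, "stability.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      k <- stab@chosenK
      extra$chosen_k <- k
    } else k <- as.integer(k_fixed)
    env$fit <- runStage1(env$tmix, k,
                         maxIter = .cfgGet(cfg, "stage1", "max_iter", 2000),
                         rssTol = .cfgGet(cfg, "stage1", "rss_tol", 1e-10),
                         seed = .deriveSeed(seed, 12))
    env$assign <- assignCellTypes(env$fit, env$sim$refs, env$genes)
    writeExpressionMatrix(env$fit@M, emit(file.path(out_dir, "M.tsv")))
    write.table(t(env$fit@P), emit(file.path(out_dir, "P.tsv")),
                sep = "\t", quote = FALSE)
    write.table(env$assign@table,
                emit(file.path(out_dir, "assignment.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = env$fit@seed, iterations = env$fit@iterations,
           converged = env$fit@converged,
           rss = tail(env$fit@rssTrajectory, 1),
           explained_variance = env$fit@explainedVariance,
           explained_variance_uncentered =
             env$fit@explainedVarianceUncentered),
      emit(file.path(out_dir, "stage1_runlog.json")),
      auto_unbox = TRUE, digits = NA)
    c(list(k = k, iterations = env$fit@iterations,
           rss = tail(env$fit@rssTrajectory, 1),
           explained_variance = env$fit@explainedVariance), extra)
  })

  stage("stage2", function(emit) {
    counts <- inverseTransform(env$tmix)
    prof <- runStage2(counts, env$fit,
                      minMeanProportion = .cfgGet(cfg, "stage2",
                                                  "min_mean_proportion",
                                                  0.01))
    writeExpressionMatrix(prof@values,
                          emit(file.path(out_dir, "stage2_profiles.tsv")))
    list(n_components = ncol(prof@values))
  })

  stage("map", function(emit) {
    comp <- .cfgGet(cfg, "map", "components", "1,2,3")
    idx <- as.integer(strsplit(as.character(comp), ",")[[1]])
    map <- toSimplexCoordinates(env$fit@P, idx)
    write.table(map, emit(file.path(out_dir, "map.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_mapped = nrow(map), components = idx)
  })

  if (isTRUE(.cfgGet(cfg, "response", "enabled", FALSE)))
    stage("response", function(emit) {
      # demonstration response: logistic in the mapped trio of components
      idx <- manifest$stages$map$components
      p3 <- t(env$fit@P[idx, , drop = FALSE])
      .setSeed(.deriveSeed(seed, 13))
      y <- rbinom(nrow(p3), 1, plogis(2 * scale(p3[, 1])))
      model <- fitResponseGLM(p3, y)
      auc <- rocAUC(predictResponse(model, p3), y)
      jsonlite::write_json(
        list(coefficients = as.list(model@coefficients), auc = auc,
             separation = model@separation),
        emit(file.path(out_dir, "response.json")),
        auto_unbox = TRUE, digits = NA)
      list(auc = auc)
    })

  manifest$output_hashes <- as.list(tools::md5sum(sort(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
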