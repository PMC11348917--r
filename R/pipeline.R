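# Pipeline orchestration: stage execution with deterministic per-stage seeds,
# run manifests, and schema validation of the file interfaces.

#' Run a multi-stage analysis pipeline
#'
#' Executes the requested stages in dependency order, expanding one global
#' seed into deterministic per-stage child seeds so any stage can be rerun
#' independently. Currently wired stages: \code{simulate_clusters}
#' (parameters of \code{\link{clusterSimConfig}}), \code{specialize}
#' (parameters \code{nReps}; scores every simulated or loaded cluster
#' against the occupancy null at its cell count). Inputs are checked before
#' any stage runs.
#'
#' @param config list with \code{stages} (character vector), per-stage
#'   parameter blocks under the stage's name, \code{seed}, and \code{outDir}
#'   (NULL to skip writing).
#' @param verbose log stage progress.
#' @return Run manifest: package version, seeds, per-stage parameters,
#'   outputs and their md5 digests, and the stage results.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(is.list(config), !is.null(config$stages))
  seed <- config$seed %||% 1L
  known <- c("simulate_clusters", "specialize")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  # pre-flight: every stage's inputs must be produced upstream or on disk
  if ("specialize" %in% config$stages &&
      !("simulate_clusters" %in% config$stages)) {
    f <- config$specialize$clusters
    if (is.null(f) || !file.exists(f))
      stop("specialize needs clusters from simulate_clusters or a file")
  }
  log <- function(...) if (verbose) message("[geniculate] ", ...)
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  manifest <- list(package = as.character(utils::packageVersion("geniculate")),
                   seed = seed, stages = list(), outputs = character(0))
  clusters <- NULL
  for (stage in intersect(known, config$stages)) {
    sseed <- childSeed(seed, stage)
    log("stage ", stage, " (seed ", sseed, ")")
    if (stage == "simulate_clusters") {
      pars <- config$simulate_clusters
      pars$seed <- sseed
      cfg <- do.call(clusterSimConfig, pars)
      clusters <- list(simulateClusters(cfg))
      if (!is.null(outDir)) {
        f <- file.path(outDir, "clusters.csv")
        writeClusterTable(clusters[[1L]], f)
        manifest$outputs <- c(manifest$outputs, f)
      }
      manifest$stages[[stage]] <-
        list(seed = sseed, params = pars[setdiff(names(pars), "seed")])
    } else if (stage == "specialize") {
      pars <- config$specialize %||% list()
      if (is.null(clusters)) {
        cl <- readClusterTable(pars$clusters)
        clusters <- if (is(cl, "PresynapticCluster")) list(cl) else cl
      }
      nReps <- pars$nReps %||% 1e5
      res <- lapply(clusters, function(cl) {
        null <- occupancyNull(length(cl@typeLevels), nCells(cl),
                              nReps = nReps, seed = sseed)
        sp <- specializationZ(cl, null)
        data.frame(postsynaptic_id = cl@postsynapticId,
                   n_cells = nCells(cl),
                   observed_types = observedTypes(sp),
                   expected_types = expectedTypes(sp),
                   sd_types = sdTypes(sp), z = zScore(sp),
                   dominance = dominance(cl))
      })
      tab <- do.call(rbind, res)
      if (!is.null(outDir)) {
        f <- file.path(outDir, "specialization.csv")
        utils::write.csv(tab, f, row.names = FALSE)
        manifest$outputs <- c(manifest$outputs, f)
      }
      manifest$stages[[stage]] <-
        list(seed = sseed, params = list(nReps = nReps), result = tab)
    }
  }
  if (length(manifest$outputs))
    manifest$digests <- tools::md5sum(manifest$outputs)
  if (!is.null(outDir)) {
    mf <- file.path(outDir, "manifest.json")
    jsonlite::write_json(
      list(package = manifest$package, seed = manifest$seed,
           outputs = manifest$outputs,
           digests = as.list(manifest$digests %||% character(0))),
      mf, auto_unbox = TRUE)
  }
  manifest
}

#' Validate pipeline input files against their schemas
#'
#' Row/field-level checks of the file interfaces: cluster CSVs (columns,
#' eye values, eccentricity range), reference-distribution JSONs
#' (normalization), and TIFF stacks (dimensionality).
#'
#' @param files character vector of paths.
#' @return data.frame report: file, kind, ok, message.
#' @export
validateInputs <- function(files) {
  checkOne <- function(f) {
    if (!file.exists(f))
      return(data.frame(file = f, kind = "missing", ok = FALSE,
                        message = "file does not exist"))
    if (grepl("\\.csv$", f, ignore.case = TRUE)) {
      df <- tryCatch(utils::read.csv(f, stringsAsFactors = FALSE),
                     error = function(e) NULL)
      if (is.null(df))
        return(data.frame(file = f, kind = "csv", ok = FALSE,
                          message = "unreadable CSV"))
      need <- c("cell_id", "eye", "type_label")
      miss <- setdiff(need, names(df))
      if (length(miss))
        return(data.frame(file = f, kind = "cluster_csv", ok = FALSE,
                          message = paste("missing columns:",
                                          paste(miss, collapse = ", "))))
      badEye <- which(!(df$eye %in% c("contra", "ipsi")))
      if (length(badEye))
        return(data.frame(file = f, kind = "cluster_csv", ok = FALSE,
                          message = sprintf("row %d: invalid eye '%s'",
                                            badEye[1L], df$eye[badEye[1L]])))
      if ("eccentricity_deg" %in% names(df)) {
        bad <- which(!is.na(df$eccentricity_deg) &
                     (df$eccentricity_deg < 0 | df$eccentricity_deg > 115))
        if (length(bad))
          return(data.frame(file = f, kind = "cluster_csv", ok = FALSE,
                            message = sprintf(
                              "row %d: eccentricity outside [0, 115]",
                              bad[1L])))
      }
      return(data.frame(file = f, kind = "cluster_csv", ok = TRUE,
                        message = ""))
    }
    if (grepl("\\.json$", f, ignore.case = TRUE)) {
      p <- tryCatch(unlist(jsonlite::read_json(f)), error = function(e) NULL)
      if (is.null(p) || !is.numeric(p) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-6)
        return(data.frame(file = f, kind = "reference_json", ok = FALSE,
                          message = "not a normalized probability map"))
      return(data.frame(file = f, kind = "reference_json", ok = TRUE,
                        message = ""))
    }
    if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
      arr <- tryCatch(readStack(f), error = function(e) NULL)
      if (is.null(arr) || length(dim(arr)) != 3L || dim(arr)[3L] < 2L)
        return(data.frame(file = f, kind = "tiff", ok = FALSE,
                          message = "not a multi-page 3D stack"))
      return(data.frame(file = f, kind = "tiff", ok = TRUE, message = ""))
    }
    data.frame(file = f, kind = "unknown", ok = FALSE,
               message = "unrecognized format")
  }
  do.call(rbind, lapply(files, checkOne))
}
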