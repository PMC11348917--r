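# File-format round-tripping: cluster tables and reference distributions,
# multi-page TIFF stacks and movies, stimulus-protocol configs.

#' Read / write presynaptic-cluster tables
#'
#' CSV with columns \code{cell_id}, \code{eye} (contra/ipsi),
#' \code{type_label} and optionally \code{eccentricity_deg}. Multiple
#' postsynaptic cells can share a file via a \code{postsynaptic_id} column.
#'
#' @param path CSV file path.
#' @param typeLevels optional declared label set.
#' @return A \linkS4class{PresynapticCluster}, or a named list of them when
#'   the file holds several postsynaptic cells.
#' @export
readClusterTable <- function(path, typeLevels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "eye", "type_label")
  if (!all(need %in% names(df)))
    stop("cluster table must have columns ", paste(need, collapse = ", "))
  mk <- function(sub, id) {
    PresynapticCluster(sub$type_label, sub$eye, postsynapticId = id,
                       eccentricityDeg = sub$eccentricity_deg,
                       typeLevels = typeLevels)
  }
  if ("postsynaptic_id" %in% names(df)) {
    parts <- split(df, df$postsynaptic_id)
    if (length(parts) > 1L)
      return(mapply(mk, parts, names(parts), SIMPLIFY = FALSE))
    return(mk(parts[[1L]], names(parts)[1L]))
  }
  mk(df, "cluster1")
}

#' @rdname readClusterTable
#' @param cluster a \linkS4class{PresynapticCluster}.
#' @export
writeClusterTable <- function(cluster, path) {
  df <- cluster@cells
  df <- cbind(cell_id = seq_len(nrow(df)),
              postsynaptic_id = cluster@postsynapticId, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a reference type distribution as JSON
#'
#' JSON object mapping type labels to probabilities.
#' @param path JSON file path.
#' @return Named probability vector.
#' @export
readReferenceDistribution <- function(path) {
  p <- unlist(jsonlite::read_json(path))
  assertProbs(p, "reference distribution", tol = 1e-6)
  p / sum(p)
}

#' @rdname readReferenceDistribution
#' @param probs named probability vector.
#' @export
writeReferenceDistribution <- function(probs, path) {
  assertProbs(probs, "reference distribution", tol = 1e-6)
  jsonlite::write_json(as.list(probs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write 3D stacks and movies as multi-page TIFF
#'
#' Pages are z-planes (stacks) or frames (movies); arrays are (y, x, z|t).
#' Intensities are scaled into [0, 1] on write (TIFF stores normalized
#' floats); the scale is returned as an attribute on read when present.
#'
#' @param path TIFF file path.
#' @return Numeric array (y, x, pages).
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    arr[, , i] <- p
  }
  arr
}

#' @rdname readStack
#' @param stack numeric array (y, x, pages).
#' @export
writeStack <- function(stack, path) {
  lo <- min(stack); hi <- max(stack)
  rng <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[3L]),
                  function(i) (stack[, , i] - lo) / rng)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a stimulus-protocol config from YAML or JSON
#'
#' Recognized fields mirror the arguments of \code{\link{stimulusProtocol}}.
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return A \code{StimulusProtocol}.
#' @export
readProtocol <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(stimulusProtocol,
          cfg[intersect(names(cfg), names(formals(stimulusProtocol)))])
}
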