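#' Write / read the epochs container
#'
#' A documented on-disk directory format for epoched EEG:
#' \describe{
#'   \item{meta.json}{format tag `"alphalat-epochs"`, container version,
#'     `subject_id`, `srate`, array dimensions and the time axis.}
#'   \item{layout.json}{sensor names, 2-D positions, hemisphere and mirror
#'     pairing, posterior/midfrontal groups, and the neighbor graph as an
#'     edge list.}
#'   \item{trials.tsv}{the trial table (schedule plus behavior columns),
#'     tab-separated.}
#'   \item{data.bin}{the voltage array as little-endian float64 in R
#'     column-major order of (trials, channels, samples).}
#' }
#' The JSON/TSV files double as a plain-text sidecar of everything except
#' the voltages. `read_epochs()` refuses containers whose format tag or
#' major version does not match instead of misparsing them.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param dir Directory to create/fill.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()`
#'   returns the reconstructed [eeg_epochs()].
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "alphalat-epochs", version = CONTAINER_VERSION,
    subject_id = epochs$subject_id, srate = epochs$srate,
    dims = dim(epochs$data), times = epochs$times
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  lay <- epochs$layout
  edges <- which(lay$adjacency & upper.tri(lay$adjacency), arr.ind = TRUE)
  jsonlite::write_json(
    list(
      channels = lay$channels, posterior = lay$posterior,
      midfrontal = lay$midfrontal, neighbor_dist = lay$neighbor_dist,
      edges = unname(as.data.frame(edges))
    ),
    file.path(dir, "layout.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.table(epochs$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  invisible(dir)
}

CONTAINER_VERSION <- "1.0"

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not an epochs container: missing meta.json")
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) stop("corrupt container: ",
                                            conditionMessage(e)))
  if (!identical(meta$format, "alphalat-epochs")) {
    stop("container version error: unrecognized format tag")
  }
  if (!identical(strsplit(as.character(meta$version), ".", fixed = TRUE)[[1]][1],
                 strsplit(CONTAINER_VERSION, ".", fixed = TRUE)[[1]][1])) {
    stop("container version error: version ", meta$version,
         " is not compatible with ", CONTAINER_VERSION)
  }
  lay_js <- jsonlite::read_json(file.path(dir, "layout.json"),
                                simplifyVector = TRUE)
  channels <- tibble::as_tibble(lay_js$channels)
  n_ch <- nrow(channels)
  adjacency <- matrix(FALSE, n_ch, n_ch,
                      dimnames = list(channels$name, channels$name))
  ed <- as.matrix(lay_js$edges)
  if (length(ed)) {
    adjacency[ed] <- TRUE
    adjacency[ed[, c(2, 1), drop = FALSE]] <- TRUE
  }
  layout <- structure(
    list(channels = channels, adjacency = adjacency,
         posterior = as.character(lay_js$posterior),
         midfrontal = as.character(lay_js$midfrontal),
         neighbor_dist = lay_js$neighbor_dist),
    class = "eeg_layout"
  )
  trials <- tibble::as_tibble(
    utils::read.delim(file.path(dir, "trials.tsv"), sep = "\t")
  )
  dims <- as.integer(meta$dims)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(dims), size = 8,
                  endian = "little")
  if (length(vals) != prod(dims)) {
    stop("corrupt container: data.bin has ", length(vals),
         " values, expected ", prod(dims))
  }
  eeg_epochs(array(vals, dims), as.numeric(meta$times), meta$srate,
             layout, trials, meta$subject_id)
}
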