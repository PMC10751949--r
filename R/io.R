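#' Write a dataset container
#'
#' Persists a [assemble_dataset()]-style dataset to a directory container:
#' `meta.json` (sampling rate, onsets, dimensions, responsive mask, seed,
#' pulse shape) plus the signal arrays in long form (`channel`, `trial`,
#' `sample`, `value`) as Parquet tables (`format = "parquet"`, requires the
#' arrow package) or delimited text (`format = "csv"`, for small
#' fixtures).  The round-trip is lossless.
#'
#' @param dataset an `spes_dataset`.
#' @param path directory to create/write into.
#' @param format `"parquet"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path, format = c("parquet", "csv")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(dataset$signals)
  meta <- list(container = "mparrm-trials", version = 1L, format = format,
               n_channels = d[1], n_trials = d[2], n_samples = d[3],
               fs_hz = dataset$fs_hz,
               onset_auditory_idx = dataset$onset_auditory_idx,
               onset_artifact_idx = dataset$onset_artifact_idx,
               responsive = dataset$responsive,
               effect_g = dataset$effect_g,
               seed = dataset$seed,
               shape = as.list(dataset$shape),
               has_truth = !is.null(dataset$truth))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  tables <- list(signals = dataset$signals)
  if (!is.null(dataset$truth)) tables$truth <- dataset$truth
  for (nm in names(tables)) {
    long <- array_to_long(tables[[nm]])
    f <- file.path(path, paste0(nm, if (format == "parquet") ".parquet" else ".csv"))
    if (format == "parquet") {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the arrow package is required for parquet containers; ",
             "use format = \"csv\" instead")
      }
      arrow::write_parquet(long, f)
    } else {
      write.csv(long, f, row.names = FALSE)
    }
  }
  invisible(path)
}

array_to_long <- function(a) {
  d <- dim(a)
  tibble::tibble(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.numeric(a))
}

long_to_array <- function(df, d) {
  a <- array(NA_real_, dim = d)
  idx <- cbind(df$channel, df$trial, df$sample)
  a[idx] <- df$value
  a
}

#' Read a dataset container
#'
#' Inverse of [write_trials()]; errors with the name of any missing
#' metadata field.
#'
#' @param path container directory.
#' @return An `spes_dataset`.
#' @export
read_trials <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("schema mismatch: missing meta.json in ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  required <- c("n_channels", "n_trials", "n_samples", "fs_hz",
                "onset_artifact_idx", "format")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("schema mismatch: missing field(s) ", paste(missing, collapse = ", "))
  }
  d <- c(meta$n_channels, meta$n_trials, meta$n_samples)
  read_tab <- function(nm) {
    f <- file.path(path, paste0(nm, if (meta$format == "parquet") ".parquet" else ".csv"))
    if (!file.exists(f)) return(NULL)
    df <- if (meta$format == "parquet") arrow::read_parquet(f)
          else tibble::as_tibble(read.csv(f))
    long_to_array(df, d)
  }
  structure(list(signals = read_tab("signals"), truth = read_tab("truth"),
                 fs_hz = meta$fs_hz,
                 onset_auditory_idx = meta$onset_auditory_idx,
                 onset_artifact_idx = meta$onset_artifact_idx,
                 responsive = meta$responsive, effect_g = meta$effect_g,
                 shape = tibble::as_tibble(meta$shape), seed = meta$seed),
            class = "spes_dataset")
}

#' Read and write run configuration files
#'
#' Round-trips an [mparrm_config()]-style nested configuration through a
#' YAML file losslessly.
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return `read_config()` returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  restore <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, restore)
    if (!is.null(x[[".class"]])) {
      cls <- x[[".class"]]
      x[[".class"]] <- NULL
      class(x) <- cls
    }
    x
  }
  restore(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (!is.list(x)) return(x)
    out <- lapply(x, strip)
    if (!is.null(attr(x, "class"))) out$.class <- class(x)
    out
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}
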