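#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults, grouped by
#' stage. Serialised as a flat `group.key=value` text file; unknown keys are
#' rejected on read so typos cannot silently fall back to defaults.
#'
#' @return Nested named list of parameter groups (`detection`,
#'   `classification`, `utr`, `motif`, `expression`, `align`).
#' @export
default_config <- function() {
  list(detection = detection_params(),
       classification = classification_params(),
       utr = utr_params(),
       motif = motif_params(),
       expression = expression_params(),
       align = align_params())
}

#' Write a configuration as flat key=value text
#'
#' @param config Nested list as from [default_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (grp in names(config))
    for (key in names(config[[grp]])) {
      val <- config[[grp]][[key]]
      lines <- c(lines, paste0(grp, ".", key, "=",
                               paste(val, collapse = ",")))
    }
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Values are coerced to the type of the corresponding default; keys absent
#' from the file keep their defaults; keys unknown to [default_config()]
#' are an error.
#'
#' @param path Path to the config file.
#' @return Nested list in the shape of [default_config()].
#' @export
read_config <- function(path) {
  config <- default_config()
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || is.null(config[[parts[1L]]]) ||
        !parts[2L] %in% names(config[[parts[1L]]]))
      stop("unknown config key: ", key)
    default <- config[[parts[1L]]][[parts[2L]]]
    parsed <- if (is.logical(default)) as.logical(val)
      else if (is.numeric(default)) as.numeric(strsplit(val, ",")[[1L]])
      else val
    if (anyNA(parsed)) stop("cannot parse config value for ", key)
    config[[parts[1L]]][[parts[2L]]] <- parsed
  }
  config
}
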