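#' Read a pipeline configuration file
#'
#' Supports plain `key=value` lines (`#` comments allowed) or YAML (by
#' file extension `.yml`/`.yaml`, requires the yaml package). Recognized
#' keys, with defaults: `divisor` (100, small-object area rule),
#' `connectivity` (8), `le_variant` (`"cooccurrence"`). Unknown keys are
#' an error.
#'
#' @param path config file path, or `NULL` for all defaults
#' @return named list with `divisor`, `connectivity`, `le_variant`
#' @export
read_config <- function(path = NULL) {
  defaults <- list(divisor = 100, connectivity = 8,
                   le_variant = "cooccurrence")
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package", call. = FALSE)
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    if (any(lengths(kv) != 2))
      stop("malformed config line; expected key=value", call. = FALSE)
    vals <- lapply(kv, function(x) trimws(x[2]))
    names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  }
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in intersect(names(vals), c("divisor", "connectivity")))
    vals[[k]] <- as.numeric(vals[[k]])
  utils::modifyList(defaults, vals)
}
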