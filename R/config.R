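#' Default analysis configuration
#'
#' The study settings: 100 Hz sampling, 5-second epochs, 128 epochs, Welch
#' segments of one epoch with 50% overlap, 0.5 Hz neighborhood half-width,
#' FDR threshold 0.05, maximum VAR order 50 and the bootstrap-count rule of
#' [nboots_rule()] (`nboots = NULL` selects the rule at run time).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(fs = 100, epoch_duration = 5, n_epochs = 128L,
       segment_length = 500L, overlap = 0.5,
       d = 0.5, q_threshold = 0.05,
       lag_max = 50L, nboots = NULL, gc_mode = "welch",
       gc_boot_stride = 1L,
       arms = c("bicoherence", "granger", "snr"),
       seed = 1L, out_dir = ".")
}

#' Read an analysis configuration file
#'
#' Reads a YAML key-value configuration and merges it over the defaults of
#' [default_config()]. Unknown keys and type mismatches are errors.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return Named list as in [default_config()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config file: ", conditionMessage(e))
  })
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config file must contain key-value pairs")
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (key in names(user)) {
    val <- user[[key]]
    def <- defaults[[key]]
    if (key == "nboots") {
      if (!is.null(val) && (!is.numeric(val) || val < 1)) {
        stop("type mismatch for 'nboots': expected a positive count or null")
      }
      defaults[[key]] <- if (is.null(val)) NULL else as.integer(val)
      next
    }
    if (is.numeric(def) && !is.numeric(val)) {
      stop("type mismatch for '", key, "': expected numeric")
    }
    if (is.character(def) && !is.character(val)) {
      stop("type mismatch for '", key, "': expected character")
    }
    defaults[[key]] <- if (is.integer(def)) as.integer(val) else val
  }
  defaults
}

#' Write an analysis configuration file
#'
#' @param config Named list as returned by [default_config()] or
#'   [parse_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
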