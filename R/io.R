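# Plain-text writers and readers for the package's result types. All floats
# are written with 17 significant digits so read(write(x)) round-trips to
# full double precision.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write an epoched series as TSV
#'
#' Writes the long-format table `epoch, sample, X1, ..., Xn` with a header
#' row, and a YAML sidecar (`<path>.yml`) recording the sampling rate and,
#' when available, the generating condition.
#'
#' @param series An [epoched_series()].
#' @param path Output TSV path.
#' @param sidecar Write the metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_epoched_tsv <- function(series, path, sidecar = TRUE) {
  df <- as.data.frame(series)
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sidecar) {
    meta <- list(fs = series$fs, channels = series$channels)
    if (!is.null(series$condition)) {
      meta$condition <- unclass(series$condition)
    }
    yaml::write_yaml(meta, paste0(path, ".yml"))
  }
  invisible(path)
}

#' Read an epoched series from TSV
#'
#' Inverse of [write_epoched_tsv()]. Epochs must be equal-length and the
#' requested channels present.
#'
#' @param path TSV path written by [write_epoched_tsv()].
#' @param fs Sampling rate in Hz; taken from the YAML sidecar when `NULL`.
#' @param channels Required channel columns; default: every column after
#'   `epoch` and `sample`.
#' @return An [epoched_series()].
#' @export
read_epoched_tsv <- function(path, fs = NULL, channels = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (!all(c("epoch", "sample") %in% names(df))) {
    stop("missing 'epoch'/'sample' columns")
  }
  if (!is.numeric(df$epoch) || any(df$epoch != round(df$epoch))) {
    stop("'epoch' column must be integer")
  }
  meta <- NULL
  if (file.exists(paste0(path, ".yml"))) {
    meta <- yaml::read_yaml(paste0(path, ".yml"))
  }
  if (is.null(fs)) {
    fs <- meta$fs
    if (is.null(fs)) stop("'fs' not given and no sidecar found")
  }
  if (is.null(channels)) {
    channels <- setdiff(names(df), c("epoch", "sample"))
  }
  missing_ch <- setdiff(channels, names(df))
  if (length(missing_ch)) {
    stop("missing channels: ", paste(missing_ch, collapse = ", "))
  }
  lens <- table(df$epoch)
  if (length(unique(as.vector(lens))) != 1L) {
    stop("ragged epochs: epoch lengths differ")
  }
  ns <- as.integer(lens[1])
  ne <- length(lens)
  df <- df[order(df$epoch, df$sample), , drop = FALSE]
  data <- array(0, dim = c(ns, ne, length(channels)))
  for (ch in seq_along(channels)) {
    data[, , ch] <- matrix(df[[channels[ch]]], nrow = ns)
  }
  cond <- NULL
  if (!is.null(meta$condition)) {
    cond <- structure(meta$condition, class = "condition_spec")
  }
  epoched_series(data, fs = fs, channels = channels, condition = cond)
}

#' Write a cross-bicoherence map as long-format TSV
#'
#' Columns `f1, f2, sector, b2`, with grid metadata in `#`-prefixed header
#' comments so [read_bicoherence_tsv()] can rebuild the object.
#'
#' @param map A [cross_bicoherence()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bicoherence_tsv <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# delta_f=%.17g f_nyquist=%.17g L=%d channels=%s",
                     map$delta_f, map$f_nyquist, map$L,
                     paste(map$channels, collapse = ",")), con)
  df <- as.data.frame(map)
  df$f1 <- fmt_num(df$f1)
  df$f2 <- fmt_num(df$f2)
  df$b2 <- fmt_num(df$b2)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cross-bicoherence map written by [write_bicoherence_tsv()]
#'
#' @param path TSV path.
#' @return A `bicoherence_map`.
#' @export
read_bicoherence_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing metadata header")
  kv <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1]]
  meta <- stats::setNames(
    lapply(strsplit(kv, "="), `[`, 2L),
    vapply(strsplit(kv, "="), `[`, "", 1L))
  delta_f <- as.numeric(meta$delta_f)
  f_nyquist <- as.numeric(meta$f_nyquist)
  L <- as.integer(meta$L)
  channels <- as.integer(strsplit(meta$channels, ",")[[1]])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  grid <- bifrequency_grid(delta_f, f_nyquist)
  m <- length(grid$f1)
  b2 <- matrix(df$b2[order(match(df$f2, grid$f2), match(df$f1, grid$f1))],
               nrow = m)
  structure(list(b2 = b2, f1 = grid$f1, f2 = grid$f2, sector = grid$sector,
                 principal = grid$principal,
                 zero_denominator = matrix(FALSE, m, m), L = L,
                 channels = channels, delta_f = delta_f,
                 f_nyquist = f_nyquist),
            class = "bicoherence_map")
}

#' Write a significance map as TSV
#'
#' Columns `f1, f2, b2, q, significant` over the principal domain.
#'
#' @param sig A [significance_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_significance_tsv <- function(sig, path) {
  df <- data.frame(f1 = rep(sig$f1, times = length(sig$f2)),
                   f2 = rep(sig$f2, each = length(sig$f1)),
                   b2 = fmt_num(as.vector(sig$b2bar)),
                   q = fmt_num(as.vector(sig$q)),
                   significant = as.vector(sig$significant))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Granger-causality spectrum as TSV
#'
#' Columns `f, BGCS_median, p, q, significant, theta, lag, nboots`.
#'
#' @param spec A [bgcs()] result, after [bootstrap_significance()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gc_tsv <- function(spec, path) {
  df <- data.frame(f = fmt_num(spec$freq),
                   BGCS_median = fmt_num(spec$bgcs),
                   p = fmt_num(if (is.null(spec$p)) rep(NA_real_, length(spec$freq)) else spec$p),
                   q = fmt_num(if (is.null(spec$q)) rep(NA_real_, length(spec$freq)) else spec$q),
                   significant = if (is.null(spec$significant)) NA else spec$significant,
                   theta = fmt_num(if (is.null(spec$theta)) NA_real_ else spec$theta),
                   lag = spec$lag,
                   nboots = if (is.null(spec$nboots)) NA_integer_ else spec$nboots)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a study table as TSV
#'
#' @param table A [run_study()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_study_tsv <- function(table, path) {
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
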