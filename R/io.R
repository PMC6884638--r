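#' Read and write kinetic datasets as annotated CSV
#'
#' The on-disk format is a plain CSV with header \code{time_s,conversion},
#' preceded by \code{# key: value} comment lines carrying the run metadata
#' (\code{M0_M}, \code{ratio}, \code{label}, optionally \code{seed}). The
#' round trip is lossless to 1e-12 (values are written with 17 significant
#' digits).
#'
#' @param dataset a [kinetic_dataset()].
#' @param path file path.
#' @return \code{read_kinetic_csv} returns a [kinetic_dataset()];
#'   \code{write_kinetic_csv} returns \code{path} invisibly.
#' @export
write_kinetic_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# M0_M: %.17g", dataset$ic$M0),
    sprintf("# ratio: %.17g", dataset$ic$ratio),
    sprintf("# label: %s", dataset$label),
    if (!is.null(dataset$meta$seed)) sprintf("# seed: %d", dataset$meta$seed),
    "time_s,conversion"
  ), con)
  writeLines(sprintf("%.17g,%.17g", dataset$times, dataset$conversion), con)
  invisible(path)
}

#' @rdname write_kinetic_csv
#' @export
read_kinetic_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  for (key in c("M0_M", "ratio")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("missing required metadata key '%s' in %s", key, path))
    }
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || !grepl("^time_s\\s*,\\s*conversion", body[1])) {
    stop("missing 'time_s,conversion' header")
  }
  df <- read.table(text = body[-1], sep = ",",
                   col.names = c("time_s", "conversion"))
  if (any(diff(df$time_s) <= 0)) stop("non-monotone times in ", path)
  ic <- initial_conditions(M0 = as.numeric(meta$M0_M),
                           ratio = as.numeric(meta$ratio))
  kinetic_dataset(df$time_s, df$conversion, ic,
                  label = if (is.null(meta$label)) "" else meta$label,
                  meta = if (is.null(meta$seed)) list() else
                    list(seed = as.integer(meta$seed)))
}

#' Export a conversion series or distribution as tidy CSV
#'
#' @param x a \code{conversion_series}, \code{chain_length_distribution} or
#'   GPC trace data frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "chain_length_distribution") && nrow(df)) {
    tot <- sum(df$dp * df$conc)
    df$mass_fraction <- if (tot > 0) df$dp * df$conc / tot else 0
  }
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
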