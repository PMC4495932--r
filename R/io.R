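# Plain-text serialization: matrices, trajectories, configs, reports.
# Numbers are written with 17 significant digits so that a write/read
# round trip preserves doubles exactly; CSV always uses '.' decimals.

#' Write and read a numeric matrix as CSV
#'
#' Full-precision (17 significant digits) round-trip safe CSV without
#' row or column names.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_csv` returns the matrix.
#' @export
write_matrix_csv <- function(m, path) {
  txt <- apply(m, 1, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Write a trajectory to long-format CSV
#'
#' Columns `t, neuron, r1, r2, r3`, full precision.
#'
#' @param traj a `trajectory` object.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment configuration
#'
#' YAML is the native format; JSON is accepted (detected from the
#' extension or leading `{`).
#'
#' @param path configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  first <- trimws(readLines(path, n = 1, warn = FALSE))
  if (grepl("\\.json$", path, ignore.case = TRUE) || startsWith(first, "{"))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Serialize a stability report to JSON
#'
#' @param report a `stability_report` object.
#' @param path optional file path; if missing the JSON string is returned.
#' @param nonlinear optional result of [aizerman_tau3_network()] attached
#'   under a `"nonlinear"` section.
#' @return The JSON string, invisibly if written to file.
#' @export
stability_report_json <- function(report, path = NULL, nonlinear = NULL) {
  x <- list(regime = report$regime, marginal = report$marginal,
            dominant_eigenvalue = c(re = Re(report$dominant_eigenvalue),
                                    im = Im(report$dominant_eigenvalue)),
            tau3_crit_ms = report$tau3_crit,
            tau3_osc_free_ms = report$tau3_osc_free,
            method = as.list(report$method))
  if (!is.null(nonlinear)) x$nonlinear <- nonlinear
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# FNV-1a hash of the canonical JSON encoding of a config, for provenance
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (b in bytes) {
    low <- bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- h - (h %% 256) + low
    lo <- h %% 65536; hi <- h %/% 65536
    h <- ((lo * 16777619) %% 4294967296 +
            ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
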