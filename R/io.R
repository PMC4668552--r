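# Delimited-text interchange formats.  Signals are CSV matrices preceded
# by comment headers ("# dt1 = ...") carrying the dwell times; masks are
# two-column 0-based TSV; configs are YAML.

#' Write / read a 2D time-domain signal as delimited text
#'
#' The matrix is stored row-major as comma-separated values, preceded by
#' comment lines `# dt1 = <s>`, `# dt2 = <s>` and `# meta = <text>` that
#' carry the dwell times and provenance.
#'
#' @param signal a [td_signal()].
#' @param path file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `write_signal` returns `path` invisibly; `read_signal` returns
#'   a [td_signal()].
#' @export
write_signal <- function(signal, path, sep = ",") {
  stopifnot(inherits(signal, "td_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt1 = %.17g", signal$dt1),
               sprintf("# dt2 = %.17g", signal$dt2),
               paste0("# meta = ", gsub("[\r\n]", " ", signal$meta))), con)
  write.table(format(signal$values, digits = 17, trim = TRUE,
                     scientific = TRUE),
              con, sep = sep, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path, sep = ",") {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(ln)) stop("missing header key '", key, "' in ", path)
    as.numeric(sub(".*=\\s*", "", ln[1L]))
  }
  meta_ln <- grep("^#\\s*meta\\s*=", hdr, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  vals <- do.call(rbind, lapply(strsplit(body, sep, fixed = TRUE),
                                as.numeric))
  td_signal(vals, get_num("dt1"), get_num("dt2"),
            meta = if (length(meta_ln))
              sub(".*=\\s*", "", meta_ln[1L]) else "")
}

#' Write / read an observation mask as two-column text
#'
#' Masks are stored as tab-separated 0-based `(row, col)` pairs, one per
#' line, no header.
#'
#' @param omega two-column integer matrix of 0-based index pairs.
#' @param path file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns the
#'   index matrix.
#' @export
write_mask <- function(omega, path) {
  omega <- as.matrix(omega)
  storage.mode(omega) <- "integer"
  write.table(omega, path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                            colClasses = "integer"))
  dimnames(m) <- list(NULL, c("row", "col"))
  m
}

#' Read an SVT solver configuration from YAML
#'
#' Recognized keys: `tau`, `delta`, `eps0`, `max_iter`, `seed` (the seed
#' is returned alongside the config for use by mask drawing).
#'
#' @param path YAML file path.
#' @return A list with `config` (an [svt_config()]) and `seed` (integer
#'   or NULL).
#' @export
read_svt_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("tau", "delta", "eps0", "max_iter", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown key(s) in ", path, ": ", paste(bad, collapse = ", "))
  cfg <- svt_config(tau = y$tau, delta = y$delta,
                    eps0 = if (is.null(y$eps0)) 1e-4 else y$eps0,
                    max_iter = if (is.null(y$max_iter)) 1000L else y$max_iter)
  list(config = cfg, seed = if (is.null(y$seed)) NULL else as.integer(y$seed))
}

#' Read a spin-system description from YAML
#'
#' Keys use explicit units: `D_hz`, `g`, `b_mT`, `theta_deg`, `phi_deg`,
#' `A_n_hz` (3x3 nested list), `A_c_hz` (optional 3x3 nested list),
#' `include_nuclear_zeeman`, `P_n_hz`.
#'
#' @param path YAML file path.
#' @return A [spin_system()].
#' @export
read_spin_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("D_hz", "g", "b_mT", "theta_deg", "phi_deg", "A_n_hz",
             "A_c_hz", "include_nuclear_zeeman", "P_n_hz")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown key(s) in ", path, ": ", paste(bad, collapse = ", "))
  as_tensor <- function(x) if (is.null(x)) NULL else
    matrix(as.numeric(unlist(x)), 3, 3, byrow = TRUE)
  spin_system(
    D_hz = if (is.null(y$D_hz)) 2.87e9 else y$D_hz,
    g = if (is.null(y$g)) 2.0028 else y$g,
    b_t = if (is.null(y$b_mT)) 0 else y$b_mT * 1e-3,
    theta_deg = if (is.null(y$theta_deg)) 0 else y$theta_deg,
    phi_deg = if (is.null(y$phi_deg)) 0 else y$phi_deg,
    A_n_hz = if (is.null(y$A_n_hz)) matrix(0, 3, 3) else as_tensor(y$A_n_hz),
    A_c_hz = as_tensor(y$A_c_hz),
    include_nuclear_zeeman = if (is.null(y$include_nuclear_zeeman)) TRUE
      else isTRUE(y$include_nuclear_zeeman),
    P_n_hz = y$P_n_hz)
}

#' Write / read sweep results as CSV
#'
#' @param sweep a [sweep_fraction()] / [sweep_threshold()] result.
#' @param path file path.
#' @return `write_sweep` returns `path` invisibly; `read_sweep` the
#'   `sweep_result` data frame.
#' @export
write_sweep <- function(sweep, path) {
  write.table(as.data.frame(sweep), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE,
                   stringsAsFactors = FALSE)
  class(df) <- c("sweep_result", "data.frame")
  df
}
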