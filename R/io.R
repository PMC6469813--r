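#' Read a univariate activity series from disk
#'
#' Accepts single-column text (whitespace/newline separated) or CSV; for
#' CSV the column named `A` (or the first numeric column) is used. This is
#' the interoperability entry point for running the analysis stages on
#' externally produced series.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_activity <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path)
    col <- if ("A" %in% names(d)) "A" else names(d)[vapply(d, is.numeric,
                                                           logical(1))][1]
    if (is.na(col)) stop("no numeric column found in ", path)
    return(as.numeric(d[[col]]))
  }
  as.numeric(scan(path, quiet = TRUE))
}

#' Write a trace's activity series as single-column text
#'
#' @param trace A `cros_trace` or numeric vector.
#' @param path Output path.
#' @export
write_activity <- function(trace, path) {
  A <- if (inherits(trace, "cros_trace")) trace$A else as.numeric(trace)
  writeLines(format(A, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Export an avalanche catalog as TSV
#'
#' Writes the event table with header `t_i`, `t_f`, `T_ms`, `s_g`,
#' `s_theta` (profiles are not serialized; regenerate them from the trace).
#'
#' @param catalog A `cros_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "cros_catalog"))
  ev <- catalog$events
  out <- data.frame(t_i = ev$t_i, t_f = ev$t_f, T_ms = ev$T,
                    s_g = ev$s_g, s_theta = ev$s_theta)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a network topology as plain text
#'
#' Two-file plain-text representation: a TSV of the coordinate-format
#' signed sparse weight list (`pre_index`, `post_index`, `weight`;
#' 0-based, row-major over the lattice) preceded by comment header lines
#' carrying the scalar fields and the per-neuron type string.
#'
#' @param topology A `cros_topology`.
#' @param path Output path.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "cros_topology"))
  W <- methods::as(topology$weights, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# L=%d ell=%d r_E=%g r_I=%g exc_fraction=%g seed=%d",
            topology$L, topology$ell, topology$r_E, topology$r_I,
            topology$exc_fraction, topology$seed),
    paste0("# types=", paste(ifelse(topology$is_excitatory, "E", "I"),
                             collapse = ""))), con)
  utils::write.table(data.frame(pre_index = W@i, post_index = W@j,
                                weight = W@x),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a topology written by [write_topology()]
#'
#' @param path File path.
#' @return A `cros_topology`.
#' @export
read_topology <- function(path) {
  hdr <- readLines(path, n = 2)
  kv <- strsplit(sub("^# ", "", hdr[1]), " ")[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  types <- sub("^# types=", "", hdr[2])
  is_exc <- strsplit(types, "")[[1]] == "E"
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n <- as.integer(vals["L"])^2
  W <- Matrix::sparseMatrix(i = d$pre_index + 1L, j = d$post_index + 1L,
                            x = d$weight, dims = c(n, n))
  structure(list(L = as.integer(vals["L"]), ell = as.integer(vals["ell"]),
                 r_E = vals[["r_E"]], r_I = vals[["r_I"]],
                 exc_fraction = vals[["exc_fraction"]],
                 is_excitatory = is_exc, weights = W,
                 seed = as.integer(vals["seed"]),
                 normalization = "neighborhood"),
            class = "cros_topology")
}
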