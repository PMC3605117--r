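#' Time series of nodal fields on a mesh
#'
#' Stores time stamps and per-time nodal arrays (scalars as columns of a
#' matrix), with the generating mesh and field metadata.
#'
#' @param times strictly increasing numeric time stamps (s)
#' @param values matrix (n_nodes x n_times) of nodal values
#' @param mesh the `uw_mesh` the values live on
#' @param name field name (e.g. "v_m")
#' @param units unit string (e.g. "V")
#' @return a `field_series` object
#' @export
field_series <- function(times, values, mesh, name = "field", units = "") {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("field_series: times must be strictly increasing")
  values <- as.matrix(values)
  if (ncol(values) != length(times))
    stop("field_series: one value column per time stamp required")
  if (nrow(values) != nrow(mesh$nodes))
    stop("field_series: value rows (", nrow(values),
         ") must match mesh nodes (", nrow(mesh$nodes), ")")
  structure(list(times = times, values = values, mesh = mesh,
                 name = name, units = units), class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("field_series '%s' [%s]: %d nodes x %d times, t in [%g, %g] s\n",
              x$name, x$units, nrow(x$values), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Extract probe traces from a field series
#'
#' Values at the mesh nodes nearest to the requested probe positions.
#'
#' @param series a [field_series()]
#' @param points matrix of probe positions (n x dim) or a vector for one
#'   probe
#' @return data.frame with column `t` and one column per probe
#' @export
probe_trace <- function(series, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  d <- ncol(series$mesh$nodes)
  points <- points[, seq_len(d), drop = FALSE]
  ids <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- rowSums(sweep(series$mesh$nodes, 2, points[i, ])^2)
    ids[i] <- which.min(d2)
  }
  out <- data.frame(t = series$times)
  for (i in seq_along(ids))
    out[[paste0("probe", i)]] <- series$values[ids[i], ]
  attr(out, "node_ids") <- ids
  out
}

#' Write a field series as CSV (long: time rows, node columns are wide)
#' @param series a [field_series()]
#' @param file output path
#' @export
write_series_csv <- function(series, file) {
  df <- as.data.frame(t(series$values))
  names(df) <- paste0("n", seq_len(nrow(series$values)))
  df <- cbind(t = series$times, df)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
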