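#' Discrete gene-expression time series
#'
#' Container for an N x (T+1) matrix of discrete states, one row per
#' variable (gene) and one column per time point. Time points are indexed
#' from zero: column 1 holds the initial observation x(0) and the remaining
#' T columns the observations x(1..T), so a series with T+1 columns carries
#' T usable transitions t-1 -> t. Entry `values[i, ]` must lie in
#' `0..arities[i]-1`.
#'
#' @param values integer matrix, variables x time points; no missing values.
#' @param arities integer vector of per-variable state counts (each >= 2);
#'   defaults to `max(row) + 1`, floored at 2.
#' @param var_names variable identifiers; default rownames or `V1..VN`.
#' @param time_labels optional column labels.
#' @return An object of class `discrete_ts` with fields `values`,
#'   `arities`, `var_names`, `time_labels`.
#' @seealso [binarize()], [read_expression_tsv()]
#' @export
discrete_timeseries <- function(values, arities = NULL, var_names = NULL,
                                time_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("need at least one variable and two time points (T >= 1)")
  if (anyNA(values))
    stop("missing entries are not supported; impute or drop before loading")
  if (!all(values == floor(values)))
    stop("discrete states must be integers")
  storage.mode(values) <- "integer"
  if (any(values < 0L))
    stop("discrete states must be coded 0..r_i-1")
  if (is.null(arities))
    arities <- pmax(apply(values, 1L, max) + 1L, 2L)
  arities <- as.integer(arities)
  if (length(arities) != nrow(values))
    stop("one arity per variable required")
  if (any(arities < 2L))
    stop("all arities must be >= 2")
  bad <- which(apply(values, 1L, max) >= arities)
  if (length(bad))
    stop("states out of range for variable(s): ",
         paste(bad, collapse = ", "))
  if (is.null(var_names)) var_names <- rownames(values)
  if (is.null(var_names)) var_names <- paste0("V", seq_len(nrow(values)))
  if (is.null(time_labels)) time_labels <- colnames(values)
  dimnames(values) <- NULL
  structure(list(values = values, arities = arities,
                 var_names = as.character(var_names),
                 time_labels = time_labels),
            class = "discrete_ts")
}

#' Continuous gene-expression time series
#'
#' Raw (pre-discretization) expression container with the same
#' genes x time-points orientation as [discrete_timeseries()].
#'
#' @param values numeric matrix, variables x time points; finite entries.
#' @param var_names,time_labels as in [discrete_timeseries()].
#' @return An object of class `continuous_ts`.
#' @export
continuous_timeseries <- function(values, var_names = NULL,
                                  time_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop("continuous series must be finite with no missing entries")
  storage.mode(values) <- "double"
  if (is.null(var_names)) var_names <- rownames(values)
  if (is.null(var_names)) var_names <- paste0("V", seq_len(nrow(values)))
  if (is.null(time_labels)) time_labels <- colnames(values)
  dimnames(values) <- NULL
  structure(list(values = values, var_names = as.character(var_names),
                 time_labels = time_labels),
            class = "continuous_ts")
}

#' @export
print.discrete_ts <- function(x, ...) {
  cat(sprintf("discrete_ts: %d variables x %d time points (T = %d), arities %s\n",
              nrow(x$values), ncol(x$values), ncol(x$values) - 1L,
              paste(range(x$arities), collapse = "-")))
  invisible(x)
}

#' @export
print.continuous_ts <- function(x, ...) {
  cat(sprintf("continuous_ts: %d variables x %d time points\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Number of transitions in a time series
#'
#' @param x a `discrete_ts` or `continuous_ts`.
#' @return T, the number of usable transitions (columns minus one).
#' @export
n_transitions <- function(x) ncol(x$values) - 1L

#' Read a tab-separated expression matrix
#'
#' Expects a rectangular TSV with a header row of time labels and a first
#' column of gene names; remaining cells numeric. The header may or may not
#' carry a corner label for the gene-name column.
#'
#' @param path file path.
#' @return A [continuous_timeseries()] preserving row order.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expected a header row and at least one gene row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  body <- cells[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L)
    stop("ragged rows: row(s) ",
         paste(which(widths != widths[1L]) + 1L, collapse = ", "),
         " have a different number of fields (format error)")
  ntime <- widths[1L] - 1L
  if (ntime < 1L) stop("no data columns found")
  if (length(header) == ntime) {
    time_labels <- header
  } else if (length(header) == ntime + 1L) {
    time_labels <- header[-1L]
  } else {
    stop("header has ", length(header), " fields but data rows have ",
         widths[1L], " (format error)")
  }
  var_names <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_real_, length(body), ntime)
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !nzchar(trimws(raw)))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d (gene '%s'), column %d",
                   i + 1L, var_names[i], bad[1L] + 1L))
    vals[i, ] <- num
  }
  continuous_timeseries(vals, var_names = var_names,
                        time_labels = time_labels)
}

#' Write an expression matrix as TSV
#'
#' Mirrors [read_expression_tsv()]: numeric values are serialized with
#' `%.17g` so that a write/read round trip reproduces doubles bit-exactly;
#' integer matrices round-trip verbatim.
#'
#' @param x a `continuous_ts` or `discrete_ts`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  vals <- x$values
  labs <- x$time_labels
  if (is.null(labs)) labs <- paste0("t", seq_len(ncol(vals)) - 1L)
  fmt <- if (is.integer(vals)) function(v) sprintf("%d", v)
         else function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", labs), collapse = "\t"), con)
  for (i in seq_len(nrow(vals)))
    writeLines(paste(c(x$var_names[i], fmt(vals[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Binarize a continuous expression series
#'
#' Thresholds each gene at its own mean (default) or median; a value is
#' mapped to 1 iff it strictly exceeds the threshold. Constant rows carry no
#' signal and are mapped to all-zero with a warning.
#'
#' @param data a [continuous_timeseries()].
#' @param method `"mean"` or `"median"` per-gene threshold.
#' @return A [discrete_timeseries()] with all arities 2.
#' @export
binarize <- function(data, method = c("mean", "median")) {
  method <- match.arg(method)
  vals <- data$values
  if (nrow(vals) == 0L || ncol(vals) == 0L) stop("empty matrix")
  thr <- switch(method,
                mean = rowMeans(vals),
                median = apply(vals, 1L, stats::median))
  const <- apply(vals, 1L, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant row(s) mapped to all-zero: ",
            paste(data$var_names[const], collapse = ", "), call. = FALSE)
  out <- (vals > thr) * 1L
  storage.mode(out) <- "integer"
  discrete_timeseries(out, arities = rep(2L, nrow(vals)),
                      var_names = data$var_names,
                      time_labels = data$time_labels)
}

#' Mixed-radix parent-configuration index
#'
#' Maps a tuple of parent states to the flat configuration index j used to
#' address multinomial CPD rows. The first parent is the most significant
#' digit; the empty parent set always maps to 0.
#'
#' @param values integer vector of parent states (one per parent, 0-based).
#' @param parent_arities integer vector of matching arities.
#' @return Integer j in `[0, prod(parent_arities))`.
#' @examples
#' parent_config_index(c(1, 0), c(2, 2))   # 2
#' parent_config_index(c(1, 2), c(2, 3))   # 5
#' parent_config_index(integer(0), integer(0))  # 0
#' @export
parent_config_index <- function(values, parent_arities) {
  if (length(values) != length(parent_arities))
    stop("one state per parent required")
  if (length(values) == 0L) return(0L)
  values <- as.integer(values)
  parent_arities <- as.integer(parent_arities)
  if (any(values < 0L) || any(values >= parent_arities))
    stop("parent state out of range for its arity")
  j <- 0L
  for (p in seq_along(values)) j <- j * parent_arities[p] + values[p]
  j
}
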