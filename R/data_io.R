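#' Construct a concentration time-series set
#'
#' The sole experimental input of the inference pipeline: sampling times in
#' hours, one concentration column per species (nM), and optionally a matrix
#' of absolute measurement errors of the same shape.
#'
#' @param times strictly increasing sampling times in hours (>= 3).
#' @param values numeric matrix, rows = times, columns = species; column
#'   names are the species identifiers.
#' @param errors optional nonnegative matrix of absolute errors, same shape.
#' @return An object of class `tlc_timeseries` with fields `species`,
#'   `times`, `values`, `errors`.
#' @export
#' @examples
#' ts <- timeseries_set(c(0, 4, 12, 24), cbind(A = c(1, 2, 3, 4)))
timeseries_set <- function(times, values, errors = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  }
  times <- as.numeric(times)
  if (length(times) != nrow(values)) {
    stop("length(times) must equal nrow(values)", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("at least 3 time points are required", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("non-monotone times", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate species: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(errors)) {
    errors <- as.matrix(errors)
    if (!all(dim(errors) == dim(values))) {
      stop("errors must have the same shape as values", call. = FALSE)
    }
    if (any(!is.finite(errors)) || any(errors < 0)) {
      stop("errors must be finite and nonnegative", call. = FALSE)
    }
    colnames(errors) <- colnames(values)
  }
  structure(
    list(species = colnames(values), times = times, values = values,
         errors = errors),
    class = "tlc_timeseries"
  )
}

#' @export
print.tlc_timeseries <- function(x, ...) {
  cat(sprintf(
    "Time series: %d species, %d samples on [%g, %g] h%s\n",
    length(x$species), length(x$times), min(x$times), max(x$times),
    if (is.null(x$errors)) "" else ", with measurement errors"
  ))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Read a time-series table
#'
#' Expects a delimited text file with a header row, a first column named
#' `time` (hours) and one numeric column per species (nM). Columns whose name
#' carries an `_err` suffix are interpreted as absolute measurement errors of
#' the matching species column.
#'
#' @param path file path.
#' @param sep field delimiter (default tab; `","` and `";"` tables work too).
#' @return A [timeseries_set()] object.
#' @export
read_timeseries <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) stop("need a time column plus >= 1 species", call. = FALSE)
  if (tolower(names(df)[1L]) != "time") {
    stop("first column must be named 'time'", call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df)))
  )
  bad <- which(is.na(num) & !is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1L, 1L], names(df)[bad[1L, 2L]]), call. = FALSE)
  }
  times <- num[, 1L]
  rest <- num[, -1L, drop = FALSE]
  colnames(rest) <- names(df)[-1L]
  is_err <- grepl("_err$", colnames(rest))
  values <- rest[, !is_err, drop = FALSE]
  errors <- NULL
  if (any(is_err)) {
    err_for <- sub("_err$", "", colnames(rest)[is_err])
    missing_sp <- setdiff(err_for, colnames(values))
    if (length(missing_sp) > 0L) {
      stop("error column without species column: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    errors <- matrix(0, nrow(values), ncol(values),
                     dimnames = dimnames(values))
    errors[, err_for] <- rest[, is_err, drop = FALSE]
  }
  timeseries_set(times, values, errors)
}

#' Write a time-series table
#'
#' Inverse of [read_timeseries()]: full-precision delimited text with a
#' `time` column, species columns, and `<species>_err` columns when errors
#' are present.
#'
#' @param ts a [timeseries_set()] object.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  stopifnot(inherits(ts, "tlc_timeseries"))
  df <- data.frame(time = format(ts$times, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (sp in ts$species) {
    df[[sp]] <- format(ts$values[, sp], digits = 17, trim = TRUE)
  }
  if (!is.null(ts$errors)) {
    for (sp in ts$species) {
      df[[paste0(sp, "_err")]] <- format(ts$errors[, sp], digits = 17,
                                         trim = TRUE)
    }
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resample a time series onto a uniform grid
#'
#' Values are interpolated with the monotone, overshoot-free Stineman
#' interpolant; errors (when present) are interpolated linearly. Needed
#' because the lag grid assumes equally spaced samples while experimental
#' series are typically irregular.
#'
#' @param ts a [timeseries_set()] object.
#' @param step grid step in hours; defaults to the smallest observed
#'   inter-sample gap.
#' @return A resampled [timeseries_set()].
#' @export
resample_uniform <- function(ts, step = NULL) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  span <- diff(range(ts$times))
  if (is.null(step)) step <- min(diff(ts$times))
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (step > span / 2) {
    stop("step larger than half the observation span", call. = FALSE)
  }
  grid <- seq(min(ts$times), max(ts$times), by = step)
  vals <- vapply(
    ts$species,
    function(sp) stineman_interp(ts$times, ts$values[, sp], grid),
    numeric(length(grid))
  )
  colnames(vals) <- ts$species
  errs <- NULL
  if (!is.null(ts$errors)) {
    errs <- vapply(
      ts$species,
      function(sp) approx(ts$times, ts$errors[, sp], xout = grid)$y,
      numeric(length(grid))
    )
    colnames(errs) <- ts$species
  }
  timeseries_set(grid, vals, errs)
}

#' Construct a reaction network
#'
#' @param reactions data frame with columns `id`, `from`, `to` and optional
#'   numeric columns `k` (rate constant, 1/h) and `dk` (its error).
#' @param species optional species universe; defaults to the species named in
#'   the reactions.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(reactions, species = NULL) {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  need <- c("id", "from", "to")
  if (!all(need %in% names(reactions))) {
    stop("reactions need columns id, from, to", call. = FALSE)
  }
  if (!"k" %in% names(reactions)) {
    reactions$k <- rep(NA_real_, nrow(reactions))
  }
  if (!"dk" %in% names(reactions)) {
    reactions$dk <- rep(NA_real_, nrow(reactions))
  }
  reactions <- reactions[, c("id", "from", "to", "k", "dk")]
  if (nrow(reactions) > 0L) {
    if (any(!is.na(reactions$k) & reactions$k < 0)) {
      stop("rate constants must be nonnegative", call. = FALSE)
    }
    dup <- duplicated(reactions[, c("id", "from", "to")])
    if (any(dup)) {
      stop("duplicate reaction: ", reactions$id[dup][1L], call. = FALSE)
    }
  }
  if (is.null(species)) {
    species <- unique(c(reactions$from, reactions$to))
  } else {
    unknown <- setdiff(unique(c(reactions$from, reactions$to)), species)
    if (length(unknown) > 0L) {
      stop("reaction references species outside the universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d reactions over %d species\n",
              nrow(x$reactions), length(x$species)))
  if (nrow(x$reactions) > 0L) {
    for (i in seq_len(nrow(x$reactions))) {
      r <- x$reactions[i, ]
      ktxt <- if (is.na(r$k)) "" else {
        if (is.na(r$dk)) sprintf("  k = %.4g", r$k)
        else sprintf("  k = %.4g +- %.4g", r$k, r$dk)
      }
      cat(sprintf("  %-4s %s -> %s%s\n", r$id, r$from, r$to, ktxt))
    }
  }
  invisible(x)
}

#' Read a plain-text reaction list
#'
#' Each non-empty, non-comment line has the form `A -> B`, optionally
#' followed by `; k` and `; dk`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param species optional species universe; by default collected from the
#'   file. Passing a universe makes unknown species an error.
#' @return A [reaction_network()].
#' @export
read_reactions <- function(path, species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  rows <- lapply(keep, function(ln) {
    parts <- trimws(strsplit(lines[ln], ";", fixed = TRUE)[[1L]])
    m <- regmatches(parts[1L],
                    regexec("^(\\S+)\\s*->\\s*(\\S+)$", parts[1L]))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("malformed reaction at line %d: '%s'", ln, lines[ln]),
           call. = FALSE)
    }
    k <- if (length(parts) >= 2L) as.numeric(parts[2L]) else NA_real_
    dk <- if (length(parts) >= 3L) as.numeric(parts[3L]) else NA_real_
    if ((length(parts) >= 2L && is.na(k)) ||
        (length(parts) >= 3L && is.na(dk))) {
      stop(sprintf("malformed rate constant at line %d", ln), call. = FALSE)
    }
    list(from = m[2L], to = m[3L], k = k, dk = dk)
  })
  reactions <- data.frame(
    id = paste0("R", seq_along(rows), recycle0 = TRUE),
    from = vapply(rows, `[[`, "", "from"),
    to = vapply(rows, `[[`, "", "to"),
    k = vapply(rows, `[[`, 0, "k"),
    dk = vapply(rows, `[[`, 0, "dk"),
    stringsAsFactors = FALSE
  )
  reaction_network(reactions, species = species)
}

#' Write a reaction list
#'
#' Exact inverse of [read_reactions()] (up to reaction ids, which are
#' positional in the text format).
#'
#' @param net a [reaction_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  lines <- character(nrow(net$reactions))
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    line <- paste(r$from, "->", r$to)
    if (!is.na(r$k)) {
      line <- paste(line, ";", format(r$k, digits = 17, trim = TRUE))
      if (!is.na(r$dk)) {
        line <- paste(line, ";", format(r$dk, digits = 17, trim = TRUE))
      }
    }
    lines[i] <- line
  }
  writeLines(lines, path)
  invisible(path)
}
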