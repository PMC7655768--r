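#' Time-series container for state trajectories
#'
#' Bundles a time grid with sampled states, optional derivatives and
#' optional control inputs. All regression routines in the package
#' consume this container; simulators return it with analytically
#' evaluated derivatives.
#'
#' @param t numeric vector of sample times (strictly increasing).
#' @param X numeric matrix (m x n) of states; column names identify the
#'   state variables.
#' @param Xdot optional numeric matrix (m x n) of time derivatives.
#'   Column names default to the state names prefixed with "d".
#' @param U optional numeric matrix (m x q) of control inputs.
#' @return An object of class `ts_data`.
#' @export
ts_data <- function(t, X, Xdot = NULL, U = NULL) {
  t <- as.numeric(t)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(t) != nrow(X)) stop("length(t) must equal nrow(X)")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (!is.null(Xdot)) {
    Xdot <- as.matrix(Xdot)
    if (nrow(Xdot) != nrow(X)) stop("Xdot must have the same number of rows as X")
    if (is.null(colnames(Xdot))) colnames(Xdot) <- paste0("d", colnames(X))
  }
  if (!is.null(U)) {
    U <- as.matrix(U)
    if (nrow(U) != nrow(X)) stop("U must have the same number of rows as X")
    if (is.null(colnames(U))) colnames(U) <- paste0("u", seq_len(ncol(U)))
  }
  obj <- structure(list(t = t, X = X, Xdot = Xdot, U = U), class = "ts_data")
  validate_ts_data(obj)
  obj
}

validate_ts_data <- function(data) {
  for (nm in c("X", "Xdot", "U")) {
    m <- data[[nm]]
    if (!is.null(m) && any(!is.finite(m)))
      stop(sprintf("non-finite values in %s", nm))
  }
  invisible(data)
}

#' @export
print.ts_data <- function(x, ...) {
  cat(sprintf("<ts_data> %d samples, states: %s", nrow(x$X),
              paste(colnames(x$X), collapse = ", ")))
  if (!is.null(x$Xdot)) cat(" (+derivatives)")
  if (!is.null(x$U)) cat(sprintf(" (+%d controls)", ncol(x$U)))
  cat(sprintf("; t in [%g, %g]\n", x$t[1], x$t[length(x$t)]))
  invisible(x)
}

# All measured channels of a ts_data as one named matrix (states,
# derivatives, controls). The variable lookup table used by term
# evaluation.
ts_variables <- function(data) {
  out <- data$X
  if (!is.null(data$Xdot)) out <- cbind(out, data$Xdot)
  if (!is.null(data$U)) out <- cbind(out, data$U)
  out
}

#' Chronological train/validation split
#'
#' Splits a `ts_data` (or any row-indexed object used here) into a
#' leading training block and trailing validation block. The split is
#' chronological rather than random so that adjacent, strongly
#' correlated samples do not leak between the two sets.
#'
#' @param data a `ts_data` object.
#' @param train_frac fraction of samples (from the start) used for
#'   training; default 0.8.
#' @return list with elements `train` and `test`, both `ts_data`.
#' @export
split_ts_data <- function(data, train_frac = 0.8) {
  stopifnot(inherits(data, "ts_data"), train_frac > 0, train_frac < 1)
  m <- nrow(data$X)
  k <- max(2L, floor(m * train_frac))
  if (k >= m) stop("train fraction leaves no validation samples")
  idx <- list(train = seq_len(k), test = (k + 1L):m)
  lapply(idx, function(i) subset_ts_data(data, i))
}

subset_ts_data <- function(data, i) {
  structure(list(
    t = data$t[i],
    X = data$X[i, , drop = FALSE],
    Xdot = if (!is.null(data$Xdot)) data$Xdot[i, , drop = FALSE],
    U = if (!is.null(data$U)) data$U[i, , drop = FALSE]
  ), class = "ts_data")
}

#' Write / read a trajectory as delimited text
#'
#' Plain tab-separated export with a time column followed by states,
#' derivatives and controls, column names in the header.
#'
#' @param data a `ts_data` object.
#' @param path file path.
#' @export
write_ts_data <- function(data, path) {
  tab <- cbind(t = data$t, ts_variables(data))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ts_data
#' @param states,derivs,controls character vectors naming which columns
#'   of the file hold states, derivatives and controls. Defaults: every
#'   non-time column is a state.
#' @export
read_ts_data <- function(path, states = NULL, derivs = NULL, controls = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"t" %in% names(tab)) stop("no time column 't' in file")
  if (is.null(states)) states <- setdiff(names(tab), c("t", derivs, controls))
  ts_data(tab$t, as.matrix(tab[states]),
          Xdot = if (length(derivs)) as.matrix(tab[derivs]),
          U = if (length(controls)) as.matrix(tab[controls]))
}
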