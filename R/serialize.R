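# Structured-text model serialization: a small key/value format with
# term-label/coefficient lines, lossless for coefficients (17
# significant digits round-trips IEEE doubles).

MODEL_FORMAT_VERSION <- 1L

#' Serialize / load a candidate model as structured text
#'
#' @param model a `candidate_model`.
#' @param path file path.
#' @return `serialize_model` returns `path` invisibly; `load_model`
#'   returns a `candidate_model` (without the fitted-library pieces,
#'   which are data-dependent).
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "candidate_model"))
  nz <- model$coef[model$coef != 0]
  lines <- c(
    sprintf("sindypi_model: %d", MODEL_FORMAT_VERSION),
    sprintf("lhs: %s", model$lhs_label),
    sprintf("lambda: %.17g", model$lambda),
    sprintf("residual: %.17g", model$residual),
    sprintf("sparsity: %d", model$sparsity),
    "coef:",
    sprintf("%s\t%.17g", names(nz), nz)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname serialize_model
#' @param vocabulary optional character vector of known term labels;
#'   any loaded label outside it is an error.
#' @export
load_model <- function(path, vocabulary = NULL) {
  lines <- readLines(path)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(hit) != 1) stop("malformed model file: missing ", key)
    sub(paste0("^", key, ": "), "", hit)
  }
  ver <- as.integer(get_field("sindypi_model"))
  if (!identical(ver, MODEL_FORMAT_VERSION))
    stop(sprintf("model format version mismatch: file %d, supported %d",
                 ver, MODEL_FORMAT_VERSION))
  ci <- match("coef:", lines)
  coef <- numeric(0)
  if (!is.na(ci) && ci < length(lines)) {
    parts <- strsplit(lines[(ci + 1):length(lines)], "\t", fixed = TRUE)
    labs <- vapply(parts, `[[`, "", 1L)
    coef <- stats::setNames(as.numeric(vapply(parts, `[[`, "", 2L)), labs)
  }
  lhs <- get_field("lhs")
  if (!is.null(vocabulary)) {
    unknown <- setdiff(c(lhs, names(coef)), vocabulary)
    if (length(unknown))
      stop("unknown term labels in model file: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(
    lhs_term = NULL, lhs_label = lhs, coef = coef,
    lambda = as.numeric(get_field("lambda")),
    residual = as.numeric(get_field("residual")),
    sparsity = as.integer(get_field("sparsity")),
    empty_model = length(coef) == 0,
    rhs_terms = NULL, spec = NULL, fit = NULL, diagnostics = list()
  ), class = "candidate_model")
}
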