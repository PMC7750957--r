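#' Residue scale objects
#'
#' A residue scale maps each of the 20 standard amino acids to a real value.
#' Scales carry the normalized B-factor sets used as flexibility propensities,
#' the final SWI weights, and the Kyte-Doolittle hydropathy index.
#'
#' @param name Short identifier for the scale.
#' @param values Named numeric vector with exactly one finite value per
#'   standard residue (names from [aa_alphabet()]).
#' @param provenance Free-text citation recording where the values come from.
#' @return An object of class `residue_scale`: a list with elements `name`,
#'   `values` (named numeric, alphabetical residue order) and `provenance`.
#' @export
#' @examples
#' toy <- residue_scale("toy", setNames(seq(0, 1, length.out = 20), aa_alphabet()))
#' toy$values[["A"]]
residue_scale <- function(name, values, provenance = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.list(values)) values <- unlist(values)
  if (!is.numeric(values)) stop("scale values must be numeric")
  keys <- names(values)
  missing <- setdiff(AA20, keys)
  extra <- setdiff(keys, AA20)
  if (length(missing))
    stop("scale '", name, "' is missing residue(s): ", paste(missing, collapse = ", "))
  if (length(extra))
    stop("scale '", name, "' has non-standard key(s): ", paste(extra, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicated residue keys in scale '", name, "'")
  values <- values[AA20]
  if (!all(is.finite(values))) stop("scale '", name, "' contains non-finite values")
  structure(list(name = name, values = values, provenance = provenance),
            class = "residue_scale")
}

#' @export
print.residue_scale <- function(x, ...) {
  cat("<residue_scale> ", x$name, "\n", sep = "")
  if (nzchar(x$provenance)) cat("  ", strtrim(x$provenance, 100), "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

# registry cache; scales are read once from the packaged JSON files
.scale_env <- new.env(parent = emptyenv())

.scale_registry <- function() {
  if (!length(ls(.scale_env))) {
    dir <- system.file("extdata", "scales", package = "swisol")
    for (f in list.files(dir, pattern = "\\.json$", full.names = TRUE)) {
      sc <- load_weights(f)
      assign(sc$name, sc, envir = .scale_env)
    }
  }
  .scale_env
}

#' List the packaged residue scales
#'
#' @return Character vector of registered scale names: the four published
#'   normalized B-factor sets (`"bhaskaran"`, `"karplus_schulz"`, `"smith"`,
#'   `"vihinen"`), the final SWI weights (`"swi_final"`) and Kyte-Doolittle
#'   hydropathy (`"kyte_doolittle"`).
#' @export
list_scales <- function() sort(ls(.scale_registry()))

#' Retrieve a packaged residue scale
#'
#' The registry is read-only: the shipped tables are never modified at run
#' time. User-supplied scales enter through [load_weights()].
#'
#' @param name One of [list_scales()].
#' @return A [residue_scale()].
#' @export
#' @examples
#' w <- get_scale("swi_final")
#' names(which.min(w$values))  # cysteine has the lowest final weight
get_scale <- function(name) {
  reg <- .scale_registry()
  if (!is.character(name) || length(name) != 1L || !exists(name, envir = reg))
    stop("unknown scale '", name, "'; available scales: ",
         paste(sort(ls(reg)), collapse = ", "))
  get(name, envir = reg)
}

#' Read and write residue-weight JSON files
#'
#' Weight files are JSON objects `{"name": ..., "provenance": ...,
#' "values": {"A": ..., ..., "Y": ...}}` with exactly the 20 standard residue
#' keys. [save_weights()] serializes each value as a 17-significant-digit
#' decimal string so doubles round-trip exactly; [load_weights()] accepts
#' numbers or numeric strings.
#'
#' @param path Path to a weight JSON file.
#' @return `load_weights()` returns a [residue_scale()]; `save_weights()`
#'   returns `path` invisibly.
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop("weight file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("name", "values")) {
    if (is.null(obj[[field]])) stop("weight file ", path, " lacks field '", field, "'")
  }
  vals <- unlist(obj$values)
  if (is.character(vals)) {
    parsed <- suppressWarnings(as.numeric(vals))
    if (anyNA(parsed) & !anyNA(vals))
      stop("non-numeric value in weight file ", path)
    vals <- setNames(parsed, names(vals))
  }
  if (!is.numeric(vals)) stop("non-numeric value in weight file ", path)
  residue_scale(obj$name, vals, provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}

#' @param scale A [residue_scale()].
#' @rdname load_weights
#' @export
save_weights <- function(scale, path) {
  stopifnot(inherits(scale, "residue_scale"))
  obj <- list(name = scale$name, provenance = scale$provenance,
              values = lapply(as.list(scale$values), function(v) sprintf("%.17g", v)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
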