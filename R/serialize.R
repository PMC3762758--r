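#' @include AllClasses.R
NULL

.SERIALIZABLE <- c("CSPModel", "ERDClassifier", "CCAReference",
                   "XdawnModel", "BLDAModel", "SelectorModel")

#' Save and load fitted models as JSON
#'
#' Every fitted decoder component (spatial filters, classifier weights,
#' arbiter boundaries, reference definitions) is stored in a documented
#' JSON container: a `class` tag plus one entry per slot, matrices as
#' nested arrays. `readModel` reconstructs the S4 object, so a decoder
#' trained in one session can be reloaded and applied in another.
#'
#' @param x a model object (one of `CSPModel`, `ERDClassifier`,
#'   `CCAReference`, `XdawnModel`, `BLDAModel`, `SelectorModel`).
#' @param path JSON file path.
#' @return `writeModel` invisibly returns `path`; `readModel` returns the
#'   reconstructed object.
#' @export
writeModel <- function(x, path) {
  cls <- as.character(class(x))
  if (!(cls %in% .SERIALIZABLE))
    stop("no JSON serialization for class ", cls)
  slots <- lapply(methods::slotNames(cls), function(s) methods::slot(x, s))
  names(slots) <- methods::slotNames(cls)
  jsonlite::write_json(list(class = cls, slots = slots), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  if (!(cls %in% .SERIALIZABLE))
    stop("unknown model class in ", path, ": ", cls)
  proto <- methods::new(cls)
  args <- list()
  for (s in methods::slotNames(cls)) {
    v <- obj$slots[[s]]
    target <- class(methods::slot(proto, s))[1]
    v <- switch(target,
                matrix = as.matrix(v),
                integer = as.integer(v),
                numeric = as.numeric(v),
                character = as.character(v),
                logical = as.logical(v),
                v)
    if (target == "matrix" && length(dim(v)) != 2) v <- matrix(v, ncol = 1)
    args[[s]] <- v
  }
  do.call(methods::new, c(list(Class = cls), args))
}
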