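#' Read a process network from a model file
#'
#' Reads the versioned JSON schema (YAML accepted as a convenience dialect of
#' the same schema). Top-level fields:
#' \preformatted{
#'   sepgraph_schema: 1
#'   materials: [ {id, kind, description?}, ... ]
#'   units:     [ {id, inputs: {mat: ratio, ...},
#'                     outputs: {mat: ratio, ...}, capacity?}, ... ]
#'   products:  [ids]   # optional; default = materials of kind "product"
#'   raws:      [ids]   # optional; default = materials of kind "raw"
#' }
#' A missing `capacity` means an unbounded unit. The returned network has
#' passed full validation (unique ids, declared references, disjoint
#' products/raws, no raw produced by a unit).
#'
#' @param path File path.
#' @param format `"json"` or `"yaml"`; guessed from the file extension by
#'   default.
#' @return A [process_network()].
#' @export
load_network <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  }
  doc <- tryCatch(
    if (format == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
    else yaml::read_yaml(path),
    error = function(e) {
      stop("cannot parse ", format, " model file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  network_from_list(doc, context = path)
}

network_from_list <- function(doc, context = "model") {
  for (field in c("materials", "units")) {
    if (is.null(doc[[field]])) {
      stop(context, ": missing required field '", field, "'", call. = FALSE)
    }
  }
  mats <- lapply(doc$materials, function(m) {
    if (is.null(m$id)) stop(context, ": material without id", call. = FALSE)
    material(m$id, kind = m$kind %||% "intermediate",
             description = m$description %||% "")
  })
  units <- lapply(doc$units, function(u) {
    if (is.null(u$id)) stop(context, ": unit without id", call. = FALSE)
    operating_unit(u$id, inputs = u$inputs, outputs = u$outputs,
                   capacity = u$capacity %||% Inf)
  })
  process_network(mats, units,
                  products = if (is.null(doc$products)) NULL else unlist(doc$products),
                  raws = if (is.null(doc$raws)) NULL else unlist(doc$raws))
}

network_to_list <- function(network) {
  list(
    sepgraph_schema = 1L,
    materials = lapply(unname(network$materials), function(m) {
      list(id = m$id, kind = m$kind, description = m$description)
    }),
    units = lapply(unname(network$units), function(u) {
      out <- list(id = u$id, inputs = as.list(u$inputs),
                  outputs = as.list(u$outputs))
      if (is.finite(u$capacity)) out$capacity <- u$capacity
      out
    }),
    products = as.list(network$products),
    raws = as.list(network$raws)
  )
}

#' Write a process network to a model file
#'
#' Inverse of [load_network()]; `load_network(write_network(net, f))` returns
#' a network identical to `net` field by field.
#'
#' @param network A [process_network()].
#' @param path Output file path.
#' @param format `"json"` or `"yaml"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("auto", "json", "yaml")) {
  stopifnot(inherits(network, "process_network"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  }
  doc <- network_to_list(network)
  if (format == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
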