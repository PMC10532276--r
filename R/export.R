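#' Convert a network or structure to an igraph object
#'
#' Builds the directed bipartite graph: one vertex per material and per
#' operating unit, arcs material -> unit for inputs and unit -> material for
#' outputs. Vertex attributes: `type` (`"material"`/`"unit"`), `role`
#' (`"raw"`, `"intermediate"`, `"product"`, `"unit"`) and `ratio` arc weights.
#'
#' @param network A [process_network()].
#' @param structure Optional [solution_structure()]; if given, only its units
#'   and incident materials are included.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(network, structure = NULL) {
  stopifnot(inherits(network, "process_network"))
  units <- network$units
  if (!is.null(structure)) units <- units[structure$unit_ids]
  mids <- if (is.null(structure)) material_ids(network) else structure$material_ids
  role <- ifelse(mids %in% network$raws, "raw",
                 ifelse(mids %in% network$products, "product", "intermediate"))
  verts <- data.frame(
    name = c(mids, names(units)),
    type = c(rep("material", length(mids)), rep("unit", length(units))),
    role = c(role, rep("unit", length(units))),
    stringsAsFactors = FALSE)
  edges <- do.call(rbind, c(list(
    data.frame(from = character(0), to = character(0), ratio = numeric(0))),
    lapply(units, function(u) {
      rbind(
        data.frame(from = names(u$inputs), to = u$id, ratio = unname(u$inputs),
                   stringsAsFactors = FALSE),
        data.frame(from = u$id, to = names(u$outputs), ratio = unname(u$outputs),
                   stringsAsFactors = FALSE))
    })))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export a network or structure as DOT or GraphML text
#'
#' Renders the bipartite digraph with distinct node shapes: operating units
#' as boxes; raw materials as triangle-marked circles (inputs from outside
#' the system), intermediates as solid circles, products as double circles —
#' mirroring the usual SEP-graph drawing conventions.
#'
#' @param network A [process_network()].
#' @param structure Optional [solution_structure()] restricting the drawing.
#' @param format `"dot"` or `"graphml"`.
#' @return A character scalar with the graph document.
#' @export
export_graph <- function(network, structure = NULL,
                         format = c("dot", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(network, structure)
    tmp <- tempfile(fileext = ".graphml")
    on.exit(unlink(tmp))
    igraph::write_graph(g, tmp, format = "graphml")
    return(paste(readLines(tmp, warn = FALSE), collapse = "\n"))
  }
  units <- network$units
  mids <- material_ids(network)
  if (!is.null(structure)) {
    units <- units[structure$unit_ids]
    mids <- structure$material_ids
  }
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph sepgraph {", "  rankdir=LR;")
  for (m in mids) {
    shape <- if (m %in% network$products) "doublecircle"
             else if (m %in% network$raws) "invtriangle" else "circle"
    style <- if (!(m %in% network$products) && !(m %in% network$raws))
      ', style=filled, fillcolor=black, fontcolor=white' else ""
    lines <- c(lines, paste0("  ", q(m), " [shape=", shape, style, "];"))
  }
  for (u in names(units)) {
    lines <- c(lines, paste0("  ", q(u), " [shape=box];"))
  }
  for (u in units) {
    for (m in names(u$inputs)) {
      lines <- c(lines, paste0("  ", q(m), " -> ", q(u$id),
                               " [label=", q(format(u$inputs[[m]])), "];"))
    }
    for (m in names(u$outputs)) {
      lines <- c(lines, paste0("  ", q(u$id), " -> ", q(m),
                               " [label=", q(format(u$outputs[[m]])), "];"))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
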