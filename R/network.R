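#' Create a material (M-type node)
#'
#' Materials are the M-type nodes of a SEP-graph: species, population states,
#' resources and ecosystem services. Each material has a `kind`: `"raw"`
#' (enters the system from outside), `"intermediate"` (produced and consumed
#' inside the system) or `"product"` (a terminal output such as a yield or a
#' service level).
#'
#' @param id Non-empty character scalar; unique within a network.
#'   Ids are case-sensitive exact strings.
#' @param kind One of `"raw"`, `"intermediate"`, `"product"`.
#' @param description Optional free-text description.
#' @return An object of class `"sep_material"`.
#' @export
material <- function(id, kind = c("intermediate", "raw", "product"),
                     description = "") {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("material id must be a non-empty character scalar", call. = FALSE)
  }
  structure(list(id = id, kind = kind, description = as.character(description)),
            class = "sep_material")
}

#' Create an operating unit (O-type node)
#'
#' Operating units are the O-type nodes: processes, trophic interactions or
#' interventions. A unit consumes its `inputs` and produces its `outputs` in
#' fixed ratios per unit of operating level, up to `capacity`.
#'
#' @param id Non-empty character scalar; unique within a network.
#' @param inputs Named numeric vector: material id -> flow consumed per unit
#'   operating level. All ratios must be > 0; at least one input.
#' @param outputs Named numeric vector: material id -> flow produced per unit
#'   operating level. All ratios must be > 0; at least one output. Input and
#'   output material sets must be disjoint.
#' @param capacity Non-negative upper bound on the operating level;
#'   `Inf` means unbounded.
#' @return An object of class `"sep_unit"`.
#' @export
operating_unit <- function(id, inputs, outputs, capacity = Inf) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("unit id must be a non-empty character scalar", call. = FALSE)
  }
  inputs <- unlist(inputs)
  outputs <- unlist(outputs)
  for (side in list(inputs, outputs)) {
    if (length(side) == 0L || is.null(names(side)) || any(!nzchar(names(side)))) {
      stop("unit '", id, "': inputs and outputs must be non-empty named vectors",
           call. = FALSE)
    }
  }
  if (anyDuplicated(names(inputs)) || anyDuplicated(names(outputs))) {
    stop("unit '", id, "': duplicated material in inputs or outputs", call. = FALSE)
  }
  if (any(names(inputs) %in% names(outputs))) {
    stop("unit '", id, "': inputs and outputs must be disjoint", call. = FALSE)
  }
  if (any(!is.finite(inputs)) || any(inputs <= 0) ||
      any(is.na(outputs)) || any(outputs <= 0) || any(!is.finite(outputs))) {
    stop("unit '", id, "': all flow ratios must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(capacity) || length(capacity) != 1L || is.na(capacity) ||
      capacity < 0) {
    stop("unit '", id, "': capacity must be a single number >= 0 (Inf allowed)",
         call. = FALSE)
  }
  structure(list(id = id,
                 inputs = inputs[order(names(inputs), method = "radix")],
                 outputs = outputs[order(names(outputs), method = "radix")],
                 capacity = as.numeric(capacity)),
            class = "sep_unit")
}

#' Assemble a process network
#'
#' A process network is the bipartite digraph of materials and operating
#' units. Arcs exist only between a unit and a material (implicitly encoded
#' by each unit's `inputs`/`outputs`). The designated `raws` are external
#' inputs that the environment supplies; `products` are terminal outputs.
#'
#' Validation enforces: unique, declared material references; disjoint
#' products and raws; and that no declared raw material is the output of any
#' unit (raws can only enter the system).
#'
#' @param materials List of [material()] objects (or a single one).
#' @param units List of [operating_unit()] objects.
#' @param products Character vector of product material ids. Defaults to all
#'   materials of kind `"product"`.
#' @param raws Character vector of raw material ids available as external
#'   inputs. Defaults to all materials of kind `"raw"`. A network may declare
#'   fewer raws than it has raw-kind materials (see [gate_network()]).
#' @return An object of class `"process_network"`.
#' @export
process_network <- function(materials, units, products = NULL, raws = NULL) {
  if (inherits(materials, "sep_material")) materials <- list(materials)
  if (inherits(units, "sep_unit")) units <- list(units)
  mids <- vapply(materials, function(m) m$id, character(1))
  if (anyDuplicated(mids)) {
    stop("duplicate material id: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "), call. = FALSE)
  }
  uids <- vapply(units, function(u) u$id, character(1))
  if (anyDuplicated(uids)) {
    stop("duplicate unit id: ",
         paste(unique(uids[duplicated(uids)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(mids, method = "radix")
  materials <- materials[ord]
  mids <- mids[ord]
  ordu <- order(uids, method = "radix")
  units <- units[ordu]
  uids <- uids[ordu]
  names(materials) <- mids
  names(units) <- uids

  kinds <- vapply(materials, function(m) m$kind, character(1))
  if (is.null(products)) products <- mids[kinds == "product"]
  if (is.null(raws)) raws <- mids[kinds == "raw"]
  products <- sort(unique(as.character(products)), method = "radix")
  raws <- sort(unique(as.character(raws)), method = "radix")

  for (u in units) {
    refs <- c(names(u$inputs), names(u$outputs))
    bad <- setdiff(refs, mids)
    if (length(bad)) {
      stop("unit '", u$id, "' references undeclared material: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (length(bad <- setdiff(products, mids))) {
    stop("undeclared product material: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(bad <- setdiff(raws, mids))) {
    stop("undeclared raw material: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(bad <- intersect(products, raws))) {
    stop("products and raws must be disjoint; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw_kind <- mids[kinds == "raw"]
  for (u in units) {
    bad <- intersect(names(u$outputs), raw_kind)
    if (length(bad)) {
      stop("raw material cannot be a unit output (axiom S2): unit '", u$id,
           "' produces ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(materials = materials, units = units,
                 products = products, raws = raws),
            class = "process_network")
}

#' @export
print.process_network <- function(x, ...) {
  cat("<process_network> ", length(x$materials), " materials, ",
      length(x$units), " operating units\n", sep = "")
  cat("  raws available: ", length(x$raws),
      " | products: ", paste(x$products, collapse = ", "), "\n", sep = "")
  invisible(x)
}

material_ids <- function(network) names(network$materials)
unit_ids <- function(network) names(network$units)

#' Restrict the external inputs of a network
#'
#' Scenario gating: returns the same network with only `available_raws`
#' declared as external inputs. Materials and units are unchanged; units that
#' lose input support become structurally infeasible and are removed by
#' [msg()].
#'
#' @param network A [process_network()].
#' @param available_raws Character vector, subset of `network$raws`.
#' @return A [process_network()] with the reduced raw set.
#' @export
gate_network <- function(network, available_raws) {
  stopifnot(inherits(network, "process_network"))
  available_raws <- as.character(available_raws)
  bad <- setdiff(available_raws, network$raws)
  if (length(bad)) {
    stop("available_raws not declared as raws in the network: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  network$raws <- sort(unique(available_raws), method = "radix")
  network
}

# Consumption/production incidence matrices (materials x units).
net_matrices <- function(network) {
  mids <- material_ids(network)
  uids <- unit_ids(network)
  A <- matrix(0, length(mids), length(uids), dimnames = list(mids, uids))
  B <- A
  for (u in network$units) {
    A[names(u$inputs), u$id] <- u$inputs
    B[names(u$outputs), u$id] <- u$outputs
  }
  list(A = A, B = B)
}

# Sub-network induced by a unit subset: keeps incident materials plus any
# declared raw/product that stays incident; used by msg().
induce_subnetwork <- function(network, keep_units) {
  units <- network$units[keep_units]
  inc <- unique(unlist(lapply(units, function(u) c(names(u$inputs), names(u$outputs)))))
  materials <- network$materials[intersect(material_ids(network), inc)]
  process_network(materials, unname(units),
                  products = intersect(network$products, inc),
                  raws = intersect(network$raws, inc))
}

# Empty network (the infeasible-problem result of msg()).
empty_network <- function() {
  structure(list(materials = list(), units = list(),
                 products = character(0), raws = character(0)),
            class = "process_network")
}

#' Number of nodes of the bipartite graph
#'
#' @param network A [process_network()].
#' @return Integer: materials plus operating units.
#' @export
n_nodes <- function(network) length(network$materials) + length(network$units)
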