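#' Maximal structure generation (MSG)
#'
#' Computes the maximal structure: the unique largest sub-network that
#' contains every axiom-consistent solution structure. Implemented as
#' fixed-point pruning; at each pass a unit is deleted when
#' (i) it has no directed path to any product through the remaining network,
#' or (ii) some input material is neither an available raw nor producible by
#' any remaining unit; materials incident to no remaining unit are dropped at
#' the end.
#'
#' If a required product is not producible in the pruned network — in
#' particular when no product is reachable from any raw — the synthesis
#' problem is infeasible and the empty network is returned with a warning.
#'
#' @param network A [process_network()].
#' @param required_products Products that must be attainable (default: none;
#'   products are optional).
#' @param quiet Suppress the infeasibility warning.
#' @return A [process_network()] (possibly empty).
#' @export
msg <- function(network, required_products = character(0), quiet = FALSE) {
  stopifnot(inherits(network, "process_network"))
  required_products <- as.character(required_products)
  infeasible <- function(why) {
    if (!quiet) warning("synthesis problem infeasible: ", why, call. = FALSE)
    empty_network()
  }
  if (length(network$units) == 0L) {
    if (length(required_products)) {
      return(infeasible("network has no operating units"))
    }
    return(induce_subnetwork(network, character(0)))
  }
  M <- net_matrices(network)
  Ain <- M$A > 0
  Bout <- M$B > 0
  raws <- material_ids(network) %in% network$raws
  products <- material_ids(network) %in% network$products
  keep <- rep(TRUE, length(network$units))
  repeat {
    # (ii) input support: every input raw or producible by a remaining unit
    producible <- raws | (rowSums(Bout[, keep, drop = FALSE]) > 0)
    supported <- colSums(Ain & !producible) == 0
    # (i) path to a product within the remaining network
    reach_m <- products
    reach_u <- rep(FALSE, ncol(Ain))
    repeat {
      reach_u <- keep & (colSums(Bout[reach_m, , drop = FALSE]) > 0)
      new_m <- reach_m | (rowSums(Ain[, reach_u, drop = FALSE]) > 0)
      if (all(new_m == reach_m)) break
      reach_m <- new_m
    }
    new_keep <- keep & supported & reach_u
    if (all(new_keep == keep)) break
    keep <- new_keep
  }
  kept_ids <- unit_ids(network)[keep]
  if (!length(kept_ids)) {
    return(infeasible("no product is reachable from any available raw"))
  }
  sub <- induce_subnetwork(network, kept_ids)
  if (length(setdiff(required_products, sub$products))) {
    return(infeasible(paste0("required product(s) not producible: ",
                             paste(setdiff(required_products, sub$products),
                                   collapse = ", "))))
  }
  sub
}
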