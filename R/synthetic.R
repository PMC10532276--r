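#' Specification for a random layered synthesis instance
#'
#' @param n_raws,n_intermediates,n_products Positive material counts.
#' @param n_units Positive unit count; at least `n_products` (every product
#'   needs a producer).
#' @param max_inputs_per_unit,max_outputs_per_unit Arc caps per random unit.
#' @param extra_arc_prob Probability in `[0, 1]` of adding each optional
#'   random unit/arc beyond the planted chain; 0 yields exactly the planted
#'   chain.
#' @param seed Integer seed; instances are fully reproducible.
#' @return A `"generator_spec"`.
#' @export
generator_spec <- function(n_raws = 2, n_intermediates = 3, n_products = 1,
                           n_units = 6, max_inputs_per_unit = 2,
                           max_outputs_per_unit = 2, extra_arc_prob = 0.3,
                           seed = 1L) {
  for (v in list(n_raws = n_raws, n_intermediates = n_intermediates,
                 n_products = n_products, n_units = n_units,
                 max_inputs_per_unit = max_inputs_per_unit,
                 max_outputs_per_unit = max_outputs_per_unit)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v)) {
      stop("generator_spec counts must be positive integers", call. = FALSE)
    }
  }
  if (n_intermediates < 0 || n_products < 1) {
    stop("need at least one product to plant a feasible pathway", call. = FALSE)
  }
  if (n_units < n_products) {
    stop("n_units must be >= n_products (one planted producer per product)",
         call. = FALSE)
  }
  if (!is.numeric(extra_arc_prob) || extra_arc_prob < 0 || extra_arc_prob > 1) {
    stop("extra_arc_prob must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_raws = as.integer(n_raws),
                 n_intermediates = as.integer(n_intermediates),
                 n_products = as.integer(n_products),
                 n_units = as.integer(n_units),
                 max_inputs_per_unit = as.integer(max_inputs_per_unit),
                 max_outputs_per_unit = as.integer(max_outputs_per_unit),
                 extra_arc_prob = extra_arc_prob,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a random layered synthesis instance with a planted pathway
#'
#' Builds a layered bipartite network (raws at layer 0, intermediates at
#' layers 1..k, products on top) containing a planted chain of units that
#' forms an axiom-consistent structure producing every product: raw ->
#' intermediate chain -> each product. Additional random units (each
#' included with probability `extra_arc_prob`, up to `n_units` total) consume
#' materials from strictly lower layers and produce a higher-layer
#' intermediate or product, with optional extra arcs added at the same
#' probability — layering guarantees no raw is ever produced. Unit
#' capacities are drawn uniformly from (0, 1].
#'
#' @param spec A [generator_spec()].
#' @return List with `network` (a [process_network()]) and `planted`
#'   (a [solution_structure()] labelled `"planted"`).
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  raw_ids <- sprintf("R%02d", seq_len(spec$n_raws))
  int_ids <- if (spec$n_intermediates) sprintf("I%02d", seq_len(spec$n_intermediates)) else character(0)
  prod_ids <- sprintf("P%02d", seq_len(spec$n_products))
  layer <- stats::setNames(c(rep(0L, length(raw_ids)), seq_along(int_ids),
                             rep(spec$n_intermediates + 1L, length(prod_ids))),
                           c(raw_ids, int_ids, prod_ids))
  materials <- c(lapply(raw_ids, material, kind = "raw"),
                 lapply(int_ids, material, kind = "intermediate"),
                 lapply(prod_ids, material, kind = "product"))

  units <- list()
  add_unit <- function(id, inputs, outputs) {
    units[[length(units) + 1L]] <<- operating_unit(
      id, inputs, outputs, capacity = stats::runif(1))
  }
  # planted chain through as many intermediates as the unit budget allows
  chain_len <- min(spec$n_intermediates, spec$n_units - spec$n_products)
  u <- 0L
  prev <- raw_ids[1L]
  if (chain_len > 0) {
    for (t in seq_len(chain_len)) {
      u <- u + 1L
      add_unit(sprintf("u%02d", u), stats::setNames(1, prev),
               stats::setNames(1, int_ids[t]))
      prev <- int_ids[t]
    }
  }
  for (p in prod_ids) {
    u <- u + 1L
    add_unit(sprintf("u%02d", u), stats::setNames(1, prev), stats::setNames(1, p))
  }
  planted_ids <- vapply(units, function(x) x$id, character(1))

  # optional random units on top of the planted chain
  n_extra <- spec$n_units - length(units)
  all_ids <- names(layer)
  for (k in seq_len(max(0L, n_extra))) {
    if (stats::runif(1) >= spec$extra_arc_prob) next
    out1 <- sample(c(int_ids, prod_ids), 1L)
    lower <- all_ids[layer < layer[[out1]]]
    ins <- sample(lower, min(length(lower),
                             sample.int(spec$max_inputs_per_unit, 1L)))
    outs <- out1
    upper <- setdiff(all_ids[layer >= layer[[out1]]], c(out1, raw_ids, ins))
    while (length(outs) < spec$max_outputs_per_unit && length(upper) &&
           stats::runif(1) < spec$extra_arc_prob) {
      pick <- sample(upper, 1L)
      outs <- c(outs, pick)
      upper <- setdiff(upper, pick)
    }
    u <- u + 1L
    add_unit(sprintf("u%02d", u),
             stats::setNames(round(stats::runif(length(ins), 0.1, 2), 3), ins),
             stats::setNames(round(stats::runif(length(outs), 0.1, 2), 3), outs))
  }
  net <- process_network(materials, units)
  list(network = net,
       planted = solution_structure(net, planted_ids, label = "planted"))
}
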