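#' Specify a flow-optimisation model over a process network
#'
#' Couples a network with the data the LP needs: unit capacities, the
#' intermediate balance convention, the objective weights on product net
#' flows, and optional required minimum flows (the "production goal" of a
#' synthesis problem — e.g. a pest-control service that must be delivered in
#' full).
#'
#' @param network A [process_network()] (normally a maximal structure).
#' @param capacities Named numeric vector unit id -> capacity override;
#'   defaults to each unit's own capacity.
#' @param balance_mode `"surplus"` (intermediate net flow >= 0; services may
#'   dissipate) or `"exact"` (net flow = 0).
#' @param objective Named numeric vector product id -> weight; defaults to
#'   weight 1 on every product of the network.
#' @param required_flows Named numeric vector product id -> minimum net flow
#'   (default none). Products always have net flow >= 0.
#' @return An object of class `"flow_model"`.
#' @export
flow_model <- function(network, capacities = NULL,
                       balance_mode = c("surplus", "exact"),
                       objective = NULL, required_flows = numeric(0)) {
  stopifnot(inherits(network, "process_network"))
  balance_mode <- match.arg(balance_mode)
  caps <- vapply(network$units, function(u) u$capacity, numeric(1))
  if (!is.null(capacities)) {
    bad <- setdiff(names(capacities), names(caps))
    if (length(bad)) {
      stop("capacity override for nonexistent unit: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    caps[names(capacities)] <- capacities
  }
  if (is.null(objective)) {
    objective <- stats::setNames(rep(1, length(network$products)),
                                 network$products)
  }
  bad <- setdiff(names(objective), material_ids(network))
  if (length(bad)) {
    stop("objective weight on unknown material: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(objective))) stop("objective weights must be finite", call. = FALSE)
  if (length(required_flows)) {
    bad <- setdiff(names(required_flows), network$products)
    if (length(bad)) {
      stop("required flow on non-product material: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(network = network, capacities = caps,
                 balance_mode = balance_mode, objective = objective,
                 required_flows = required_flows),
            class = "flow_model")
}

# Core LP: maximise sum_p w_p * netflow_p over operating levels x of the
# `free` units (all other units fixed at level 0).
#   netflow_m = sum_j (b_mj - a_mj) x_j
#   intermediates: netflow = 0 (exact) or >= 0 (surplus)
#   products: netflow >= max(0, required)
#   0 <= x_j <= cap_j
# Returns list(levels, value, status) with status "optimal"/"infeasible"/
# "unbounded". Solved with the internal two-phase simplex; unbounded units
# get a large sentinel bound and are detected from the solution.
solve_flow_lp <- function(model, free_units) {
  net <- model$network
  BIG <- 1e9
  if (length(free_units) == 0L) {
    req <- model$required_flows
    feas <- !length(req) || all(req <= 0)
    return(list(levels = stats::setNames(numeric(0), character(0)),
                value = 0,
                status = if (feas) "optimal" else "infeasible"))
  }
  M <- net_matrices(net)
  Net <- (M$B - M$A)[, free_units, drop = FALSE]
  mids <- rownames(Net)
  nx <- length(free_units)

  w <- stats::setNames(rep(0, length(mids)), mids)
  w[names(model$objective)] <- model$objective
  obj <- as.numeric(w %*% Net)

  caps <- model$capacities[free_units]
  bounded <- pmin(caps, BIG)

  incident <- rowSums(abs(Net)) > 0
  inter <- incident & !(mids %in% net$raws) & !(mids %in% net$products)
  prods <- incident & (mids %in% net$products)

  A1 <- diag(nx); b1 <- bounded                      # x <= cap
  A2 <- NULL; b2 <- NULL                             # >= rows
  A3 <- NULL; b3 <- NULL                             # == rows
  if (model$balance_mode == "exact") {
    if (any(inter)) { A3 <- Net[inter, , drop = FALSE]; b3 <- rep(0, sum(inter)) }
  } else if (any(inter)) {
    A2 <- Net[inter, , drop = FALSE]; b2 <- rep(0, sum(inter))
  }
  if (any(prods)) {
    req <- stats::setNames(rep(0, sum(prods)), mids[prods])
    hit <- intersect(names(model$required_flows), names(req))
    req[hit] <- pmax(req[hit], model$required_flows[hit])
    A2 <- rbind(A2, Net[prods, , drop = FALSE])
    b2 <- c(b2, req)
  }
  # required flow on a product not incident to the free units: infeasible
  # unless the requirement is <= 0
  off <- setdiff(names(model$required_flows), mids[prods])
  if (length(off) && any(model$required_flows[off] > 0)) {
    return(list(levels = stats::setNames(rep(0, nx), free_units),
                value = -Inf, status = "infeasible"))
  }

  Acon <- rbind(A1, A2, A3)
  dirs <- c(rep("<=", length(b1)),
            rep(">=", length(b2 %||% numeric(0))),
            rep("==", length(b3 %||% numeric(0))))
  s <- lp_simplex(obj, Acon, dirs, c(b1, b2, b3))
  if (s$status != "optimal") {
    return(list(levels = stats::setNames(rep(0, nx), free_units),
                value = if (s$status == "unbounded") Inf else -Inf,
                status = s$status))
  }
  x <- stats::setNames(s$x, free_units)
  if (any(!is.finite(caps)) && any(x > BIG * 0.5 & !is.finite(caps))) {
    return(list(levels = x, value = Inf, status = "unbounded"))
  }
  list(levels = x, value = s$value, status = "optimal")
}

#' Optimal flows on a fixed solution structure
#'
#' Solves the flow LP with the structure's units free in `[0, capacity]` and
#' all other units fixed at zero: maximise the weighted sum of product net
#' flows subject to the balance convention and any required flows.
#'
#' @param structure A [solution_structure()] (or character vector of unit
#'   ids) over the model's network.
#' @param model A [flow_model()].
#' @return A `"flow_result"`: `levels` (operating level per structure unit),
#'   `net_flows` (net flow per structure material), `objective_value`,
#'   `status` (`"optimal"` or `"infeasible"`; an unbounded LP is an error
#'   asking for a capacity bound).
#' @export
optimize_structure <- function(structure, model) {
  stopifnot(inherits(model, "flow_model"))
  if (!inherits(structure, "solution_structure")) {
    structure <- solution_structure(model$network, structure)
  }
  res <- solve_flow_lp(model, structure$unit_ids)
  if (identical(res$status, "unbounded")) {
    stop("flow LP is unbounded: give every unit on an open objective path ",
         "a finite capacity bound", call. = FALSE)
  }
  net_flows <- stats::setNames(rep(0, length(structure$material_ids)),
                               structure$material_ids)
  if (length(structure$unit_ids) && identical(res$status, "optimal")) {
    M <- net_matrices(model$network)
    Net <- (M$B - M$A)[structure$material_ids, structure$unit_ids, drop = FALSE]
    net_flows <- stats::setNames(as.numeric(Net %*% res$levels),
                                 structure$material_ids)
  }
  out <- list(structure = structure,
              levels = res$levels,
              net_flows = net_flows,
              objective_value = if (identical(res$status, "optimal")) res$value else NA_real_,
              status = res$status)
  if (identical(res$status, "infeasible")) {
    out$violated <- model$required_flows
  }
  structure(out, class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat("<flow_result> status: ", x$status, sep = "")
  if (identical(x$status, "optimal")) {
    cat(", objective = ", format(x$objective_value), "\n", sep = "")
    if (length(x$levels)) {
      cat("  levels: ",
          paste(sprintf("%s=%.4g", names(x$levels), x$levels), collapse = ", "),
          "\n", sep = "")
    }
  } else cat("\n")
  invisible(x)
}
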