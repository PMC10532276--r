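#' Relaxation bound for a partial unit decision
#'
#' LP relaxation used by [abb()]: excluded units are fixed at level zero,
#' while included and undecided units are free in `[0, capacity]`. Because a
#' completed structure only ever adds exclusions (more constraints), the
#' relaxation value is an admissible upper bound on the objective of every
#' descendant structure; an infeasible relaxation proves the whole subtree
#' infeasible.
#'
#' @param model A [flow_model()].
#' @param excluded Character vector of unit ids fixed at level zero.
#' @return Numeric bound (`-Inf` when the relaxation is infeasible).
#' @export
abb_bound <- function(model, excluded = character(0)) {
  free <- setdiff(unit_ids(model$network), excluded)
  res <- solve_flow_lp(model, free)
  if (identical(res$status, "unbounded")) return(Inf)
  if (identical(res$status, "infeasible")) return(-Inf)
  res$value
}

#' Accelerated branch-and-bound over solution structures (ABB)
#'
#' Best-first branch-and-bound over unit inclusion/exclusion decisions
#' (units branched in lexicographic id order). At each node the LP
#' relaxation ([abb_bound()]) bounds every completion; subtrees are pruned
#' when the bound cannot beat the current n-th best or when the relaxation
#' is infeasible. Leaves are kept when the decided unit set is
#' axiom-consistent and its LP is feasible.
#'
#' @param model A [flow_model()] whose network is a maximal structure
#'   ([msg()] is applied internally).
#' @param n_best Number of structures to return, ranked by objective value
#'   (descending), ties broken lexicographically by sorted unit-id set.
#'   `Inf` returns every feasible structure.
#' @param required_products Product ids every structure must represent.
#' @param allow_null Admit the empty structure (only with no required
#'   products).
#' @return A list of class `"abb_ranking"`; each element has `$structure`
#'   (a [solution_structure()]) and `$flow` (a `"flow_result"`). Attributes
#'   `nodes_expanded` and `lp_solves` carry search statistics.
#' @export
abb <- function(model, n_best = 1, required_products = character(0),
                allow_null = FALSE) {
  stopifnot(inherits(model, "flow_model"))
  if (!is.numeric(n_best) || length(n_best) != 1L || is.na(n_best) || n_best < 1) {
    stop("n_best must be a number >= 1 (Inf for all structures)", call. = FALSE)
  }
  required_products <- sort(unique(as.character(required_products)), method = "radix")
  net0 <- model$network
  net <- suppressWarnings(msg(net0, required_products, quiet = TRUE))
  null_ok <- allow_null && length(required_products) == 0L

  candidates <- list()
  lp_solves <- 0L
  nodes <- 0L

  if (length(net$units)) {
    sub_model <- flow_model(net, capacities = model$capacities[unit_ids(net)],
                            balance_mode = model$balance_mode,
                            objective = model$objective[names(model$objective) %in% material_ids(net)],
                            required_flows = model$required_flows)
    uids <- unit_ids(net)
    n <- length(uids)
    M <- net_matrices(net)
    Ain <- M$A > 0
    Bout <- M$B > 0
    raws <- material_ids(net) %in% net$raws
    prods <- material_ids(net) %in% net$products
    req_i <- match(required_products, material_ids(net))
    use_bounds <- is.finite(n_best) || length(model$required_flows) > 0

    take_leaf <- function(sel) {
      if (length(sel) == 0L && !null_ok) return(NULL)
      if (!axioms_ok_fast(Ain, Bout, raws, prods, req_i, sel)) return(NULL)
      fr <- optimize_structure(solution_structure(net0, uids[sel]), sub_model)
      lp_solves <<- lp_solves + 1L
      if (!identical(fr$status, "optimal")) return(NULL)
      candidates[[length(candidates) + 1L]] <<- list(structure = fr$structure,
                                                     flow = fr)
      invisible(NULL)
    }

    if (!use_bounds) {
      # Without a ranking cutoff or a feasibility requirement no subtree can
      # be pruned; the search degenerates to exhaustive leaf enumeration.
      if (n > 20L) stop("abb with n_best = Inf needs <= 20 units", call. = FALSE)
      for (mask in 0:(2^n - 1)) {
        nodes <- nodes + 1L
        take_leaf(which(bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1L)) > 0))
      }
    } else {
      # Best-first queue of partial decisions; each node: depth, included,
      # excluded, bound. Deterministic order: bound desc, then insertion id.
      queue <- list(list(depth = 0L, inc = integer(0), exc = integer(0),
                         bound = Inf, id = 0L))
      next_id <- 1L
      worst_kept <- -Inf
      pop_best <- function() {
        bounds <- vapply(queue, function(nd) nd$bound, numeric(1))
        ids <- vapply(queue, function(nd) nd$id, numeric(1))
        i <- order(-bounds, ids)[1L]
        nd <- queue[[i]]
        queue[[i]] <<- NULL
        nd
      }
      while (length(queue)) {
        nd <- pop_best()
        nodes <- nodes + 1L
        if (length(candidates) >= n_best && nd$bound < worst_kept - 1e-9) next
        if (nd$depth == n) {
          n_before <- length(candidates)
          take_leaf(nd$inc)
          if (length(candidates) > n_before && length(candidates) >= n_best) {
            objs <- sort(vapply(candidates, function(cc) cc$flow$objective_value,
                                numeric(1)), decreasing = TRUE)
            worst_kept <- objs[n_best]
          }
          next
        }
        j <- nd$depth + 1L
        for (decision in c("in", "out")) {
          inc <- nd$inc; exc <- nd$exc
          if (decision == "in") {
            inc <- c(inc, j)
            bound <- nd$bound    # exclusions unchanged: parent bound still tight
          } else {
            exc <- c(exc, j)
            bound <- abb_bound(sub_model, uids[exc])
            lp_solves <- lp_solves + 1L
          }
          if (bound == -Inf) next
          if (length(candidates) >= n_best && bound < worst_kept - 1e-9) next
          queue[[length(queue) + 1L]] <- list(depth = j, inc = inc, exc = exc,
                                              bound = bound, id = next_id)
          next_id <- next_id + 1L
        }
      }
    }
  } else if (null_ok) {
    fr <- optimize_structure(solution_structure(net0), model)
    if (identical(fr$status, "optimal")) {
      candidates <- list(list(structure = fr$structure, flow = fr))
    }
  }

  candidates <- rank_flow_results(candidates)
  if (is.finite(n_best) && length(candidates) > n_best) {
    candidates <- candidates[seq_len(n_best)]
  }
  structure(candidates, class = "abb_ranking",
            nodes_expanded = nodes, lp_solves = lp_solves)
}

# Deterministic ranking shared with the exhaustive oracle in the test suite:
# objective value (rounded to 1e-9) descending, then lexicographic unit-id
# set ascending.
rank_flow_results <- function(pairs) {
  if (!length(pairs)) return(pairs)
  objs <- round(vapply(pairs, function(p) p$flow$objective_value, numeric(1)), 9)
  keys <- vapply(pairs, function(p) structure_key(p$structure$unit_ids), character(1))
  ki <- match(keys, sort(unique(keys), method = "radix"))  # locale-free order
  pairs[order(-objs, ki)]
}

#' @export
print.abb_ranking <- function(x, ...) {
  cat("<abb_ranking> ", length(x), " structure(s); ",
      attr(x, "nodes_expanded"), " nodes expanded, ",
      attr(x, "lp_solves"), " LP solves\n", sep = "")
  for (i in seq_along(x)) {
    cat(sprintf("  %2d. obj = %-10.6g {%s}\n", i, x[[i]]$flow$objective_value,
                paste(x[[i]]$structure$unit_ids, collapse = ", ")))
  }
  invisible(x)
}
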