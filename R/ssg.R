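#' Solution structure generation (SSG)
#'
#' Enumerates every axiom-consistent solution structure of a maximal
#' structure by recursive decision mapping: a frontier of materials awaiting
#' production is maintained; for the next material (lexicographic id order)
#' the algorithm branches over every admissible nonempty subset of its
#' candidate producer units (binary-counter order), the producers left out
#' being banned for the rest of the branch; input requirements of newly
#' included units are closed over; dead branches (a needed non-raw material
#' with no admissible producer) are pruned.
#'
#' Products are optional: with `required_products` empty the enumeration
#' runs over every subset of achievable products, and the null structure is
#' included when `allow_null` is set. Structures are deduplicated by unit-id
#' set and returned in deterministic lexicographic order.
#'
#' @param maximal A [process_network()], normally an [msg()] output (msg is
#'   applied internally, making the operation idempotent on maximal inputs).
#' @param required_products Character vector of product ids each structure
#'   must represent (axiom S1). Default: none.
#' @param allow_null Include the empty (null) structure when no product is
#'   required. Default `FALSE`.
#' @return A `"structure_set"`: list of [solution_structure()] objects,
#'   ordered lexicographically by sorted unit ids.
#' @export
ssg <- function(maximal, required_products = character(0), allow_null = FALSE) {
  stopifnot(inherits(maximal, "process_network"))
  required_products <- sort(unique(as.character(required_products)), method = "radix")
  net <- suppressWarnings(msg(maximal, required_products, quiet = TRUE))
  null_ok <- allow_null && length(required_products) == 0L
  if (length(net$units) == 0L) {
    out <- if (null_ok) list(solution_structure(maximal)) else list()
    return(structure_set(out))
  }
  achievable <- net$products
  if (length(setdiff(required_products, achievable))) {
    return(structure_set(if (null_ok) list(solution_structure(maximal)) else list()))
  }

  M <- net_matrices(net)
  Ain <- M$A > 0
  Bout <- M$B > 0
  mids <- material_ids(net)
  uids <- unit_ids(net)
  raws <- mids %in% net$raws
  prods_of <- lapply(seq_along(mids), function(i) which(Bout[i, ]))  # producers
  names(prods_of) <- mids

  found <- new.env(parent = emptyenv())

  # Decision mapping for one target product set S (material indices).
  solve_for <- function(S_idx) {
    n_u <- length(uids)
    recurse <- function(included, excluded, queue, processed) {
      if (length(queue) == 0L) {
        key <- structure_key(uids[sort(included)])
        if (is.null(found[[key]])) found[[key]] <- sort(included)
        return(invisible(NULL))
      }
      m <- queue[1L]           # smallest pending material index (lexicographic)
      queue <- queue[-1L]
      processed <- c(processed, m)
      cands <- prods_of[[m]]
      fixed_in <- intersect(cands, included)    # already produce m; cannot be undone
      free <- setdiff(setdiff(cands, fixed_in), excluded)
      # choose C with fixed_in <= C <= fixed_in + free, C nonempty
      n_free <- length(free)
      for (mask in 0:(2^n_free - 1L)) {
        pick <- if (n_free) free[bitwAnd(mask, bitwShiftL(1L, seq_len(n_free) - 1L)) > 0] else integer(0)
        C <- c(fixed_in, pick)
        if (length(C) == 0L) next
        new_units <- setdiff(C, included)
        new_excl <- c(excluded, setdiff(free, pick))
        new_inc <- c(included, new_units)
        # close over inputs of the newly included units
        need <- integer(0)
        for (j in new_units) {
          for (mi in which(Ain[, j])) {
            if (raws[mi] || mi %in% processed || mi %in% queue || mi %in% need) next
            need <- c(need, mi)
          }
        }
        recurse(new_inc, new_excl, sort(unique(c(queue, need))), processed)
      }
      invisible(NULL)
    }
    recurse(integer(0), integer(0), sort(S_idx), integer(0))
  }

  opt_idx <- match(setdiff(achievable, required_products), mids)
  req_idx <- match(required_products, mids)
  n_opt <- length(opt_idx)
  for (mask in 0:(2^n_opt - 1L)) {
    extra <- if (n_opt) opt_idx[bitwAnd(mask, bitwShiftL(1L, seq_len(n_opt) - 1L)) > 0] else integer(0)
    S_idx <- c(req_idx, extra)
    if (length(S_idx) == 0L) next   # null handled separately
    solve_for(S_idx)
  }

  # Safety filter: every emitted structure must pass the full axiom check.
  raws_l <- raws
  prods_l <- mids %in% net$products
  req_i <- match(required_products, mids)
  keys <- ls(found)
  sets <- lapply(keys, function(k) found[[k]])
  ok <- vapply(sets, function(sel) {
    axioms_ok_fast(Ain, Bout, raws_l, prods_l, req_i, sel)
  }, logical(1))
  sets <- sets[ok]
  out <- lapply(sets, function(sel) solution_structure(maximal, uids[sel]))
  if (null_ok) out <- c(out, list(solution_structure(maximal)))
  structure_set(out)
}

#' Construct an ordered, duplicate-free structure set
#'
#' @param structures List of [solution_structure()] objects.
#' @return A `"structure_set"` ordered lexicographically by sorted unit ids
#'   (the null structure, if present, first).
#' @export
structure_set <- function(structures = list()) {
  keys <- vapply(structures, function(s) structure_key(s$unit_ids), character(1))
  keep <- !duplicated(keys)
  structures <- structures[keep]
  keys <- keys[keep]
  structures <- structures[order(keys, method = "radix")]
  structure(structures, class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> ", length(x), " solution structure(s)\n", sep = "")
  for (i in seq_along(x)) {
    s <- x[[i]]
    lab <- if (!is.null(s$label)) paste0(s$label, ": ") else ""
    cat(sprintf("  %2d. %s{%s}\n", i, lab,
                paste(s$unit_ids, collapse = ", ")))
  }
  invisible(x)
}

#' Brute-force enumeration of solution structures
#'
#' Independent oracle for [ssg()] and [msg()]: enumerates all `2^n` unit
#' subsets and keeps exactly those with an empty [check_axioms()] violation
#' list. Refuses networks with more than 20 units.
#'
#' @inheritParams ssg
#' @param network A [process_network()].
#' @return A `"structure_set"`.
#' @export
brute_force_structures <- function(network, required_products = character(0),
                                   allow_null = FALSE) {
  stopifnot(inherits(network, "process_network"))
  n <- length(network$units)
  if (n > 20L) {
    stop("brute_force_structures refuses networks with more than 20 units (got ",
         n, ")", call. = FALSE)
  }
  required_products <- as.character(required_products)
  M <- net_matrices(network)
  Ain <- M$A > 0
  Bout <- M$B > 0
  raws <- material_ids(network) %in% network$raws
  prods <- material_ids(network) %in% network$products
  req <- match(required_products, material_ids(network))
  uids <- unit_ids(network)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1L)) > 0)
    if (length(sel) == 0L && !allow_null) next
    if (axioms_ok_fast(Ain, Bout, raws, prods, req, sel)) {
      out[[length(out) + 1L]] <- solution_structure(network, uids[sel])
    }
  }
  structure_set(out)
}

#' Union of the unit sets of a structure set
#' @param structures A `"structure_set"`.
#' @return Sorted character vector of unit ids.
#' @export
structure_union <- function(structures) {
  sort(unique(unlist(lapply(structures, function(s) s$unit_ids))) %||% character(0),
       method = "radix")
}
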