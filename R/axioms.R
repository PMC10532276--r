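#' Create a solution structure
#'
#' A solution structure is a sub-network identified by a subset of operating
#' units; its materials are exactly the materials incident to those units
#' (axiom S5 holds by construction). The empty unit set is the legal null
#' structure.
#'
#' @param network A [process_network()].
#' @param unit_ids Character vector of unit ids (possibly empty).
#' @param label Optional label, e.g. `"SS3"`.
#' @return An object of class `"solution_structure"` with fields `unit_ids`,
#'   `material_ids` (both sorted) and `label`.
#' @export
solution_structure <- function(network, unit_ids = character(0), label = NULL) {
  stopifnot(inherits(network, "process_network"))
  unit_ids <- sort(unique(as.character(unit_ids)), method = "radix")
  unknown <- setdiff(unit_ids, names(network$units))
  if (length(unknown)) {
    stop("unknown unit id in structure: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mids <- unique(unlist(lapply(network$units[unit_ids], function(u) {
    c(names(u$inputs), names(u$outputs))
  })))
  structure(list(unit_ids = unit_ids,
                 material_ids = sort(as.character(mids %||% character(0)),
                                     method = "radix"),
                 label = label),
            class = "solution_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.solution_structure <- function(x, ...) {
  lab <- if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  if (length(x$unit_ids) == 0L) {
    cat("<solution_structure>", lab, " null structure (no units)\n", sep = "")
  } else {
    cat("<solution_structure>", lab, " ", length(x$unit_ids), " units: ",
        paste(x$unit_ids, collapse = ", "), "\n  ",
        length(x$material_ids), " incident materials\n", sep = "")
  }
  invisible(x)
}

structure_key <- function(unit_ids) paste(unit_ids, collapse = "\x01")

#' Check the five structural axioms on a candidate structure
#'
#' Evaluates the process-network-synthesis axioms S1-S5 for `structure`
#' within `network`:
#' \describe{
#'   \item{S1}{every required product is represented in the structure;}
#'   \item{S2}{a material in the structure is an external input if and only
#'     if it is not produced by any unit of the structure (so a declared raw
#'     must not be produced, and every consumed non-raw material needs a
#'     producer inside the structure);}
#'   \item{S3}{every unit of the structure is defined in the network
#'     (an unknown unit id is an error, not a violation);}
#'   \item{S4}{every unit has a directed path, within the structure, to some
#'     product of the network;}
#'   \item{S5}{every material of the structure is an input to or output from
#'     at least one of its units (holds by construction of
#'     [solution_structure()]; checked when explicit `material_ids` are
#'     supplied).}
#' }
#'
#' Products are optional by default: S1 is evaluated against the caller's
#' `required_products` set, which defaults to none, so the null structure is
#' vacuously consistent when nothing is required.
#'
#' @param network A [process_network()].
#' @param structure A [solution_structure()] or a character vector of unit ids.
#' @param required_products Character vector of product ids that must be
#'   represented (default: none).
#' @return A data frame of violations with columns `axiom`, `node`,
#'   `message`; zero rows iff the structure is axiom-consistent.
#' @export
check_axioms <- function(network, structure, required_products = character(0)) {
  stopifnot(inherits(network, "process_network"))
  if (!inherits(structure, "solution_structure")) {
    structure <- solution_structure(network, structure)
  } else {
    unknown <- setdiff(structure$unit_ids, names(network$units))
    if (length(unknown)) {
      stop("unknown unit id in structure: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  M <- net_matrices(network)
  v <- axiom_violations_fast(M$A > 0, M$B > 0,
                             raws = material_ids(network) %in% network$raws,
                             products = material_ids(network) %in% network$products,
                             required = match(as.character(required_products),
                                              material_ids(network)),
                             required_ids = as.character(required_products),
                             unit_sel = match(structure$unit_ids,
                                              unit_ids(network)))
  # S5: only checkable against an explicitly carried material set
  expected <- solution_structure(network, structure$unit_ids)$material_ids
  extra <- setdiff(structure$material_ids, expected)
  miss <- setdiff(expected, structure$material_ids)
  for (m in c(extra, miss)) {
    v <- rbind(v, data.frame(axiom = "S5", node = m,
                             message = "material set does not match the materials incident to the structure's units",
                             stringsAsFactors = FALSE))
  }
  rownames(v) <- NULL
  v
}

# Fast axiom evaluation over logical incidence matrices.
# Ain/Bout: materials x units logical matrices; unit_sel: integer column
# indices of the candidate structure; required: row indices of required
# products (NA for ids absent from the network).
axiom_violations_fast <- function(Ain, Bout, raws, products, required,
                                  required_ids, unit_sel) {
  mids <- rownames(Ain)
  uids <- colnames(Ain)
  out <- data.frame(axiom = character(0), node = character(0),
                    message = character(0), stringsAsFactors = FALSE)
  add <- function(axiom, node, msg) {
    rbind(out, data.frame(axiom = axiom, node = node, message = msg,
                          stringsAsFactors = FALSE))
  }
  if (length(unit_sel) == 0L) {
    for (i in seq_along(required)) {
      out <- add("S1", required_ids[i], "required product absent from the (null) structure")
    }
    return(out)
  }
  Ain_s <- Ain[, unit_sel, drop = FALSE]
  Bout_s <- Bout[, unit_sel, drop = FALSE]
  consumed <- rowSums(Ain_s) > 0
  produced <- rowSums(Bout_s) > 0
  incident <- consumed | produced

  # S1: required products represented
  for (i in seq_along(required)) {
    if (is.na(required[i]) || !incident[required[i]]) {
      out <- add("S1", required_ids[i], "required product absent from the structure")
    }
  }
  # S2: raw iff not produced within the structure
  bad_raw <- which(raws & produced)
  for (i in bad_raw) {
    out <- add("S2", mids[i], "declared raw material is produced inside the structure")
  }
  orphan <- which(!raws & consumed & !produced)
  for (i in orphan) {
    out <- add("S2", mids[i],
               "non-raw input is consumed but produced by no unit of the structure")
  }
  # S4: every unit reaches a product of the network within the structure
  reach_m <- products & incident     # materials from which a product is reachable
  reach_u <- rep(FALSE, length(unit_sel))
  repeat {
    reach_u <- colSums(Bout_s[reach_m, , drop = FALSE]) > 0
    new_m <- reach_m | (rowSums(Ain_s[, reach_u, drop = FALSE]) > 0)
    if (all(new_m == reach_m)) break
    reach_m <- new_m
  }
  for (j in which(!reach_u)) {
    out <- add("S4", uids[unit_sel[j]], "unit has no directed path to any product")
  }
  out
}

# TRUE iff the unit subset (integer columns) is axiom-consistent; fast path
# shared by the enumeration algorithms.
axioms_ok_fast <- function(Ain, Bout, raws, products, required, unit_sel) {
  if (length(unit_sel) == 0L) return(length(required) == 0L)
  Ain_s <- Ain[, unit_sel, drop = FALSE]
  Bout_s <- Bout[, unit_sel, drop = FALSE]
  consumed <- rowSums(Ain_s) > 0
  produced <- rowSums(Bout_s) > 0
  incident <- consumed | produced
  if (length(required) && (anyNA(required) || !all(incident[required]))) return(FALSE)
  if (any(raws & produced)) return(FALSE)
  if (any(!raws & consumed & !produced)) return(FALSE)
  # S4 via reverse reachability from products
  reach_m <- products & incident
  reach_u <- rep(FALSE, length(unit_sel))
  repeat {
    new_u <- (colSums(Bout_s[reach_m, , drop = FALSE]) > 0)
    if (all(new_u == reach_u)) break
    reach_u <- new_u
    reach_m <- (products & incident) | (rowSums(Ain_s[, reach_u, drop = FALSE]) > 0)
  }
  all(reach_u)
}
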