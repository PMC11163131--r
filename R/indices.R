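#' The nine degree-based topological index identifiers
#'
#' In reference-table column order: first Zagreb (M1), second Zagreb (M2),
#' modified second Zagreb (mM2), harmonic (H), forgotten (F), hyper-Zagreb
#' (HM), symmetric division (SD), first revised Randic (FRR), second revised
#' Randic (SRR).
#'
#' @return character vector of the nine identifiers.
#' @export
topo_indices <- function() {
  c("M1", "M2", "mM2", "H", "F", "HM", "SD", "FRR", "SRR")
}

#' Long display names for the index identifiers
#' @return named character vector.
#' @export
topo_index_names <- function() {
  c(M1 = "first Zagreb index", M2 = "second Zagreb index",
    mM2 = "modified second Zagreb index", H = "harmonic index",
    F = "forgotten index", HM = "hyper-Zagreb index",
    SD = "symmetric division index", FRR = "first revised Randic index",
    SRR = "second revised Randic index")
}

#' Per-edge contribution of a degree-based topological index
#'
#' Every index here is an edge-additive invariant: the index of a graph is
#' the sum over its edges of a symmetric function of the two endpoint
#' degrees. This function evaluates that per-edge weight.
#'
#' The first revised Randic index has two variants. \code{as_stated} is the
#' definition as written, \eqn{1/(ab + a + b)}. \code{as_tabulated} is
#' \eqn{1/\sqrt{2(ab + a + b)}}, the form that reconciles the published
#' reference values of the benchmark drug set (see the package vignette);
#' the two disagree and reports always state which was used.
#'
#' @param index one of \code{topo_indices()}.
#' @param low,high endpoint degrees (vectors are recycled); the pair is
#'   unordered, so arguments are canonicalised internally.
#' @param frr_variant \code{"as_stated"} or \code{"as_tabulated"}; only
#'   consulted when \code{index == "FRR"}.
#' @return numeric vector of per-edge weights, always positive.
#' @examples
#' edge_weight("SRR", 2, 3)          # (3-2+1)/sqrt(6)
#' edge_weight("HM", 2, 3) - edge_weight("F", 2, 3)  # equals 2*M2 weight
#' @export
edge_weight <- function(index, low, high,
                        frr_variant = c("as_stated", "as_tabulated")) {
  index <- match.arg(index, topo_indices())
  frr_variant <- match.arg(frr_variant)
  a <- pmin(low, high); b <- pmax(low, high)
  if (any(a < 1)) stop_invalid("vertex degrees must be >= 1")
  switch(index,
    M1  = a + b,
    M2  = a * b,
    mM2 = 1 / (a * b),
    H   = 2 / (a + b),
    F   = a^2 + b^2,
    HM  = (a + b)^2,
    SD  = a / b + b / a,
    FRR = if (frr_variant == "as_stated") 1 / (a * b + a + b)
          else 1 / sqrt(2 * (a * b + a + b)),
    SRR = (b - a + 1) / sqrt(a * b)
  )
}

#' Evaluate a topological index from an edge partition
#'
#' Fast path: the index is the count-weighted sum of the per-edge weights of
#' the partition's degree-pair classes. M1, M2, F and HM are integer-valued
#' on every graph.
#'
#' @param partition an \code{edge_partition} (see
#'   \code{\link{edge_partition}}, \code{\link{as_edge_partition}}).
#' @param index one of \code{topo_indices()}.
#' @inheritParams edge_weight
#' @return scalar index value.
#' @examples
#' naph <- as_edge_partition(
#'   data.frame(low = c(2, 2, 3), high = c(2, 3, 3), count = c(8, 8, 2)))
#' index_from_partition(naph, "M1")   # 84
#' @export
index_from_partition <- function(partition, index,
                                 frr_variant = c("as_stated", "as_tabulated")) {
  stopifnot(inherits(partition, "edge_partition"))
  w <- edge_weight(index, partition$low, partition$high,
                   frr_variant = match.arg(frr_variant))
  as.numeric(sum(partition$count * w))
}

#' Evaluate a topological index by direct edge enumeration
#'
#' Oracle path: sums the per-edge weight over every edge of the graph
#' without grouping. Always equals the partition path to floating-point
#' accuracy; kept separate so the two routes can cross-check each other.
#'
#' @param g a \code{mol_graph}.
#' @inheritParams index_from_partition
#' @return scalar index value.
#' @export
index_brute_force <- function(g, index,
                              frr_variant = c("as_stated", "as_tabulated")) {
  stopifnot(inherits(g, "mol_graph"))
  deg <- igraph::degree(g$graph)
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  w <- edge_weight(index, deg[el[, 1]], deg[el[, 2]],
                   frr_variant = match.arg(frr_variant))
  as.numeric(sum(w))
}

#' Compute all nine topological indices of a structure
#'
#' @param g a \code{mol_graph}.
#' @inheritParams edge_weight
#' @return named numeric vector over \code{topo_indices()}, computed via the
#'   edge-partition path; attribute \code{"name"} carries the structure
#'   label and \code{"frr_variant"} the FRR variant used.
#' @examples
#' g <- mol_graph_from_edges(cbind("a", "b"), "ethane")
#' compute_indices(g)
#' @export
compute_indices <- function(g, frr_variant = c("as_stated", "as_tabulated")) {
  frr_variant <- match.arg(frr_variant)
  part <- edge_partition(g)
  vals <- vapply(topo_indices(), function(i)
    index_from_partition(part, i, frr_variant = frr_variant), numeric(1))
  attr(vals, "name") <- g$name
  attr(vals, "frr_variant") <- frr_variant
  vals
}

#' Descriptor table for a list of structures
#'
#' @param graphs list of \code{mol_graph} objects.
#' @inheritParams edge_weight
#' @return data.frame with a \code{name} column followed by the nine index
#'   columns in reference-table order.
#' @export
compute_index_table <- function(graphs,
                                frr_variant = c("as_stated", "as_tabulated")) {
  frr_variant <- match.arg(frr_variant)
  rows <- lapply(graphs, function(g) {
    v <- compute_indices(g, frr_variant = frr_variant)
    cbind(data.frame(name = g$name, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "frr_variant") <- frr_variant
  out
}
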