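#' @importFrom igraph graph_from_edgelist graph_from_data_frame degree components vcount ecount
#'   as_edgelist V simplify is_simple add_edges make_empty_graph
NULL

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("topoqspr_invalid_structure", "error")))
}

stop_disconnected <- function(msg) {
  stop(errorCondition(msg, class = c("topoqspr_disconnected_structure", "error")))
}

new_mol_graph <- function(ig, name) {
  structure(list(name = name, graph = ig), class = "mol_graph")
}

validate_mol_graph <- function(g, require_connected = TRUE) {
  ig <- g$graph
  el <- igraph::as_edgelist(ig, names = TRUE)
  if (any(el[, 1] == el[, 2])) {
    stop_invalid(sprintf("structure '%s' contains a self-loop", g$name))
  }
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  if (anyDuplicated(key)) {
    stop_invalid(sprintf("structure '%s' contains a duplicate edge", g$name))
  }
  if (igraph::vcount(ig) < 2L || igraph::ecount(ig) < 1L) {
    stop_invalid(sprintf("structure '%s' must have at least 2 atoms and 1 bond",
                         g$name))
  }
  if (require_connected && igraph::components(ig)$no != 1L) {
    stop_disconnected(sprintf(
      "structure '%s' has %d components; pass strip_salts = TRUE to keep the largest",
      g$name, igraph::components(ig)$no))
  }
  g
}

#' Build a molecular graph from an explicit heavy-atom edge list
#'
#' Constructs a simple, connected, hydrogen-suppressed molecular graph from
#' unordered vertex pairs. Vertex identifiers are opaque labels; every index
#' computed downstream depends only on the unlabeled graph.
#'
#' @param pairs two-column matrix or data.frame of vertex identifiers, one
#'   bond per row.
#' @param name text label for the structure.
#' @return an object of class \code{mol_graph}.
#' @examples
#' g <- mol_graph_from_edges(cbind(c("a", "b"), c("b", "c")), "propane")
#' degree_map(g)
#' @export
mol_graph_from_edges <- function(pairs, name = "structure") {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2, byrow = TRUE)
  if (nrow(pairs) < 1L) stop_invalid("edge list is empty")
  storage.mode(pairs) <- "character"
  ig <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  validate_mol_graph(new_mol_graph(ig, name))
}

#' Build a hydrogen-suppressed molecular graph from a SMILES string
#'
#' Parses the SMILES with ChemmineR/Open Babel and keeps the heavy-atom
#' skeleton: hydrogens never appear as vertices and every bond (single,
#' double, triple, or aromatic) contributes exactly one edge. Stereochemistry
#' and formal charges are accepted and discarded; only the 2-D connectivity
#' is retained.
#'
#' @param smiles SMILES string with at least two heavy atoms.
#' @param name text label; defaults to the SMILES itself.
#' @param strip_salts if \code{TRUE}, keep only the largest connected
#'   component of a multi-component input (e.g. a salt); otherwise a
#'   multi-component SMILES is an error.
#' @return an object of class \code{mol_graph}.
#' @examples
#' \donttest{
#' g <- mol_graph_from_smiles("c1ccccc1", "benzene")
#' edge_partition(g)
#' }
#' @export
mol_graph_from_smiles <- function(smiles, name = smiles, strip_salts = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop_invalid(
      sprintf("cannot parse SMILES for '%s': %s", name, conditionMessage(e)))
  )
  sd <- sdf[[1]]
  ab <- ChemmineR::atomblock(sd)
  bb <- ChemmineR::bondblock(sd)
  if (is.null(ab) || nrow(ab) < 2L || is.null(bb) || nrow(bb) < 1L) {
    stop_invalid(sprintf("SMILES for '%s' has fewer than 2 heavy atoms or no bonds",
                         name))
  }
  sym <- gsub("_.*$", "", rownames(ab))
  if (any(sym %in% c("H", "D", "T"))) {
    keep <- which(!(sym %in% c("H", "D", "T")))   # explicit hydrogens, if any
  } else {
    keep <- seq_len(nrow(ab))
  }
  vid <- paste0(sym, "_", seq_len(nrow(ab)))
  e1 <- as.integer(bb[, 1]); e2 <- as.integer(bb[, 2])
  sel <- e1 %in% keep & e2 %in% keep
  if (!any(sel)) stop_invalid(sprintf("SMILES for '%s' has no heavy-atom bonds", name))
  # build over every heavy atom so isolated counter-ions still count as a
  # component (they must trigger the disconnected error / salt stripping)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = vid[e1[sel]], to = vid[e2[sel]]),
    directed = FALSE,
    vertices = data.frame(name = vid[keep]))
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    if (!strip_salts) {
      stop_disconnected(sprintf(
        "SMILES for '%s' encodes %d disconnected components; set strip_salts = TRUE",
        name, comp$no))
    }
    main <- which.max(comp$csize)
    ig <- igraph::induced_subgraph(ig, which(comp$membership == main))
  }
  validate_mol_graph(new_mol_graph(ig, name))
}

#' Vertex degrees of a molecular graph
#'
#' @param g a \code{mol_graph}.
#' @return named integer vector mapping each vertex to its degree (number of
#'   distinct heavy-atom neighbours). The degrees always satisfy the
#'   handshake identity: their sum equals twice the number of edges.
#' @export
degree_map <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  igraph::degree(g$graph)
}

#' Number of edges of a molecular graph
#' @param g a \code{mol_graph}.
#' @return integer edge count.
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  igraph::ecount(g$graph)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d vertices, %d edges, degrees %d..%d\n",
              x$name, igraph::vcount(x$graph), igraph::ecount(x$graph),
              min(igraph::degree(x$graph)), max(igraph::degree(x$graph))))
  invisible(x)
}

#' Partition the edges of a molecular graph by endpoint degrees
#'
#' Groups every edge by the unordered pair of its endpoint degrees
#' (canonically ordered low \eqn{\le} high) and counts the members of each
#' class. All nine topological indices are edge-additive and therefore
#' computable from this partition alone.
#'
#' @param g a \code{mol_graph}.
#' @return an \code{edge_partition}: a data.frame with columns \code{low},
#'   \code{high}, \code{count}, one row per degree-pair class, sorted by
#'   (low, high). The counts sum to the number of edges.
#' @export
edge_partition <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  deg <- igraph::degree(g$graph)
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  d1 <- deg[el[, 1]]; d2 <- deg[el[, 2]]
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  tab <- table(lo, hi)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  out <- data.frame(low = as.integer(df$lo), high = as.integer(df$hi),
                    count = as.integer(df$Freq))
  out <- out[order(out$low, out$high), ]
  rownames(out) <- NULL
  as_edge_partition(out)
}

#' Coerce a data.frame of degree-pair counts to an edge partition
#'
#' Useful for entering a partition printed in a reference table directly,
#' e.g. \code{data.frame(low = c(2, 2, 3), high = c(2, 3, 3),
#' count = c(8, 8, 2))} for naphazoline.
#'
#' @param x data.frame with columns \code{low}, \code{high}, \code{count}.
#' @return an \code{edge_partition}.
#' @export
as_edge_partition <- function(x) {
  stopifnot(is.data.frame(x), all(c("low", "high", "count") %in% names(x)))
  lo <- pmin(x$low, x$high); hi <- pmax(x$low, x$high)
  x$low <- as.integer(lo); x$high <- as.integer(hi)
  x$count <- as.integer(x$count)
  if (any(x$low < 1L) || any(x$count < 1L)) {
    stop_invalid("edge partition needs positive degrees and counts")
  }
  if (anyDuplicated(paste(x$low, x$high))) {
    agg <- stats::aggregate(count ~ low + high, data = x, FUN = sum)
    x <- agg
  }
  x <- x[order(x$low, x$high), c("low", "high", "count")]
  rownames(x) <- NULL
  class(x) <- c("edge_partition", "data.frame")
  x
}

#' Generate a random chemistry-like graph
#'
#' Builds a connected simple graph as a random spanning tree plus up to
#' \code{extra_edges} additional edges, rejecting any edge that would push a
#' vertex past \code{max_degree}. Used for property-based testing; the
#' default degree cap of 4 mirrors the valence ceiling of organic
#' hydrogen-suppressed graphs.
#'
#' @param n_vertices number of vertices (>= 2).
#' @param extra_edges maximum number of cycle-creating edges to add.
#' @param max_degree degree cap (>= 2).
#' @param seed integer seed; the result is deterministic for a fixed seed.
#' @return a \code{mol_graph}.
#' @export
random_mol_graph <- function(n_vertices, extra_edges = 0L, max_degree = 4L,
                             seed = NULL) {
  if (n_vertices < 2L) stop_invalid("need at least 2 vertices")
  if (max_degree < 2L) {
    stop(errorCondition("max_degree < 2 cannot host a connected graph on >2 vertices",
                        class = c("topoqspr_generation_error", "error")))
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  deg <- integer(n_vertices)
  edges <- matrix(integer(0), ncol = 2)
  for (v in 2:n_vertices) {
    cand <- which(deg[seq_len(v - 1L)] < max_degree)
    if (!length(cand)) {
      stop(errorCondition("degree budget exhausted while growing spanning tree",
                          class = c("topoqspr_generation_error", "error")))
    }
    u <- if (length(cand) == 1L) cand else sample(cand, 1L)
    edges <- rbind(edges, c(u, v))
    deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
  }
  if (extra_edges > 0L && n_vertices > 2L) {
    have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    added <- 0L
    tries <- 0L
    while (added < extra_edges && tries < 50L * extra_edges) {
      tries <- tries + 1L
      uv <- sample.int(n_vertices, 2L)
      u <- min(uv); v <- max(uv)
      key <- paste(u, v)
      if (key %in% have || deg[u] >= max_degree || deg[v] >= max_degree) next
      edges <- rbind(edges, c(u, v))
      have <- c(have, key)
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      added <- added + 1L
    }
  }
  ig <- igraph::graph_from_edgelist(
    cbind(paste0("v", edges[, 1]), paste0("v", edges[, 2])), directed = FALSE)
  validate_mol_graph(new_mol_graph(ig, sprintf("random(n=%d)", n_vertices)))
}

#' Read structures from a SMILES file
#'
#' One record per line, either \code{SMILES<TAB>name} or a bare SMILES.
#' Blank lines and \code{#} comments are skipped.
#'
#' @param path file path.
#' @param strip_salts passed to \code{\link{mol_graph_from_smiles}}.
#' @return list of \code{mol_graph} objects. Unparseable lines are reported
#'   via a warning and dropped; the failed line numbers are attached as
#'   attribute \code{"failed"}.
#' @export
read_smiles_file <- function(path, strip_salts = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  out <- list(); failed <- integer(0)
  for (i in keep) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    smi <- trimws(parts[1])
    nm <- if (length(parts) > 1L && nzchar(trimws(parts[2]))) trimws(parts[2]) else smi
    g <- tryCatch(mol_graph_from_smiles(smi, nm, strip_salts = strip_salts),
                  error = function(e) e)
    if (inherits(g, "error")) {
      warning(sprintf("line %d (%s): %s", i, nm, conditionMessage(g)),
              call. = FALSE)
      failed <- c(failed, i)
    } else {
      out[[length(out) + 1L]] <- g
    }
  }
  attr(out, "failed") <- failed
  out
}

#' Read a structure from an edge-list file
#'
#' Plain text, one \code{u v} pair per line; \code{#} comments allowed.
#'
#' @param path file path.
#' @param name structure label; defaults to the file name.
#' @return a \code{mol_graph}.
#' @export
read_edge_list_file <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_invalid(sprintf("no edges in '%s'", path))
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- lengths(toks) != 2L
  if (any(bad)) stop_invalid(sprintf("malformed edge line(s) in '%s'", path))
  mol_graph_from_edges(do.call(rbind, toks), name = name)
}
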