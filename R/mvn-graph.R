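#' Microvascular network graph
#'
#' An `mvn` object is a geometric vascular graph: a node table with 3-D
#' positions (um; z is cortical depth, surface at z = 0) and a vessel table
#' with diameters and lengths (um), tortuous centerlines, and vessel-type
#' labels (`PA`, `DA`, `C`, `AV`, `PV`). Boundary nodes (degree 1) carry the
#' pressure boundary conditions of the flow solver.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`, `z`
#'   (um) and optionally `is_boundary` (logical; defaults to degree-1 nodes).
#' @param vessels data.frame with columns `id` (integer, unique), `source`,
#'   `target` (node ids), `diameter`, `length` (um, positive) and optionally
#'   `type` (character), `main_branch` (logical) and `centerline` (list of
#'   n x 3 matrices, or missing for straight segments).
#' @return an object of class `mvn`.
#' @export
mvn_graph <- function(nodes, vessels) {
  nodes <- as.data.frame(nodes)
  vessels <- as.data.frame(vessels)
  req_n <- c("id", "x", "y", "z")
  req_v <- c("id", "source", "target", "diameter", "length")
  miss <- setdiff(req_n, names(nodes))
  if (length(miss)) stop("nodes table lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(req_v, names(vessels))
  if (length(miss)) stop("vessels table lacks column(s): ", paste(miss, collapse = ", "))
  nodes$id <- as.integer(nodes$id)
  vessels$id <- as.integer(vessels$id)
  vessels$source <- as.integer(vessels$source)
  vessels$target <- as.integer(vessels$target)
  bad <- !(vessels$source %in% nodes$id & vessels$target %in% nodes$id)
  if (any(bad)) {
    stop("vessel(s) ", paste(vessels$id[bad], collapse = ", "),
         " reference missing node id(s)")
  }
  if (is.null(vessels$type)) vessels$type <- rep("C", nrow(vessels))
  if (is.null(vessels$main_branch)) vessels$main_branch <- rep(FALSE, nrow(vessels))
  if (is.null(vessels$centerline)) vessels$centerline <- vector("list", nrow(vessels))
  deg <- node_degree(nodes, vessels)
  if (is.null(nodes$is_boundary)) nodes$is_boundary <- deg == 1L
  g <- structure(list(nodes = nodes, vessels = vessels), class = "mvn")
  g
}

#' @export
print.mvn <- function(x, ...) {
  cat(sprintf("mvn graph: %d nodes, %d vessels (%d boundary nodes)\n",
              nrow(x$nodes), nrow(x$vessels), sum(x$nodes$is_boundary)))
  cat("vessel types:", paste(sprintf("%s=%d", names(table(x$vessels$type)),
                                     table(x$vessels$type)), collapse = " "), "\n")
  invisible(x)
}

node_degree <- function(nodes, vessels) {
  tab <- table(factor(c(vessels$source, vessels$target), levels = nodes$id))
  as.integer(tab)
}

node_xyz <- function(g, ids) {
  idx <- match(ids, g$nodes$id)
  cbind(g$nodes$x[idx], g$nodes$y[idx], g$nodes$z[idx])
}

#' Validate a microvascular network graph
#'
#' Report-only structural check: duplicate ids, non-positive diameters or
#' lengths, lengths shorter than the Euclidean endpoint distance, centerline
#' polylines inconsistent with the stated length, disconnected components,
#' isolated nodes, and boundary nodes with more than one incident vessel.
#'
#' @param g an [mvn_graph()].
#' @param length_tol relative tolerance on centerline length vs. `length`.
#' @return data.frame with columns `level` ("fatal"/"warning"), `code`, and
#'   `message`; zero rows for a well-formed graph.
#' @export
validate_graph <- function(g, length_tol = 0.01) {
  findings <- list()
  add <- function(level, code, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, code = code, message = msg, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(g$nodes$id)) {
    add("fatal", "dup_node_id", "duplicate node ids present")
  }
  if (anyDuplicated(g$vessels$id)) {
    add("fatal", "dup_vessel_id", "duplicate vessel ids present")
  }
  if (!all(is.finite(as.matrix(g$nodes[, c("x", "y", "z")])))) {
    add("fatal", "nonfinite_position", "non-finite node position(s)")
  }
  bad <- which(!is.finite(g$vessels$diameter) | g$vessels$diameter <= 0)
  for (i in bad) add("fatal", "bad_diameter",
                     sprintf("vessel %d has non-positive diameter", g$vessels$id[i]))
  bad <- which(!is.finite(g$vessels$length) | g$vessels$length <= 0)
  for (i in bad) add("fatal", "bad_length",
                     sprintf("vessel %d has non-positive length", g$vessels$id[i]))
  # tortuosity: length must not undercut the chord
  p1 <- node_xyz(g, g$vessels$source)
  p2 <- node_xyz(g, g$vessels$target)
  chord <- sqrt(rowSums((p1 - p2)^2))
  bad <- which(g$vessels$length < chord * (1 - 1e-9) & g$vessels$length > 0)
  for (i in bad) add("warning", "length_lt_chord",
                     sprintf("vessel %d shorter than endpoint distance", g$vessels$id[i]))
  for (i in seq_len(nrow(g$vessels))) {
    cl <- g$vessels$centerline[[i]]
    if (is.null(cl)) next
    lpoly <- polyline_length(cl)
    if (abs(lpoly - g$vessels$length[i]) > length_tol * g$vessels$length[i]) {
      add("warning", "centerline_length",
          sprintf("vessel %d centerline length %.3f != length %.3f",
                  g$vessels$id[i], lpoly, g$vessels$length[i]))
    }
  }
  deg <- node_degree(g$nodes, g$vessels)
  iso <- which(deg == 0L)
  for (i in iso) add("warning", "isolated_node",
                     sprintf("node %d has no incident vessel", g$nodes$id[i]))
  multi_b <- which(g$nodes$is_boundary & deg > 1L)
  for (i in multi_b) add("warning", "boundary_degree",
                         sprintf("boundary node %d has degree %d", g$nodes$id[i], deg[i]))
  ig <- as_igraph(g)
  if (igraph::vcount(ig) > 0 && igraph::components(ig)$no > 1L) {
    add("warning", "disconnected",
        sprintf("graph has %d connected components", igraph::components(ig)$no))
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(), code = character(), message = character(),
               stringsAsFactors = FALSE)
}

as_igraph <- function(g, directed = FALSE) {
  el <- cbind(as.character(g$vessels$source), as.character(g$vessels$target))
  ig <- igraph::graph_from_edgelist(el, directed = directed)
  ig <- igraph::set_edge_attr(ig, "vessel_id", value = g$vessels$id)
  # keep isolated nodes out: igraph built from edge list only
  ig
}

polyline_length <- function(cl) {
  if (is.null(cl) || nrow(cl) < 2) return(0)
  sum(sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2)))
}

#' Vessel centerline (straight fallback)
#'
#' Returns the stored centerline polyline of a vessel, or the straight
#' source-target segment when none is stored.
#'
#' @param g an [mvn_graph()].
#' @param vessel_id vessel id.
#' @return n x 3 matrix of points (um).
#' @export
vessel_centerline <- function(g, vessel_id) {
  i <- match(vessel_id, g$vessels$id)
  if (is.na(i)) stop("unknown vessel id ", vessel_id)
  cl <- g$vessels$centerline[[i]]
  if (!is.null(cl)) return(cl)
  rbind(node_xyz(g, g$vessels$source[i])[1, ],
        node_xyz(g, g$vessels$target[i])[1, ])
}

lumen_volume <- function(g) {
  pi * g$vessels$diameter^2 / 4 * g$vessels$length
}

#' Read / write a network as node and edge tables
#'
#' CSV schema: `nodes.csv` with `id,x,y,z,is_boundary`; `edges.csv` with
#' `id,source,target,diameter,length,type,main_branch,centerline` where
#' `centerline` is a semicolon-separated list of `x:y:z` triples (empty for
#' straight vessels). Extra columns are preserved as opaque attributes.
#' Round-trip is lossless up to float formatting.
#'
#' @param nodes_file,edges_file CSV paths.
#' @param g an [mvn_graph()].
#' @param dir output directory (created if needed).
#' @return `read_network` returns an `mvn`; `write_network` returns the paths
#'   invisibly.
#' @export
read_network <- function(nodes_file, edges_file) {
  nodes <- utils::read.csv(nodes_file, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_file, stringsAsFactors = FALSE)
  for (col in c("id", "x", "y", "z")) {
    if (is.null(nodes[[col]])) stop("nodes file lacks column ", col)
    if (!is.numeric(nodes[[col]])) stop("nodes column ", col, " is not numeric")
  }
  for (col in c("id", "source", "target", "diameter", "length")) {
    if (is.null(edges[[col]])) stop("edges file lacks column ", col)
    if (!is.numeric(edges[[col]])) stop("edges column ", col, " is not numeric")
  }
  if (!is.null(nodes$is_boundary)) nodes$is_boundary <- as.logical(nodes$is_boundary)
  if (!is.null(edges$main_branch)) edges$main_branch <- as.logical(edges$main_branch)
  if (!is.null(edges$centerline)) {
    cl <- lapply(edges$centerline, parse_centerline)
    edges$centerline <- NULL
    edges$centerline <- cl
  }
  mvn_graph(nodes, edges)
}

parse_centerline <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(pts, as.numeric))
  if (ncol(m) != 3 || anyNA(m)) stop("malformed centerline string: ", s)
  m
}

format_centerline <- function(cl) {
  if (is.null(cl)) return("")
  paste(apply(cl, 1, function(p) paste(format(p, digits = 17, trim = TRUE,
                                              scientific = FALSE),
                                       collapse = ":")), collapse = ";")
}

#' @rdname read_network
#' @export
write_network <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- file.path(dir, "nodes.csv")
  ef <- file.path(dir, "edges.csv")
  ed <- g$vessels
  ed$centerline <- vapply(ed$centerline, format_centerline, character(1))
  utils::write.csv(g$nodes, nf, row.names = FALSE, quote = FALSE)
  utils::write.csv(ed, ef, row.names = FALSE, quote = FALSE)
  invisible(c(nodes = nf, edges = ef))
}
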