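#' Flow-direction DAG with DA/AV endpoints
#'
#' Orients every vessel by the sign of its (time-averaged) flow, drops
#' vessels with |q| at or below `q_eps`, asserts acyclicity (flow follows
#' the pressure potential), and identifies the DA and AV endpoints: the
#' first branch point reached from the main branch of each penetrating
#' tree through its offshoots (mirrored on the venule side).
#'
#' @param g an [mvn_graph()] with types and main branches assigned.
#' @param flow flow field on `g`.
#' @param q_eps zero-flow tolerance (um^3/ms), default 1e-8.
#' @return list of class `flow_dag`: `edges` (data.frame `vessel`, `from`,
#'   `to`, oriented by flow), `da_endpoints`, `av_endpoints`, `order`
#'   (node ids in topological order).
#' @export
build_flow_dag <- function(g, flow, q_eps = 1e-8) {
  q <- flow_of(flow, g)
  active <- which(abs(q) > q_eps)
  from <- ifelse(q[active] >= 0, g$vessels$source[active], g$vessels$target[active])
  to <- ifelse(q[active] >= 0, g$vessels$target[active], g$vessels$source[active])
  edges <- data.frame(vessel = g$vessels$id[active], from = from, to = to)
  if (!nrow(edges)) {
    return(structure(list(edges = edges,
                          da_endpoints = tree_endpoints(g, "DA"),
                          av_endpoints = tree_endpoints(g, "AV"),
                          order = integer(0), q_eps = q_eps),
                     class = "flow_dag"))
  }
  ig <- igraph::graph_from_edgelist(cbind(as.character(from), as.character(to)),
                                    directed = TRUE)
  if (!igraph::is_dag(ig)) {
    cyc <- igraph::feedback_arc_set(ig)
    stop("flow orientation contains a cycle (numerical artifact) involving edge(s): ",
         paste(utils::head(attr(cyc, "vnames") %||% as.integer(cyc), 5), collapse = ", "))
  }
  ord <- as.integer(names(igraph::topo_sort(ig, mode = "out")))
  structure(list(edges = edges,
                 da_endpoints = tree_endpoints(g, "DA"),
                 av_endpoints = tree_endpoints(g, "AV"),
                 order = ord, q_eps = q_eps),
            class = "flow_dag")
}

# first branch point after the main branch: follow each offshoot leaving a
# main-branch node through degree-2 nodes until a node with >= 3 incident
# vessels
tree_endpoints <- function(g, side) {
  inc <- incidence_list(g)
  deg <- node_degree(g$nodes, g$vessels)
  names(deg) <- as.character(g$nodes$id)
  mb <- which(g$vessels$main_branch & g$vessels$type == side)
  mb_nodes <- unique(c(g$vessels$source[mb], g$vessels$target[mb]))
  endpoints <- integer(0)
  for (node in mb_nodes) {
    for (vi in inc[[as.character(node)]]) {
      if (vi %in% mb) next
      if (g$vessels$type[vi] != side) {
        # the main branch meets the capillary bed directly: this node is
        # itself the first branch point
        if (g$vessels$type[vi] == "C") endpoints <- c(endpoints, node)
        next
      }
      # walk away from the main branch
      prev <- node
      cur_v <- vi
      repeat {
        nxt <- if (g$vessels$source[cur_v] == prev) g$vessels$target[cur_v] else g$vessels$source[cur_v]
        if (deg[as.character(nxt)] >= 3L) { endpoints <- c(endpoints, nxt); break }
        cand <- setdiff(inc[[as.character(nxt)]], cur_v)
        if (!length(cand)) break  # dead end
        prev <- nxt
        cur_v <- cand[1]
      }
    }
  }
  sort(unique(endpoints))
}

#' Count DA-to-AV flow paths by dynamic programming
#'
#' For each node, `U` is the number of distinct directed paths from any DA
#' endpoint and `W` the number to any AV endpoint, computed in topological
#' order; the number of DA-to-AV paths through an edge is
#' `U(tail) * W(head)` and the total is the sum of `U` over AV endpoints.
#' Counts are exact within double precision (< 2^53).
#'
#' @param dag a [build_flow_dag()] result.
#' @return list of class `path_index`: `U`, `W` (named by node id),
#'   `edge_paths` (named by vessel id), `total`.
#' @export
count_paths <- function(dag) {
  nodes <- unique(c(dag$edges$from, dag$edges$to, dag$order))
  U <- stats::setNames(numeric(length(nodes)), as.character(nodes))
  W <- stats::setNames(numeric(length(nodes)), as.character(nodes))
  U[as.character(dag$da_endpoints[dag$da_endpoints %in% nodes])] <- 1
  in_edges <- split(seq_len(nrow(dag$edges)), as.character(dag$edges$to))
  out_edges <- split(seq_len(nrow(dag$edges)), as.character(dag$edges$from))
  for (n in as.character(dag$order)) {
    for (ei in in_edges[[n]]) {
      U[n] <- U[n] + U[as.character(dag$edges$from[ei])]
    }
    # paths are rooted at DA endpoints: the +1 above was the seed
  }
  W[as.character(dag$av_endpoints[dag$av_endpoints %in% nodes])] <- 1
  for (n in rev(as.character(dag$order))) {
    for (ei in out_edges[[n]]) {
      W[n] <- W[n] + W[as.character(dag$edges$to[ei])]
    }
  }
  edge_paths <- U[as.character(dag$edges$from)] * W[as.character(dag$edges$to)]
  names(edge_paths) <- dag$edges$vessel
  total <- sum(U[as.character(dag$av_endpoints[dag$av_endpoints %in% nodes])])
  structure(list(U = U, W = W, edge_paths = edge_paths, total = total),
            class = "path_index")
}

# single-source / single-sink path-count DP
dp_from <- function(dag, source_node) {
  nodes <- unique(c(dag$edges$from, dag$edges$to))
  U <- stats::setNames(numeric(length(nodes)), as.character(nodes))
  if (!as.character(source_node) %in% names(U)) return(U)
  U[as.character(source_node)] <- 1
  in_edges <- split(seq_len(nrow(dag$edges)), as.character(dag$edges$to))
  for (n in as.character(dag$order)) {
    for (ei in in_edges[[n]]) U[n] <- U[n] + U[as.character(dag$edges$from[ei])]
  }
  U
}

dp_to <- function(dag, sink_node) {
  nodes <- unique(c(dag$edges$from, dag$edges$to))
  W <- stats::setNames(numeric(length(nodes)), as.character(nodes))
  if (!as.character(sink_node) %in% names(W)) return(W)
  W[as.character(sink_node)] <- 1
  out_edges <- split(seq_len(nrow(dag$edges)), as.character(dag$edges$from))
  for (n in rev(as.character(dag$order))) {
    for (ei in out_edges[[n]]) W[n] <- W[n] + W[as.character(dag$edges$to[ei])]
  }
  W
}

#' DA-AV endpoint-pair analysis across a microstroke
#'
#' Per endpoint pair, counts the unique flow paths at baseline and after
#' the occlusion, classifies the pair (category 1: at least one baseline
#' path traverses the MSC; category 2: none does; excluded: connected only
#' through the MSC after the stroke), and tallies pairs with an increase,
#' decrease or no change of their path count, plus pairs gained and lost.
#'
#' @param dag_base,dag_stroke [build_flow_dag()] results on the same graph.
#' @param g the [mvn_graph()].
#' @param msc the occluded vessel id.
#' @return list with `pairs` (data.frame `da`, `av`, `n_base`, `n_stroke`,
#'   `through_msc_base`, `category`, `ratio`) and `summary` (per-category
#'   increase/decrease/no-change tallies, pairs gained and lost).
#' @export
pair_analysis <- function(dag_base, dag_stroke, g, msc) {
  pairs <- expand.grid(da = dag_base$da_endpoints, av = dag_base$av_endpoints)
  eb <- match(msc, dag_base$edges$vessel)
  es <- match(msc, dag_stroke$edges$vessel)
  Ub <- lapply(dag_base$da_endpoints, dp_from, dag = dag_base)
  Wb <- lapply(dag_base$av_endpoints, dp_to, dag = dag_base)
  Us <- lapply(dag_base$da_endpoints, dp_from, dag = dag_stroke)
  Ws <- lapply(dag_base$av_endpoints, dp_to, dag = dag_stroke)
  names(Ub) <- names(Us) <- as.character(dag_base$da_endpoints)
  names(Wb) <- names(Ws) <- as.character(dag_base$av_endpoints)
  at <- function(v, n) if (as.character(n) %in% names(v)) unname(v[as.character(n)]) else 0
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- as.character(pairs$da[i]); a <- as.character(pairs$av[i])
    n_base <- at(Ub[[d]], pairs$av[i])
    n_stroke <- at(Us[[d]], pairs$av[i])
    thr_b <- if (!is.na(eb))
      at(Ub[[d]], dag_base$edges$from[eb]) *
        at(Wb[[a]], dag_base$edges$to[eb]) else 0
    thr_s <- if (!is.na(es))
      at(Us[[d]], dag_stroke$edges$from[es]) *
        at(Ws[[a]], dag_stroke$edges$to[es]) else 0
    data.frame(da = pairs$da[i], av = pairs$av[i], n_base = n_base,
               n_stroke = n_stroke, through_msc_base = thr_b,
               through_msc_stroke = thr_s)
  })
  pairs <- do.call(rbind, res)
  pairs <- pairs[pairs$n_base > 0 | pairs$n_stroke > 0, , drop = FALSE]
  pairs$category <- ifelse(
    pairs$n_stroke > 0 & pairs$n_stroke == pairs$through_msc_stroke, "excluded",
    ifelse(pairs$through_msc_base > 0, "cat1", "cat2"))
  pairs$ratio <- ifelse(pairs$n_base > 0, pairs$n_stroke / pairs$n_base, Inf)
  tally <- function(p) {
    c(increase = sum(p$ratio > 1 & is.finite(p$ratio)),
      decrease = sum(p$ratio < 1),
      no_change = sum(p$ratio == 1))
  }
  summary <- list(
    cat1 = tally(pairs[pairs$category == "cat1" & pairs$n_base > 0, ]),
    cat2 = tally(pairs[pairs$category == "cat2" & pairs$n_base > 0, ]),
    gained = sum(pairs$n_base == 0 & pairs$n_stroke > 0),
    lost = sum(pairs$n_base > 0 & pairs$n_stroke == 0),
    n_excluded = sum(pairs$category == "excluded"))
  list(pairs = pairs, summary = summary)
}
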