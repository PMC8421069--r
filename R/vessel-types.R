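#' Vessel-type labeling from penetrating-tree roots
#'
#' Walks outward from each descending-arteriole (DA) and ascending-venule
#' (AV) root at the cortical surface and applies the diameter criterion:
#' vessels keep the penetrating label until the first pair of consecutive
#' vessels both thinner than `d_thresh`; the first vessel of that pair and
#' everything reached beyond it is labeled capillary (`C`). Pial vessels
#' (`PA`, `PV`) are never relabeled. Vessels unreachable from any root are
#' labeled `C` with a warning. Labels are deterministic (breadth-first,
#' first visit wins; DA walk takes precedence over AV on conflict).
#'
#' @param g an [mvn_graph()] whose vessels carry provisional `DA`/`AV` labels
#'   identifying the penetrating trees, or explicit `roots`.
#' @param d_thresh diameter threshold (um) below which two consecutive
#'   vessels trigger the type change; default 6.
#' @param roots optional data.frame with columns `node` (root node id) and
#'   `side` ("DA" or "AV"); default: boundary nodes at the surface (z <=
#'   `surface_z`) incident to a DA/AV-labeled vessel.
#' @param surface_z depth (um) below which a boundary node counts as a
#'   surface root; default 1.
#' @return the graph with updated `type` labels.
#' @export
assign_vessel_types <- function(g, d_thresh = 6, roots = NULL, surface_z = 1) {
  if (is.null(roots)) {
    deg <- node_degree(g$nodes, g$vessels)
    cand <- g$nodes$id[g$nodes$is_boundary & g$nodes$z <= surface_z]
    roots <- do.call(rbind, lapply(cand, function(nid) {
      vi <- which(g$vessels$source == nid | g$vessels$target == nid)
      ty <- g$vessels$type[vi]
      if (any(ty %in% c("DA", "AV"))) {
        data.frame(node = nid, side = ty[ty %in% c("DA", "AV")][1],
                   stringsAsFactors = FALSE)
      } else NULL
    }))
  }
  if (is.null(roots) || nrow(roots) == 0) {
    warning("no penetrating-tree roots identified; all non-pial vessels labeled C")
    g$vessels$type[!(g$vessels$type %in% c("PA", "PV"))] <- "C"
    return(g)
  }
  inc <- incidence_list(g)
  nv <- nrow(g$vessels)
  label <- rep(NA_character_, nv)
  pial <- g$vessels$type %in% c("PA", "PV")
  label[pial] <- g$vessels$type[pial]
  for (side in c("DA", "AV")) {
    side_roots <- roots$node[roots$side == side]
    if (!length(side_roots)) next
    other_side <- if (side == "DA") "AV" else "DA"
    # breadth-first walk from the surface roots; a branch stops as soon as
    # the sub-threshold pair fires — everything beyond is capillary bed.
    # Vessels provisionally labeled as the other penetrating tree act as a
    # barrier so one walk cannot claim the opposite tree.
    frontier <- data.frame(node = side_roots, prev_d = Inf,
                           prev_vessel = NA_integer_)
    visited <- rep(FALSE, nv)
    visited[pial] <- TRUE
    visited[g$vessels$type == other_side] <- TRUE
    while (nrow(frontier)) {
      nxt <- list()
      for (r in seq_len(nrow(frontier))) {
        nid <- frontier$node[r]
        for (vi in inc[[as.character(nid)]]) {
          if (visited[vi] || !is.na(label[vi])) next
          visited[vi] <- TRUE
          d <- g$vessels$diameter[vi]
          if (d < d_thresh && frontier$prev_d[r] < d_thresh) {
            # the FIRST vessel of the qualifying pair becomes capillary and
            # the walk does not continue past the pair
            prev_vi <- frontier$prev_vessel[r]
            if (!is.na(prev_vi)) label[prev_vi] <- "C"
            label[vi] <- "C"
            next
          }
          label[vi] <- side
          other <- if (g$vessels$source[vi] == nid) g$vessels$target[vi] else g$vessels$source[vi]
          nxt[[length(nxt) + 1L]] <- data.frame(
            node = other, prev_d = d, prev_vessel = vi)
        }
      }
      frontier <- if (length(nxt)) do.call(rbind, nxt) else
        frontier[integer(0), ]
    }
  }
  # everything beyond the penetrating trees is capillary; warn only for
  # vessels in components that contain no root at all
  if (anyNA(label)) {
    ig <- as_igraph(g)
    comp <- igraph::components(ig)$membership
    root_comps <- unique(comp[as.character(roots$node)])
    vcomp <- comp[as.character(g$vessels$source)]
    orphan <- is.na(label) & !(vcomp %in% root_comps)
    if (any(orphan)) {
      warning(sum(orphan), " vessel(s) unreachable from any root; labeled C")
    }
    label[is.na(label)] <- "C"
  }
  g$vessels$type <- label
  g$vessels$main_branch[g$vessels$type == "C"] <- FALSE
  g
}

incidence_list <- function(g) {
  idx <- seq_len(nrow(g$vessels))
  l <- split(c(idx, idx), as.character(c(g$vessels$source, g$vessels$target)))
  # make lookups for nodes without vessels return integer(0)
  out <- structure(vector("list", nrow(g$nodes)), names = as.character(g$nodes$id))
  out[names(l)] <- l
  out[vapply(out, is.null, logical(1))] <- list(integer())
  out
}

#' Main-branch labeling of penetrating trees
#'
#' Walks each DA/AV tree from its surface root. At every bifurcation inside
#' the tree exactly one child continues the main branch: the child whose
#' direction deviates least from the parent vessel's direction, unless its
#' downstream subtree path length is shorter than `min_subtree` um while the
#' best sibling's is not (then the longer child wins); exact ties break to
#' the lowest vessel id. Short offshoots therefore never become main branch.
#'
#' @param g an [mvn_graph()] with vessel types assigned.
#' @param min_subtree minimum downstream path length (um) for an angular
#'   winner to keep the main branch; default 100.
#' @param surface_z see [assign_vessel_types()].
#' @return the graph with `main_branch` flags set on DA/AV vessels.
#' @export
split_main_branch <- function(g, min_subtree = 100, surface_z = 1) {
  g$vessels$main_branch <- rep(FALSE, nrow(g$vessels))
  inc <- incidence_list(g)
  for (side in c("DA", "AV")) {
    tree_vi <- which(g$vessels$type == side)
    if (!length(tree_vi)) next
    in_tree <- rep(FALSE, nrow(g$vessels)); in_tree[tree_vi] <- TRUE
    roots <- g$nodes$id[g$nodes$is_boundary & g$nodes$z <= surface_z]
    roots <- roots[vapply(roots, function(nid)
      any(in_tree[inc[[as.character(nid)]]]), logical(1))]
    for (root in roots) {
      node <- root
      prev_dir <- c(0, 0, 1)  # trees descend into the cortex
      used <- rep(FALSE, nrow(g$vessels))
      repeat {
        cand <- inc[[as.character(node)]]
        cand <- cand[in_tree[cand] & !used[cand] & !g$vessels$main_branch[cand]]
        if (!length(cand)) break
        if (length(cand) == 1L) {
          chosen <- cand
        } else {
          dirs <- t(vapply(cand, function(vi) vessel_dir(g, vi, node), numeric(3)))
          ang <- acos(pmin(1, pmax(-1, dirs %*% prev_dir)))
          sub_len <- vapply(cand, function(vi)
            subtree_path_length(g, inc, in_tree, vi, node), numeric(1))
          ord <- order(ang, g$vessels$id[cand])
          chosen <- cand[ord[1]]
          if (sub_len[ord[1]] < min_subtree && any(sub_len >= min_subtree)) {
            ok <- which(sub_len >= min_subtree)
            ord2 <- ok[order(-sub_len[ok], g$vessels$id[cand[ok]])]
            chosen <- cand[ord2[1]]
          }
        }
        g$vessels$main_branch[chosen] <- TRUE
        used[chosen] <- TRUE
        nxt <- if (g$vessels$source[chosen] == node) g$vessels$target[chosen] else g$vessels$source[chosen]
        prev_dir <- vessel_dir(g, chosen, node)
        node <- nxt
      }
    }
  }
  g
}

vessel_dir <- function(g, vi, from_node) {
  s <- g$vessels$source[vi]; t <- g$vessels$target[vi]
  to_node <- if (s == from_node) t else s
  d <- node_xyz(g, to_node)[1, ] - node_xyz(g, from_node)[1, ]
  n <- sqrt(sum(d^2))
  if (n == 0) c(0, 0, 0) else d / n
}

# longest downstream path length (um) through the same-type subtree entered
# via vessel vi from from_node
subtree_path_length <- function(g, inc, in_tree, vi, from_node) {
  best <- 0
  stack <- list(list(vi = vi, node = from_node, len = 0, seen = vi))
  while (length(stack)) {
    s <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    len <- s$len + g$vessels$length[s$vi]
    best <- max(best, len)
    nxt_node <- if (g$vessels$source[s$vi] == s$node) g$vessels$target[s$vi] else g$vessels$source[s$vi]
    for (vj in inc[[as.character(nxt_node)]]) {
      if (!in_tree[vj] || vj %in% s$seen) next
      stack[[length(stack) + 1L]] <- list(vi = vj, node = nxt_node, len = len,
                                          seen = c(s$seen, vj))
    }
  }
  best
}

#' Cortical depth-layer assignment
#'
#' Divides the cortex into `n_layers` layers of `thickness` um. A vessel
#' belongs to layer k if one endpoint's depth lies within the layer bounds
#' and the other endpoint lies within the bounds expanded by `slack` um.
#' Vessels qualifying for several layers take the shallowest one.
#'
#' @param g an [mvn_graph()].
#' @param thickness layer thickness (um), default 200.
#' @param slack bound expansion for the second endpoint (um), default 50.
#' @param n_layers number of layers, default 5.
#' @return data.frame `vessel`, `layer` (NA when no layer qualifies) plus an
#'   attribute `n_unassigned`.
#' @export
assign_depth_layers <- function(g, thickness = 200, slack = 50, n_layers = 5) {
  z1 <- g$nodes$z[match(g$vessels$source, g$nodes$id)]
  z2 <- g$nodes$z[match(g$vessels$target, g$nodes$id)]
  layer <- rep(NA_integer_, nrow(g$vessels))
  for (k in seq_len(n_layers)) {
    lo <- (k - 1) * thickness; hi <- k * thickness
    in_core1 <- z1 >= lo & z1 < hi
    in_core2 <- z2 >= lo & z2 < hi
    in_slack1 <- z1 >= lo - slack & z1 <= hi + slack
    in_slack2 <- z2 >= lo - slack & z2 <= hi + slack
    ok <- (in_core1 & in_slack2) | (in_core2 & in_slack1)
    layer[is.na(layer) & ok] <- k
  }
  out <- data.frame(vessel = g$vessels$id, layer = layer)
  attr(out, "n_unassigned") <- sum(is.na(layer))
  out
}
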