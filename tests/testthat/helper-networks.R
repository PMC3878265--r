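# Fixture networks and independent brute-force oracles.  The oracles work
# from a plain edge data frame and re-derive the model rules from scratch,
# so they share no code with the package internals they check.

toggle_edges <- function() {
  data.frame(from = c("a", "b"), to = c("b", "a"), sign = c(-1, -1))
}

toggle_grn <- function() grn(toggle_edges())

# signed ring v1 -> v2 -> ... -> vk -> v1 with the given edge signs
ring_edges <- function(signs) {
  k <- length(signs)
  nm <- sprintf("v%02d", seq_len(k))
  data.frame(from = nm, to = nm[c(seq_len(k)[-1], 1)], sign = signs)
}

# random simple signed digraph as an edge data frame (no duplicate pairs)
random_edges <- function(n, m, p_self = 0.15, p_inh = 0.5) {
  nm <- letters[seq_len(n)]
  from <- sample(nm, m, replace = TRUE)
  to <- ifelse(stats::runif(m) < p_self, from, sample(nm, m, replace = TRUE))
  e <- data.frame(from = from, to = to,
                  sign = ifelse(stats::runif(m) < p_inh, -1, 1))
  e[!duplicated(e[, c("from", "to")]), , drop = FALSE]
}

# --- dynamics oracle ------------------------------------------------------

# inhibitor-dominant rule computed directly from the edge list
oracle_update <- function(edges, state, node, default_on = TRUE) {
  inh <- edges$from[edges$to == node & edges$sign == -1]
  act <- edges$from[edges$to == node & edges$sign == 1]
  if (any(state[inh] == 1)) return(0L)
  if (length(act) == 0) return(if (default_on) 1L else 0L)
  as.integer(any(state[act] == 1))
}

oracle_step <- function(edges, state, default_on = TRUE) {
  vapply(names(state), function(v) oracle_update(edges, state, v, default_on),
         integer(1))
}

# all fixed points by iterating every one of the 2^n states
oracle_fixed_points <- function(edges, nodes = NULL, default_on = TRUE) {
  nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  n <- length(nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(grid) <- nodes
  keep <- apply(grid, 1, function(s) {
    st <- stats::setNames(as.integer(s), nodes)
    identical(unname(oracle_step(edges, st, default_on)), unname(st))
  })
  fps <- grid[keep, , drop = FALSE]
  fps[do.call(order, as.data.frame(fps)), , drop = FALSE]
}

# --- circuit oracle -------------------------------------------------------

# all elementary circuits by plain DFS: paths start at their smallest node
# and may only visit larger nodes, so each cycle is found exactly once.
# Returns canonical keys "v1>v2>...|s1,s2,..." sorted.
oracle_cycle_keys <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  idx <- stats::setNames(seq_along(nodes), nodes)
  sgn <- function(u, v) edges$sign[edges$from == u & edges$to == v]
  out <- character(0)
  for (s in nodes) {
    if (length(sgn(s, s)) == 1) out <- c(out, paste0(s, "|", sgn(s, s)))
  }
  dfs <- function(path) {
    u <- path[length(path)]
    for (v in edges$to[edges$from == u]) {
      if (v == path[1] && length(path) > 1) {
        signs <- mapply(sgn, path, c(path[-1], path[1]))
        out <<- c(out, paste0(paste(path, collapse = ">"), "|",
                              paste(signs, collapse = ",")))
      } else if (!(v %in% path) && idx[v] > idx[path[1]]) {
        dfs(c(path, v))
      }
    }
  }
  for (s in nodes) dfs(s)
  sort(out)
}

circuit_keys <- function(circ) {
  sort(vapply(seq_len(nrow(circ)), function(r) {
    paste0(paste(circ$nodes[[r]], collapse = ">"), "|",
           paste(circ$signs[[r]], collapse = ","))
  }, character(1)))
}

# --- clamp-subset oracle --------------------------------------------------

# smallest gene-set size whose clamping to final values achieves the
# transition, by exhaustive search over all non-empty subsets of `genes`
oracle_min_clamp_size <- function(net, initial, final, genes,
                                  step_cap = 200) {
  for (k in seq_along(genes)) {
    for (sub in utils::combn(genes, k, simplify = FALSE)) {
      cl <- stats::setNames(final[sub], sub)
      if (verify_transition(net, initial, final, cl, step_cap = step_cap)) {
        return(k)
      }
    }
  }
  Inf
}

# --- contextualization oracle ---------------------------------------------

# best attainable profile-agreement score over all 2^m edge-removal masks
oracle_best_mask_score <- function(net, profiles) {
  m <- nrow(net$edges)
  best <- 0
  for (code in 0:(2^m - 1)) {
    drop <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    sub <- net$edges[setdiff(seq_len(m), drop), , drop = FALSE]
    net2 <- prune_unregulated(grn(sub, nodes = net$nodes$name))
    best <- max(best, contextualization_score(net2, profiles))
    if (best == 1) break
  }
  best
}
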