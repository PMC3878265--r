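#' Enumerate fixed-point attractors of the synchronous dynamics
#'
#' Finds every state that the synchronous inhibitor-dominant map sends to
#' itself.  Two complete strategies are available: `"exhaustive"` iterates
#' all `2^n` states in vectorised blocks (practical up to ~20 nodes) and
#' `"backtracking"` assigns values only on a feedback vertex set (every
#' self-loop node plus greedily chosen cycle breakers), derives all other
#' nodes in topological order, and keeps assignments that close
#' consistently — cost `2^|FVS|`, which exploits sparseness and scales to
#' the 20-40 gene networks this method is aimed at.  Both are provably
#' complete for fixed points (every cycle meets the FVS, so non-FVS values
#' are functionally determined);
#' `"auto"` picks by size.  Attractor ids are assigned in lexicographic
#' order of the state vector (genes in sorted name order) so runs are
#' reproducible.
#'
#' Cyclic attractors are deliberately not enumerated: reprogramming between
#' oscillatory states is outside the scope of the model.
#'
#' @param network a `grn`.
#' @param mode `"auto"`, `"exhaustive"` or `"backtracking"`.
#' @param strict_activator_rule see [boolean_update()].
#' @param max_nodes hard cap on network size (guards accidental blow-ups).
#' @return a tibble with column `id` plus one 0/1 column per node.
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' attractors(toggle)
#' @export
attractors <- function(network, mode = c("auto", "exhaustive", "backtracking"),
                       strict_activator_rule = FALSE, max_nodes = 64) {
  mode <- match.arg(mode)
  n <- network$n
  if (n == 0) {
    return(tibble::tibble(id = integer(0)))
  }
  if (n > max_nodes) {
    stop("network has ", n, " nodes, above the cap of ", max_nodes,
         "; reduce the network or raise `max_nodes`", call. = FALSE)
  }
  if (mode == "auto") mode <- if (n <= 16) "exhaustive" else "backtracking"
  if (mode == "exhaustive" && n > 22) {
    stop("exhaustive enumeration over 2^", n, " states refused; ",
         "use mode = \"backtracking\"", call. = FALSE)
  }
  states <- switch(mode,
    exhaustive = fixed_points_exhaustive(network, strict_activator_rule),
    backtracking = fixed_points_backtracking(network, strict_activator_rule)
  )
  storage.mode(states) <- "integer"
  states <- states[order_states(states), , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(states))
  names(out) <- network$nodes$name
  dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(out))), out)
}

order_states <- function(states) {
  if (nrow(states) <= 1) return(seq_len(nrow(states)))
  do.call(order, as.data.frame(states))
}

fixed_points_exhaustive <- function(network, strict) {
  n <- network$n
  total <- 2^n
  block_bits <- min(n, 14L)
  block <- 2^block_bits
  found <- list()
  pow <- 2^(seq_len(n) - 1)
  for (off in seq(0, total - 1, by = block)) {
    idx <- off + seq_len(block) - 1
    idx <- idx[idx < total]
    S <- vapply(pow, function(p) (idx %/% p) %% 2, numeric(length(idx)))
    S <- t(matrix(S, ncol = n))                # n x block, node i = bit i
    inh <- network$A_inh %*% S
    act <- network$A_act %*% S
    ok_act <- if (strict) act > 0 else (act > 0 | !network$has_act)
    nxt <- (inh == 0 & ok_act) + 0
    fix <- colSums(nxt != S) == 0
    if (any(fix)) found[[length(found) + 1]] <- t(S[, fix, drop = FALSE])
  }
  if (length(found) == 0) {
    matrix(integer(0), nrow = 0, ncol = n)
  } else {
    do.call(rbind, found)
  }
}

# Complete fixed-point enumeration via a feedback vertex set: every cycle
# of the network passes through the FVS, so once FVS values are assigned
# the remaining nodes are functionally determined in topological order; an
# assignment yields a fixed point iff it closes consistently on the FVS.
# Cost is 2^|FVS| propagations, vectorised in blocks.
fixed_points_backtracking <- function(network, strict, max_fvs = 24L) {
  n <- network$n
  fvs <- greedy_fvs(network)
  if (length(fvs) > max_fvs) {
    stop("feedback vertex set has ", length(fvs), " nodes (cap ", max_fvs,
         "); the network is too densely cyclic for complete enumeration",
         call. = FALSE)
  }
  non_fvs <- setdiff(seq_len(n), fvs)
  ord <- topo_order(network, non_fvs)
  f <- length(fvs)
  total <- 2^f
  block_bits <- min(f, 14L)
  block <- 2^block_bits
  pow <- 2^(seq_len(max(f, 1L)) - 1)
  found <- list()
  for (off in seq(0, max(total - 1, 0), by = block)) {
    idx <- off + seq_len(block) - 1
    idx <- idx[idx < total]
    k <- length(idx)
    S <- matrix(0L, n, k)
    if (f > 0) {
      for (j in seq_len(f)) S[fvs[j], ] <- as.integer((idx %/% pow[j]) %% 2)
    }
    for (v in ord) {
      inh <- network$inh_in[[v]]
      act <- network$act_in[[v]]
      inh_on <- if (length(inh) > 0) {
        colSums(S[inh, , drop = FALSE]) > 0
      } else rep(FALSE, k)
      act_ok <- if (length(act) > 0) {
        colSums(S[act, , drop = FALSE]) > 0
      } else rep(!strict, k)
      S[v, ] <- as.integer(!inh_on & act_ok)
    }
    ok <- rep(TRUE, k)
    for (v in fvs) {
      inh <- network$inh_in[[v]]
      act <- network$act_in[[v]]
      inh_on <- if (length(inh) > 0) {
        colSums(S[inh, , drop = FALSE]) > 0
      } else rep(FALSE, k)
      act_ok <- if (length(act) > 0) {
        colSums(S[act, , drop = FALSE]) > 0
      } else rep(!strict, k)
      ok <- ok & (as.integer(!inh_on & act_ok) == S[v, ])
    }
    if (any(ok)) found[[length(found) + 1]] <- t(S[, ok, drop = FALSE])
  }
  if (length(found) == 0) {
    matrix(integer(0), nrow = 0, ncol = n)
  } else {
    unique(do.call(rbind, found))
  }
}

# greedy feedback vertex set: all self-loop nodes, then repeatedly the
# highest-degree node still on a cycle
greedy_fvs <- function(network) {
  n <- network$n
  A <- (network$A_act + network$A_inh) > 0  # A[v, u]: u -> v
  fvs <- which(diag(A))
  repeat {
    sub <- setdiff(seq_len(n), fvs)
    if (length(sub) == 0) break
    R <- A[sub, sub, drop = FALSE]  # reachability closure (Warshall)
    m <- length(sub)
    for (k in seq_len(m)) R <- R | (R[, k] %o% R[k, ])
    on_cycle <- which(diag(R))
    if (length(on_cycle) == 0) break
    cyc <- sub[on_cycle]
    score <- rowSums(A[cyc, cyc, drop = FALSE]) *
      colSums(A[cyc, cyc, drop = FALSE])
    fvs <- c(fvs, cyc[which.max(score)])
  }
  sort(fvs)
}

# topological order of the given nodes in the graph restricted to them
# (assumes acyclicity among them, guaranteed by FVS removal)
topo_order <- function(network, nodes) {
  if (length(nodes) == 0) return(integer(0))
  A <- (network$A_act + network$A_inh) > 0
  sub <- A[nodes, nodes, drop = FALSE]
  indeg <- rowSums(sub)
  ord <- integer(0)
  left <- seq_along(nodes)
  while (length(left) > 0) {
    src <- left[indeg[left] == 0]
    if (length(src) == 0) stop("internal error: cycle outside FVS")
    v <- src[1]
    ord <- c(ord, v)
    left <- setdiff(left, v)
    indeg <- indeg - sub[, v]
  }
  nodes[ord]
}

# named state vector of attractor `id` from an attractors() tibble
attractor_state <- function(att, id) {
  row <- att[att$id == id, , drop = FALSE]
  if (nrow(row) != 1) stop("no attractor with id ", id, call. = FALSE)
  unlist(row[1, setdiff(names(att), "id")])
}

#' Simulate the synchronous dynamics to an attractor
#'
#' Runs the network forward from `start`, optionally holding a set of nodes
#' clamped at fixed values (a simulated over-expression or knock-down).
#' Simulation stops at a fixed point of the (clamped) system, at the first
#' revisit of an earlier state (a cycle), or at `step_cap`; the terminal
#' condition is always reported, a hit step cap is never treated as
#' convergence.
#'
#' @inheritParams boolean_update
#' @param start full starting state.
#' @param clamp named 0/1 vector of nodes to hold constant (may be empty).
#' @param step_cap maximum number of synchronous steps.
#' @return a `grn_trajectory`: list with `states` (one row per visited
#'   state, including the start), `terminal` (`"fixed_point"`, `"cycle"` or
#'   `"step_cap"`), and `steps`.
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' simulate_to_attractor(toggle, c(a = 0, b = 1), clamp = c(a = 1))
#' @export
simulate_to_attractor <- function(network, start, clamp = NULL,
                                  step_cap = 1000,
                                  strict_activator_rule = FALSE) {
  s <- as_state(network, start)
  clamp_idx <- integer(0)
  clamp_val <- integer(0)
  if (length(clamp) > 0) {
    bad <- setdiff(names(clamp), network$nodes$name)
    if (length(bad) > 0) {
      stop("clamp on unknown node(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    clamp_idx <- unname(network$index[names(clamp)])
    clamp_val <- as.integer(clamp)
    s[clamp_idx] <- clamp_val
  }
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  states <- list(s)
  assign(paste(s, collapse = ""), 1L, envir = seen)
  terminal <- "step_cap"
  for (step in seq_len(step_cap)) {
    nxt <- step_int(network, s, strict_activator_rule)
    nxt[clamp_idx] <- clamp_val
    if (identical(nxt, s)) {
      terminal <- "fixed_point"
      break
    }
    key <- paste(nxt, collapse = "")
    states[[length(states) + 1]] <- nxt
    if (!is.null(seen[[key]])) {
      terminal <- "cycle"
      s <- nxt
      break
    }
    assign(key, length(states), envir = seen)
    s <- nxt
  }
  m <- do.call(rbind, states)
  colnames(m) <- network$nodes$name
  structure(
    list(states = m, terminal = terminal, steps = nrow(m) - 1L,
         clamp = clamp),
    class = "grn_trajectory"
  )
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("<grn_trajectory> ", x$steps, " step(s), terminal: ", x$terminal, "\n",
      sep = "")
  invisible(x)
}

#' @export
#' @rdname trajectory_tidiers
tidy.grn_trajectory <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame(x$states))
  df$step <- seq_len(nrow(df)) - 1L
  tidyr::pivot_longer(df, -"step", names_to = "node", values_to = "state")
}

#' Tidiers for simulated trajectories
#'
#' `tidy()` returns the visited states in long format (`step`, `node`,
#' `state`), convenient for plotting expression-pattern ribbons.
#'
#' @param x a `grn_trajectory`.
#' @param ... unused.
#' @return a tibble.
#' @name trajectory_tidiers
NULL

final_state <- function(traj) {
  traj$states[nrow(traj$states), ]
}

#' Map attractors to phenotype expression profiles
#'
#' Scores every ordered pair of distinct attractors against the binarized
#' initial/final profiles and returns the best pair.  The score of a pair is
#' the mean, over the two phenotypes, of the fraction of measured genes
#' whose attractor state equals the observed value — the fraction of genes
#' "well explained" by the dynamical model.  Ties are broken by
#' lexicographic attractor id.
#'
#' @param att an [attractors()] tibble.
#' @param profiles a profiles tibble (see [as_profiles()]).
#' @return one-row tibble with `initial_id`, `final_id`, `score`,
#'   `match_initial`, `match_final`.
#' @export
match_attractors_to_profiles <- function(att, profiles) {
  profiles <- as_profiles(profiles)
  if (nrow(att) < 2) {
    stop("fewer than 2 attractors: the network cannot represent both ",
         "phenotypes", call. = FALSE)
  }
  genes <- intersect(profiles$gene, setdiff(names(att), "id"))
  if (length(genes) == 0) {
    stop("no measured profile gene is present in the network", call. = FALSE)
  }
  prof <- profiles[match(genes, profiles$gene), ]
  A <- as.matrix(att[, genes, drop = FALSE])
  m_init <- rowMeans(A == matrix(prof$initial, nrow(att), length(genes),
                                 byrow = TRUE))
  m_final <- rowMeans(A == matrix(prof$final, nrow(att), length(genes),
                                  byrow = TRUE))
  pairs <- expand.grid(i = seq_len(nrow(att)), f = seq_len(nrow(att)))
  pairs <- pairs[pairs$i != pairs$f, , drop = FALSE]
  pairs <- pairs[order(pairs$i, pairs$f), , drop = FALSE]
  sc <- (m_init[pairs$i] + m_final[pairs$f]) / 2
  best <- which.max(sc)  # first max = lexicographic tie-break
  tibble::tibble(
    initial_id = att$id[pairs$i[best]],
    final_id = att$id[pairs$f[best]],
    score = sc[best],
    match_initial = m_init[pairs$i[best]],
    match_final = m_final[pairs$f[best]]
  )
}

#' Attractor heatmap
#'
#' Plots the attractor table as a gene-by-attractor tile map, the usual way
#' stable expression patterns are displayed next to phenotype profiles.
#'
#' @param att an [attractors()] tibble.
#' @return a ggplot.
#' @export
plot_attractors <- function(att) {
  long <- tidyr::pivot_longer(att, -"id", names_to = "gene",
                              values_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$id), y = .data$gene,
                                     fill = factor(.data$state))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey40"),
                               name = "state") +
    ggplot2::labs(x = "attractor", y = NULL)
}
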