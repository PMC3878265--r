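#' Enumerate all elementary circuits of a signed network
#'
#' An elementary circuit is a directed cycle in which no node repeats except
#' the implicit closure; self-loops count as length-1 circuits.  Enumeration
#' uses Johnson's algorithm, extended to emit each self-loop as a length-1
#' circuit before the main recursion (the classic algorithm skips them).
#' Every circuit is reported once, in canonical rotation (starting at its
#' lexicographically smallest node), in a deterministic order.
#'
#' A circuit is positive iff it contains an even number of inhibitions;
#' positive circuits are the necessary substrate of multistability, negative
#' circuits generate oscillations.
#'
#' @param network a `grn`.
#' @param max_circuits cap on the number of circuits; exceeding it is an
#'   error (a guard against combinatorial blow-up on dense networks).
#' @return a tibble with columns `id`, `nodes` (list of node-name vectors,
#'   in traversal order), `signs` (list of +1/-1 vectors, edge `i` linking
#'   node `i` to node `i + 1`, the last closing back to the first),
#'   `length`, `n_inhibitions` and `sign` (`"positive"`/`"negative"`).
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' circuits(toggle)
#' @export
circuits <- function(network, max_circuits = 100000) {
  n <- network$n
  nm <- network$nodes$name
  sign_mat <- matrix(0L, n, n)
  if (nrow(network$edges) > 0) {
    sign_mat[cbind(network$index[network$edges$from],
                   network$index[network$edges$to])] <- network$edges$sign
  }
  acc <- new.env(parent = emptyenv())
  acc$cycles <- list()
  emit <- function(path) {
    if (length(acc$cycles) >= max_circuits) {
      stop("more than ", max_circuits, " elementary circuits; raise ",
           "`max_circuits` if this is intended", call. = FALSE)
    }
    acc$cycles[[length(acc$cycles) + 1]] <- path
  }
  # self-loops first, as length-1 circuits
  for (v in which(diag(sign_mat) != 0L)) emit(v)
  # adjacency without self-loops, sorted for determinism
  adj <- lapply(seq_len(n), function(v) {
    sort(setdiff(which(sign_mat[v, ] != 0L), v))
  })
  johnson(adj, n, emit)
  cyc <- acc$cycles
  k <- length(cyc)
  nodes <- lapply(cyc, function(p) nm[p])
  signs <- lapply(cyc, function(p) {
    sign_mat[cbind(p, c(p[-1], p[1]))]
  })
  n_inh <- vapply(signs, function(s) sum(s == -1L), 1L)
  tibble::tibble(
    id = seq_len(k),
    nodes = nodes,
    signs = signs,
    length = vapply(cyc, length, 1L),
    n_inhibitions = n_inh,
    sign = ifelse(n_inh %% 2L == 0L, "positive", "negative")
  )
}

# Johnson's elementary-circuit search over an adjacency list (self-loops
# already removed).  Emits cycles as integer vertex paths starting at the
# smallest vertex of their SCC-restricted subgraph.
johnson <- function(adj, n, emit) {
  if (n == 0) return(invisible(NULL))
  for (s in seq_len(n)) {
    # SCC of the subgraph induced by {s..n} that contains s
    comp <- scc_of(adj, s, n)
    if (length(comp) == 0) next
    in_comp <- logical(n)
    in_comp[comp] <- TRUE
    A <- lapply(seq_len(n), function(v) {
      if (in_comp[v]) adj[[v]][in_comp[adj[[v]]]] else integer(0)
    })
    if (length(A[[s]]) == 0) next
    blocked <- logical(n)
    B <- lapply(seq_len(n), function(v) integer(0))
    stack <- integer(0)
    unblock <- function(u) {
      blocked[u] <<- FALSE
      for (w in B[[u]]) {
        if (blocked[w]) unblock(w)
      }
      B[[u]] <<- integer(0)
    }
    circuit <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in A[[v]]) {
        if (w == s) {
          emit(stack)
          found <- TRUE
        } else if (!blocked[w]) {
          if (circuit(w)) found <- TRUE
        }
      }
      if (found) {
        unblock(v)
      } else {
        for (w in A[[v]]) {
          if (!(v %in% B[[w]])) B[[w]] <<- c(B[[w]], v)
        }
      }
      stack <<- stack[-length(stack)]
      found
    }
    circuit(s)
  }
  invisible(NULL)
}

# vertices of the strongly connected component containing `s` in the
# subgraph induced by {s..n}; empty if that component is trivial
scc_of <- function(adj, s, n) {
  sub <- function(v) adj[[v]][adj[[v]] >= s]
  # forward reachability from s
  fwd <- logical(n)
  stack <- s
  fwd[s] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in sub(v)) {
      if (!fwd[w]) {
        fwd[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  # backward reachability from s (reverse edges)
  radj <- lapply(seq_len(n), function(v) integer(0))
  for (v in s:n) {
    for (w in sub(v)) radj[[w]] <- c(radj[[w]], v)
  }
  bwd <- logical(n)
  stack <- s
  bwd[s] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in radj[[v]]) {
      if (!bwd[w]) {
        bwd[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  comp <- which(fwd & bwd)
  if (length(comp) <= 1) integer(0) else comp
}

#' Sign of a circuit
#'
#' A circuit is positive iff it contains an even number of inhibitions
#' (zero included), so a double-negative toggle is positive and a
#' self-inhibition is negative.
#'
#' @param signs vector of edge signs (+1/-1) along the circuit, or one row
#'   of a [circuits()] tibble.
#' @return `"positive"` or `"negative"`.
#' @examples
#' circuit_sign(c(-1, -1))      # double-negative feedback: positive
#' circuit_sign(c(1, 1, -1))    # one inhibition: negative
#' @export
circuit_sign <- function(signs) {
  if (is.data.frame(signs)) signs <- signs$signs[[1]]
  signs <- unlist(signs)
  if (sum(signs == -1L) %% 2L == 0L) "positive" else "negative"
}

#' Retain only miRNAs that lie on a positive circuit
#'
#' miRNA interactions harvested from interaction databases are only worth
#' keeping in a Boolean stability model if the miRNA can actually affect
#' multistability, i.e. if it lies on at least one positive elementary
#' circuit with the network genes.  miRNAs lying only on negative circuits
#' (oscillatory motifs, poorly captured by a Boolean model) or on no
#' circuit at all (missing incoming or outgoing links) are removed together
#' with their edges.
#'
#' @param network a `grn`.
#' @param candidate_mirna_edges optional data frame of extra edges (columns
#'   `from`, `to`, `sign`) connecting candidate miRNAs to network genes;
#'   they are added before filtering.
#' @param max_circuits passed to [circuits()].
#' @return the filtered `grn`.
#' @export
filter_mirnas <- function(network, candidate_mirna_edges = NULL,
                          max_circuits = 100000) {
  if (!is.null(candidate_mirna_edges)) {
    edges <- dplyr::bind_rows(
      network$edges,
      dplyr::mutate(
        as.data.frame(candidate_mirna_edges),
        sign = parse_sign(.data$sign)
      )
    )
    kinds <- stats::setNames(network$nodes$kind, network$nodes$name)
    network <- grn(edges, kinds = kinds)
  }
  mirnas <- network$nodes$name[network$nodes$kind == "mirna"]
  if (length(mirnas) == 0) return(network)
  circ <- circuits(network, max_circuits = max_circuits)
  pos_members <- unique(unlist(circ$nodes[circ$sign == "positive"]))
  drop <- setdiff(mirnas, pos_members)
  induced_subnetwork(network, setdiff(network$nodes$name, drop))
}
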