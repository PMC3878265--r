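#' Fixed points of an isolated circuit
#'
#' Considers a circuit in isolation (each node regulated only by its
#' predecessor on the ring) and returns the restricted states that are
#' stable: `state[v] == state[u]` across an activating edge `u -> v` and
#' `state[v] == 1 - state[u]` across an inhibiting one, around the whole
#' ring.  A positive circuit has exactly two such states, complementary to
#' each other; a negative circuit has none (the parity contradicts around
#' the ring).  An activating self-loop yields `{0}` and `{1}`, an
#' inhibiting self-loop none.
#'
#' @param circuit a one-row slice of a [circuits()] tibble, or a list with
#'   elements `nodes` (character) and `signs` (+1/-1, edge `i` from node `i`
#'   to node `i + 1`, last edge closing the ring).
#' @return a list of named 0/1 vectors (possibly empty).
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' ring_fixed_points(circuits(toggle)[1, ])
#' @export
ring_fixed_points <- function(circuit) {
  cc <- as_circuit(circuit)
  k <- length(cc$nodes)
  out <- list()
  for (s1 in c(0L, 1L)) {
    s <- integer(k)
    s[1] <- s1
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        s[i + 1] <- if (cc$signs[i] == 1L) s[i] else 1L - s[i]
      }
    }
    closure <- if (cc$signs[k] == 1L) s[k] else 1L - s[k]
    if (closure == s[1]) {
      out[[length(out) + 1]] <- stats::setNames(s, cc$nodes)
    }
  }
  out
}

as_circuit <- function(circuit) {
  if (is.data.frame(circuit)) {
    stopifnot(nrow(circuit) == 1)
    list(nodes = circuit$nodes[[1]], signs = circuit$signs[[1]])
  } else {
    list(nodes = circuit$nodes, signs = as.integer(circuit$signs))
  }
}

#' Detect differentially expressed positive circuits (DEPCs)
#'
#' A positive circuit is a DEPC for a given ordered attractor pair iff
#' (i) every one of its genes changes state between the two attractors, and
#' (ii) its restricted states in both attractors are fixed points of the
#' circuit considered in isolation (see [ring_fixed_points()]); only then
#' is the circuit a stability element actually separating the two
#' phenotypes.  Because a positive circuit's two isolated fixed points are
#' complementary, under (i) it suffices that the initial restriction is an
#' isolated fixed point.
#'
#' @param network a `grn`.
#' @param circ a [circuits()] tibble for `network` (computed if `NULL`).
#' @param attractor_initial,attractor_final full network states (named 0/1
#'   vectors or single rows of an [attractors()] tibble); both must be
#'   fixed points and must differ.
#' @param strict_activator_rule see [boolean_update()].
#' @return a tibble with columns `depc_id`, `circuit_id`, `nodes`, `signs`,
#'   `length`, `n_inhibitions`, `state_initial`, `state_final` (the last
#'   two are lists of named restricted states).
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' att <- attractors(toggle)
#' detect_depcs(toggle, attractor_initial = att[1, ],
#'              attractor_final = att[2, ])
#' @export
detect_depcs <- function(network, attractor_initial, attractor_final,
                         circ = NULL, strict_activator_rule = FALSE) {
  si <- as_attractor_arg(network, attractor_initial)
  sf <- as_attractor_arg(network, attractor_final)
  for (s in list(si, sf)) {
    if (!identical(step_int(network, s, strict_activator_rule), s)) {
      stop("supplied state is not a fixed point of the network",
           call. = FALSE)
    }
  }
  if (identical(si, sf)) {
    stop("initial and final attractors are identical; no differential ",
         "expression is possible", call. = FALSE)
  }
  if (is.null(circ)) circ <- circuits(network)
  pos <- circ[circ$sign == "positive", , drop = FALSE]
  names_i <- stats::setNames(si, network$nodes$name)
  names_f <- stats::setNames(sf, network$nodes$name)
  keep <- logical(nrow(pos))
  st_i <- vector("list", nrow(pos))
  st_f <- vector("list", nrow(pos))
  for (r in seq_len(nrow(pos))) {
    g <- pos$nodes[[r]]
    ri <- names_i[g]
    rf <- names_f[g]
    if (any(ri == rf)) next  # criterion (i): all genes differential
    fps <- ring_fixed_points(pos[r, ])
    if (!any(vapply(fps, identical, TRUE, y = ri))) next  # criterion (ii)
    keep[r] <- TRUE
    st_i[[r]] <- ri
    st_f[[r]] <- rf
  }
  out <- pos[keep, , drop = FALSE]
  tibble::tibble(
    depc_id = seq_len(nrow(out)),
    circuit_id = out$id,
    nodes = out$nodes,
    signs = out$signs,
    length = out$length,
    n_inhibitions = out$n_inhibitions,
    state_initial = st_i[keep],
    state_final = st_f[keep]
  )
}

# accept a named state vector or a one-row attractors() slice
as_attractor_arg <- function(network, x) {
  if (is.data.frame(x)) {
    x <- unlist(x[1, setdiff(names(x), "id"), drop = TRUE])
  }
  as_state(network, x)
}
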