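#' Construct a signed Boolean gene regulatory network
#'
#' A `grn` is a directed graph whose edges are signed: `+1` for activation,
#' `-1` for inhibition.  Nodes are genes or miRNAs.  The object stores the
#' edge list as a tibble plus cached adjacency structures used by the
#' dynamics and search routines.
#'
#' Input edges may give the sign as `+1`/`-1`, `"+"`/`"-"`,
#' `"activation"`/`"inhibition"` or the arrow tokens `"->"`/`"-|"`.
#' At most one edge is allowed per ordered (from, to) pair: exact duplicate
#' rows are collapsed, while duplicate pairs with conflicting signs are an
#' input error (a Boolean edge cannot both activate and inhibit).
#'
#' @param edges data frame with columns `from`, `to`, `sign`.
#' @param kinds optional character vector, named by node, with values
#'   `"gene"` or `"mirna"`.  Nodes absent from `kinds` (or all nodes when it
#'   is `NULL`) are classified by name: names starting with `MIR`, `MIRNA`,
#'   `HSA-MIR` or `LET-7` (case-insensitive) are taken to be miRNAs.
#' @param nodes optional character vector of node names; defaults to the
#'   names appearing in `edges`.  Extra isolated nodes may be declared here.
#'
#' @return an object of class `grn`.
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' toggle
#' @export
grn <- function(edges, kinds = NULL, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "sign") %in% names(edges))) {
    stop("`edges` must have columns `from`, `to`, `sign`", call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- parse_sign(edges$sign)
  edges <- dplyr::distinct(edges[, c("from", "to", "sign")])
  dup <- edges[duplicated(edges[, c("from", "to")]), , drop = FALSE]
  if (nrow(dup) > 0) {
    stop("conflicting signs for edge(s): ",
         paste0(dup$from, " -> ", dup$to, collapse = ", "), call. = FALSE)
  }
  node_names <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  if (length(node_names) == 0L) node_names <- character(0)
  kind <- infer_kinds(node_names, kinds)
  net <- structure(
    list(
      nodes = tibble::tibble(name = node_names, kind = kind),
      edges = tibble::as_tibble(edges[order(edges$from, edges$to), ,
                                      drop = FALSE])
    ),
    class = "grn"
  )
  rebuild_cache(net)
}

parse_sign <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(1, -1))) {
      stop("numeric signs must be +1 or -1", call. = FALSE)
    }
    return(as.integer(x))
  }
  x <- trimws(as.character(x))
  map <- c("+" = 1L, "-" = -1L, "1" = 1L, "-1" = -1L,
           "activation" = 1L, "inhibition" = -1L,
           "->" = 1L, "-|" = -1L)
  out <- unname(map[tolower(x)])
  out[is.na(out)] <- unname(map[x[is.na(out)]])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognised sign token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

infer_kinds <- function(node_names, kinds) {
  auto <- ifelse(
    grepl("^(hsa-)?(mir|mirna|let-7)", node_names, ignore.case = TRUE),
    "mirna", "gene"
  )
  if (is.null(kinds)) return(auto)
  if (!is.null(dim(kinds))) {
    kinds <- stats::setNames(as.character(kinds$kind), kinds$name)
  }
  if (!all(kinds %in% c("gene", "mirna"))) {
    stop("node kinds must be 'gene' or 'mirna'", call. = FALSE)
  }
  out <- auto
  hit <- node_names %in% names(kinds)
  out[hit] <- unname(kinds[node_names[hit]])
  out
}

# cached: n, index lookup, per-node incoming activator/inhibitor index lists,
# dense 0/1 adjacency matrices used by the vectorised synchronous step
rebuild_cache <- function(net) {
  nm <- net$nodes$name
  n <- length(nm)
  idx <- stats::setNames(seq_len(n), nm)
  A_act <- matrix(0, n, n, dimnames = list(nm, nm))
  A_inh <- matrix(0, n, n, dimnames = list(nm, nm))
  if (nrow(net$edges) > 0) {
    ei <- cbind(idx[net$edges$to], idx[net$edges$from])
    pos <- net$edges$sign == 1L
    A_act[ei[pos, , drop = FALSE]] <- 1
    A_inh[ei[!pos, , drop = FALSE]] <- 1
  }
  net$n <- n
  net$index <- idx
  net$A_act <- A_act
  net$A_inh <- A_inh
  net$act_in <- lapply(seq_len(n), function(v) unname(which(A_act[v, ] == 1)))
  net$inh_in <- lapply(seq_len(n), function(v) unname(which(A_inh[v, ] == 1)))
  net$has_act <- vapply(net$act_in, length, 1L) > 0L
  net$in_deg <- vapply(net$act_in, length, 1L) + vapply(net$inh_in, length, 1L)
  net
}

#' @export
print.grn <- function(x, ...) {
  cat("<grn> ", sum(x$nodes$kind == "gene"), " genes + ",
      sum(x$nodes$kind == "mirna"), " miRNAs, ",
      nrow(x$edges), " interactions (",
      sum(x$edges$sign == 1L), " activations, ",
      sum(x$edges$sign == -1L), " inhibitions)\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname grn_tidiers
tidy.grn <- function(x, ...) {
  dplyr::mutate(
    x$edges,
    interaction = ifelse(.data$sign == 1L, "activation", "inhibition")
  )
}

#' Tidiers for `grn` objects
#'
#' `tidy()` returns the edge list with a human-readable interaction column;
#' `glance()` returns a one-row summary with the counts conventionally used
#' to describe signed regulatory networks (genes, miRNAs, interactions,
#' activations, inhibitions).
#'
#' @param x a `grn`.
#' @param ... unused.
#' @return a tibble.
#' @export
#' @rdname grn_tidiers
glance.grn <- function(x, ...) {
  tibble::tibble(
    genes = sum(x$nodes$kind == "gene"),
    mirnas = sum(x$nodes$kind == "mirna"),
    interactions = nrow(x$edges),
    activations = sum(x$edges$sign == 1L),
    inhibitions = sum(x$edges$sign == -1L)
  )
}

# coerce a user-supplied state (named vector / list / 1-row data frame) to an
# unnamed 0/1 integer vector in network node order
as_state <- function(network, state) {
  if (is.data.frame(state)) {
    stopifnot(nrow(state) == 1L)
    state <- unlist(state[1, , drop = TRUE])
  }
  state <- unlist(state)
  if (is.null(names(state)) || !all(nzchar(names(state)))) {
    if (length(state) != network$n) {
      stop("unnamed state must have one value per node", call. = FALSE)
    }
    names(state) <- network$nodes$name
  }
  missing <- setdiff(network$nodes$name, names(state))
  if (length(missing) > 0) {
    stop("state is missing node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- as.integer(state[network$nodes$name])
  if (!all(s %in% c(0L, 1L))) stop("state values must be 0 or 1", call. = FALSE)
  s
}

named_state <- function(network, s) {
  stats::setNames(as.integer(s), network$nodes$name)
}

#' Inhibitor-dominant Boolean update of a single node
#'
#' A node becomes active (1) iff none of its inhibitors is active and its
#' activator requirement holds.  The activator requirement is: at least one
#' activator is active, or — under the default-ON convention — the node has
#' no activators at all (its regulators are all inhibitors), in which case
#' the requirement is vacuously true.  With `strict_activator_rule = TRUE`
#' a node with zero active activators is always inactive, and a node with no
#' incoming edges at all is an error (it should have been pruned).
#'
#' @param network a `grn`.
#' @param state a full Boolean state (named 0/1 vector over the nodes).
#' @param node node name to update.
#' @param strict_activator_rule logical; disable the default-ON convention.
#' @return 0 or 1.
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' boolean_update(toggle, c(a = 1, b = 0), "b")  # inhibitor a is active -> 0
#' @export
boolean_update <- function(network, state, node,
                           strict_activator_rule = FALSE) {
  v <- network$index[[node]]
  if (is.null(v)) stop("unknown node: ", node, call. = FALSE)
  s <- as_state(network, state)
  if (strict_activator_rule && network$in_deg[v] == 0L) {
    stop("node '", node, "' has no regulators; prune input nodes first",
         call. = FALSE)
  }
  update_node_int(network, s, v, strict_activator_rule)
}

update_node_int <- function(network, s, v, strict) {
  if (any(s[network$inh_in[[v]]] == 1L)) return(0L)
  act <- network$act_in[[v]]
  if (length(act) > 0L) return(as.integer(any(s[act] == 1L)))
  if (strict) 0L else 1L
}

#' Synchronous update of the whole network
#'
#' All nodes are updated simultaneously from the same input state using the
#' inhibitor-dominant rule of [boolean_update()].  The map is deterministic;
#' its fixed points are the attractors of the model.
#'
#' @inheritParams boolean_update
#' @return the successor state as a named 0/1 integer vector.
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' synchronous_step(toggle, c(a = 0, b = 0))  # -> (1, 1)
#' synchronous_step(toggle, c(a = 1, b = 0))  # fixed point
#' @export
synchronous_step <- function(network, state, strict_activator_rule = FALSE) {
  s <- as_state(network, state)
  named_state(network, step_int(network, s, strict_activator_rule))
}

step_int <- function(network, s, strict = FALSE) {
  inh <- as.vector(network$A_inh %*% s)
  act <- as.vector(network$A_act %*% s)
  ok_act <- if (strict) act > 0 else (act > 0 | !network$has_act)
  as.integer(inh == 0 & ok_act)
}

#' Iteratively remove unregulated nodes
#'
#' Nodes without incoming edges carry no regulatory constraint in the model,
#' so they are pruned, together with any node left unregulated by earlier
#' removals, until every remaining node has in-degree at least one.  The
#' input network is not modified; the result may be empty.
#'
#' @param network a `grn`.
#' @return the maximal sub-`grn` in which every node has in-degree >= 1.
#' @examples
#' chain <- grn(data.frame(from = c("a", "b"), to = c("b", "c"), sign = 1))
#' prune_unregulated(chain)  # cascades to the empty network
#' @export
prune_unregulated <- function(network) {
  keep <- network$nodes$name
  edges <- network$edges
  repeat {
    regulated <- unique(edges$to)
    drop <- setdiff(keep, regulated)
    if (length(drop) == 0) break
    keep <- setdiff(keep, drop)
    edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  }
  kinds <- stats::setNames(network$nodes$kind, network$nodes$name)
  grn(edges, kinds = kinds[keep], nodes = keep)
}

# induced subgraph on a node subset, keeping kinds
induced_subnetwork <- function(network, keep) {
  edges <- network$edges[network$edges$from %in% keep &
                           network$edges$to %in% keep, , drop = FALSE]
  kinds <- stats::setNames(network$nodes$kind, network$nodes$name)
  grn(edges, kinds = kinds[keep], nodes = keep)
}

# network minus a set of edge row indices (into network$edges)
drop_edges <- function(network, edge_idx) {
  edges <- network$edges[setdiff(seq_len(nrow(network$edges)), edge_idx), ,
                         drop = FALSE]
  kinds <- stats::setNames(network$nodes$kind, network$nodes$name)
  grn(edges, kinds = kinds, nodes = network$nodes$name)
}

#' Normalize gene and miRNA names
#'
#' Uppercases names and strips the `hsa-` species prefix used in miRNA
#' tables, so that e.g. `hsa-miR-203` and `MIR203` tables can be matched.
#' Hyphens and underscores internal to names are preserved.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_gene_names <- function(x) {
  toupper(sub("^hsa-", "", x, ignore.case = TRUE))
}

#' Read / write a signed network file
#'
#' Two plain-text dialects are supported.  `"sif"` is a SIF-flavoured
#' 3-column TSV `source  sign-token  target` with tokens `->` (activation)
#' and `-|` (inhibition).  `"tsv"` is `source  target  sign` with sign in
#' `{+, -, activation, inhibition, 1, -1}`.  Reading and writing round-trip
#' up to row order.  Malformed rows are reported with their line number and
#' a duplicated (source, target) pair with conflicting signs is an error.
#'
#' @param path file path.
#' @param dialect `"sif"` or `"tsv"`.
#' @param normalize apply [normalize_gene_names()] to node names.
#' @param network a `grn` (for `write_grn`).
#' @return `read_grn` returns a `grn`; `write_grn` returns `path` invisibly.
#' @export
read_grn <- function(path, dialect = c("sif", "tsv"), normalize = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- keep[vapply(parts, length, 1L) != 3L]
  if (length(bad) > 0) {
    stop("malformed row (expected 3 fields) at line ", bad[1], " of ", path,
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  edges <- if (dialect == "sif") {
    data.frame(from = m[, 1], to = m[, 3], sign = m[, 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = m[, 1], to = m[, 2], sign = m[, 3],
               stringsAsFactors = FALSE)
  }
  if (normalize) {
    edges$from <- normalize_gene_names(edges$from)
    edges$to <- normalize_gene_names(edges$to)
  }
  grn(edges)
}

#' @rdname read_grn
#' @export
write_grn <- function(network, path, dialect = c("sif", "tsv")) {
  dialect <- match.arg(dialect)
  e <- network$edges
  lines <- if (dialect == "sif") {
    paste(e$from, ifelse(e$sign == 1L, "->", "-|"), e$to, sep = "\t")
  } else {
    paste(e$from, e$to, ifelse(e$sign == 1L, "+", "-"), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype expression-profile pair
#'
#' The file is a TSV with three columns: gene name, its binarized state
#' (0/1) in the initial phenotype, and its state in the final phenotype.
#' A header row is detected and skipped.  miRNAs are typically unmeasured
#' and simply absent from the file.
#'
#' @param path file path.
#' @param normalize apply [normalize_gene_names()].
#' @return a tibble with columns `gene`, `initial`, `final`.
#' @export
read_profiles <- function(path, normalize = FALSE) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 3) stop("profile file must have 3 columns", call. = FALSE)
  if (!suppressWarnings(all(!is.na(as.integer(df[1, 2:3]))))) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  names(df) <- c("gene", "initial", "final")
  df$gene <- as.character(df$gene)
  if (normalize) df$gene <- normalize_gene_names(df$gene)
  df$initial <- as.integer(df$initial)
  df$final <- as.integer(df$final)
  if (!all(c(df$initial, df$final) %in% c(0L, 1L))) {
    stop("profile states must be 0 or 1", call. = FALSE)
  }
  as_profiles(df)
}

#' Assemble an expression-profile pair
#'
#' @param x data frame with columns `gene`, `initial`, `final` (0/1 states
#'   of each measured gene in the two phenotypes).
#' @return a validated profiles tibble.
#' @export
as_profiles <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("gene", "initial", "final") %in% names(x)))
  if (anyDuplicated(x$gene)) stop("duplicated gene in profiles", call. = FALSE)
  x[, c("gene", "initial", "final")]
}

check_profiles <- function(network, profiles) {
  profiles <- as_profiles(profiles)
  extra <- setdiff(profiles$gene, network$nodes$name)
  if (length(extra) > 0) {
    stop("profile gene(s) not in network: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  profiles
}

#' Network plot
#'
#' Draws the signed digraph with ggplot2 (Fruchterman-Reingold layout from
#' igraph when available, circle layout otherwise).  Activating edges are
#' drawn in blue, inhibiting edges in red; miRNA nodes as triangles.
#'
#' @param object a `grn`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grn <- function(object, ...) {
  nm <- object$nodes$name
  n <- length(nm)
  if (requireNamespace("igraph", quietly = TRUE) && nrow(object$edges) > 0) {
    g <- igraph::graph_from_data_frame(object$edges[, c("from", "to")],
                                       vertices = nm)
    xy <- local({
      old <- .Random.seed_exists()
      on.exit(restore_rng(old))
      set.seed(1L)
      igraph::layout_with_fr(g)
    })
  } else {
    th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    xy <- cbind(cos(th), sin(th))
  }
  lay <- tibble::tibble(name = nm, x = xy[, 1], y = xy[, 2],
                        kind = object$nodes$kind)
  ed <- dplyr::left_join(object$edges, lay, by = c("from" = "name"))
  ed <- dplyr::left_join(ed, lay, by = c("to" = "name"),
                         suffix = c("", "end"))
  ed$interaction <- ifelse(ed$sign == 1L, "activation", "inhibition")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   colour = .data$interaction),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$kind), size = 3
    ) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(activation = "#2166AC", inhibition = "#B2182B")
    ) +
    ggplot2::scale_shape_manual(values = c(gene = 16, mirna = 17)) +
    ggplot2::theme_void()
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run expr with a locally seeded RNG, restoring the caller's RNG state;
# seed = NULL leaves the global stream untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- .Random.seed_exists()
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  force(expr)
}
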