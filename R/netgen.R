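#' Extract a subnetwork by greedy neighbour selection
#'
#' Grows a node set from a random seed node, repeatedly adding the outside
#' node with the most edges (in either direction) to the current set — the
#' preferential neighbour-attachment scheme used to cut study-sized
#' regulatory cores out of a genome-scale source network.  Ties are broken
#' uniformly at random under `seed`.  The induced subgraph is returned, so
#' every source edge between selected nodes, including self-regulations,
#' is retained with its sign.
#'
#' @param source a `grn`, typically large.
#' @param size number of nodes to select.
#' @param seed integer seed; the same seed reproduces the same subnetwork.
#' @return a `grn` on `size` nodes.
#' @export
extract_subnetwork <- function(source, size, seed = NULL) {
  n <- source$n
  if (size < 1 || size > n) {
    stop("`size` must be between 1 and the number of source nodes (", n, ")",
         call. = FALSE)
  }
  with_local_seed(seed, {
    nm <- source$nodes$name
    chosen <- sample(nm, 1)
    ends <- rbind(
      cbind(source$edges$from, source$edges$to),
      cbind(source$edges$to, source$edges$from)
    )
    while (length(chosen) < size) {
      outside_end <- ends[ends[, 1] %in% chosen & !(ends[, 2] %in% chosen), 2]
      if (length(outside_end) == 0) {
        stop("source network disconnected: cannot grow the selection to ",
             size, " nodes", call. = FALSE)
      }
      deg <- table(outside_end)
      top <- names(deg)[deg == max(deg)]
      pick <- if (length(top) == 1) top else sample(top, 1)
      chosen <- c(chosen, pick)
    }
    induced_subnetwork(source, chosen)
  })
}

#' Generate a random signed network with guaranteed multistability
#'
#' Samples a random signed digraph with exactly `n_edges` edges (of which
#' exactly `n_self_loops` are self-regulations) and exactly
#' `round(inhibition_fraction * n_edges)` inhibitions, then
#' rejection-resamples until the result contains at least one positive
#' circuit and at least two fixed-point attractors, so that the full
#' reprogramming pipeline is exercisable on it.
#'
#' @param n_genes number of nodes.
#' @param n_edges total number of edges (including self-loops).
#' @param inhibition_fraction fraction of edges that inhibit.
#' @param n_self_loops number of self-regulations.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap.
#' @return a `grn`.
#' @examples
#' random_signed_network(2, 2, inhibition_fraction = 1, seed = 1)  # a toggle
#' @export
random_signed_network <- function(n_genes, n_edges, inhibition_fraction = 0.4,
                                  n_self_loops = 0, seed = NULL,
                                  max_tries = 1000) {
  stopifnot(n_edges <= n_genes^2, n_self_loops <= min(n_genes, n_edges))
  nm <- sprintf("g%02d", seq_len(n_genes))
  n_inh <- round(inhibition_fraction * n_edges)
  with_local_seed(seed, {
    for (try in seq_len(max_tries)) {
      loops <- sample(nm, n_self_loops)
      n_free <- n_edges - n_self_loops
      all_pairs <- expand.grid(from = nm, to = nm,
                               stringsAsFactors = FALSE)
      all_pairs <- all_pairs[all_pairs$from != all_pairs$to, , drop = FALSE]
      pick <- sample(nrow(all_pairs), n_free)
      edges <- rbind(
        data.frame(from = loops, to = loops, stringsAsFactors = FALSE),
        all_pairs[pick, , drop = FALSE]
      )
      sgn <- rep(1L, n_edges)
      sgn[sample(n_edges, n_inh)] <- -1L
      edges$sign <- sgn
      net <- grn(edges, nodes = nm)
      circ <- tryCatch(circuits(net, max_circuits = 50000),
                       error = function(e) NULL)
      if (is.null(circ) || !any(circ$sign == "positive")) next
      att <- tryCatch(attractors(net), error = function(e) NULL)
      if (!is.null(att) && nrow(att) >= 2) return(net)
    }
    stop("no multistable network found in ", max_tries, " draws; adjust ",
         "n_edges / inhibition_fraction / n_self_loops", call. = FALSE)
  })
}

#' Generate a transcriptional-network-like source network
#'
#' Builds a synthetic genome-scale source network with the gross topology
#' of a bacterial transcriptional regulatory network: growth by
#' preferential attachment (new genes acquire regulators with probability
#' proportional to current out-degree, producing hub regulators and a
#' power-law-like out-degree tail), a largely feed-forward structure with
#' occasional back edges, a configurable repression fraction, and
#' autoregulation on a fraction of genes.  It is a synthetic stand-in used
#' by [run_insilico_study()]; extract study-sized cores from it with
#' [extract_subnetwork()].
#'
#' @param n_nodes number of genes.
#' @param inhibition_fraction fraction of inhibiting non-self edges.
#' @param self_loop_fraction fraction of genes with autoregulation.
#' @param self_activation_fraction fraction of the autoregulations that are
#'   activating.  Positive autoregulation is the minimal latch of Boolean
#'   multistability, so this knob controls how often extracted cores carry
#'   several attractors; free-standing negative autoregulation oscillates
#'   under the synchronous scheme and contributes no fixed point.
#' @param back_edge_fraction probability that an acquired regulator edge is
#'   reversed, creating feedback beyond autoregulation.
#' @param seed integer seed.
#' @return a `grn`.
#' @export
sample_source_network <- function(n_nodes = 400, inhibition_fraction = 0.4,
                                  self_loop_fraction = 0.2,
                                  self_activation_fraction = 0.8,
                                  back_edge_fraction = 0.03, seed = NULL) {
  stopifnot(n_nodes >= 5)
  with_local_seed(seed, {
    nm <- sprintf("g%03d", seq_len(n_nodes))
    from <- character(0)
    to <- character(0)
    out_deg <- rep(0, n_nodes)
    # seed motif: three mutually wired regulators
    for (p in list(c(1, 2), c(2, 3), c(3, 1))) {
      from <- c(from, nm[p[1]]); to <- c(to, nm[p[2]])
      out_deg[p[1]] <- out_deg[p[1]] + 1
    }
    for (t in 4:n_nodes) {
      k <- sample(1:4, 1, prob = c(0.45, 0.3, 0.15, 0.1))
      k <- min(k, t - 1)
      regs <- sample(t - 1, k, prob = out_deg[seq_len(t - 1)] + 1)
      for (r in regs) {
        if (stats::runif(1) < back_edge_fraction) {
          from <- c(from, nm[t]); to <- c(to, nm[r])
          out_deg[t] <- out_deg[t] + 1
        } else {
          from <- c(from, nm[r]); to <- c(to, nm[t])
          out_deg[r] <- out_deg[r] + 1
        }
      }
    }
    sgn <- ifelse(stats::runif(length(from)) < inhibition_fraction, -1L, 1L)
    loops <- sample(nm, round(self_loop_fraction * n_nodes))
    loop_sgn <- ifelse(
      stats::runif(length(loops)) < self_activation_fraction, 1L, -1L
    )
    edges <- data.frame(from = c(from, loops), to = c(to, loops),
                        sign = c(sgn, loop_sgn), stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
    grn(edges, nodes = nm)
  })
}

#' Read a regulator-target-effect table
#'
#' Parses a RegulonDB-style TSV with columns regulator, target and effect
#' (`+`, `-`, `+-` or `?`).  Rows with a dual (`+-`) or unknown (`?`)
#' effect have no Boolean counterpart and are dropped by default; set
#' `ambiguous` to `"activation"` or `"inhibition"` to keep them under that
#' reading.
#'
#' @param path file path.
#' @param ambiguous `"drop"`, `"activation"` or `"inhibition"`.
#' @param normalize apply [normalize_gene_names()].
#' @return a `grn`.
#' @export
read_regulon_table <- function(path, ambiguous = c("drop", "activation",
                                                   "inhibition"),
                               normalize = FALSE) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expected 3 columns", call. = FALSE)
  names(df)[1:3] <- c("from", "to", "effect")
  amb <- !(df$effect %in% c("+", "-"))
  if (ambiguous == "drop") {
    df <- df[!amb, , drop = FALSE]
  } else {
    df$effect[amb] <- if (ambiguous == "activation") "+" else "-"
  }
  edges <- data.frame(from = df$from, to = df$to, sign = df$effect,
                      stringsAsFactors = FALSE)
  if (normalize) {
    edges$from <- normalize_gene_names(edges$from)
    edges$to <- normalize_gene_names(edges$to)
  }
  # conflicting duplicates (a pair listed both + and -) are dropped: they
  # are the tabular form of a dual-sign interaction
  key <- paste(edges$from, edges$to)
  conf <- names(which(tapply(edges$sign, key,
                             function(s) length(unique(s)) > 1)))
  edges <- edges[!(key %in% conf), , drop = FALSE]
  grn(edges)
}

#' Run the in silico validation study
#'
#' Generates an ensemble of study-sized networks (by greedy extraction
#' from a source network), enumerates each network's fixed-point
#' attractors, and for every ordered attractor pair runs the full
#' reprogramming-determinant pipeline.  Two properties are tabulated: the
#' fraction of pairs separated by at least one DEPC, and the fraction of
#' pairs for which a validated minimal perturbation succeeds.  Per network
#' the fraction of genes appearing in any reprogramming-determinant
#' combination (the RD fraction) is recorded.
#'
#' Networks that fail a stage (single attractor, too many attractors,
#' circuit blow-up, capped searches) are logged in the per-pair `status`
#' column and counted, never fatal.
#'
#' @param n_networks number of networks to analyse.
#' @param size_range inclusive node-count range sampled uniformly.
#' @param source optional source `grn` shared by all extractions; by
#'   default every network is extracted from its own
#'   [sample_source_network()] draw (greedy extraction repeatedly climbs to
#'   the same hubs of a shared source, which would make the ensemble
#'   pseudo-replicated).
#' @param seed master seed; every per-network seed derives from it.
#' @param max_attractors skip pair analysis on networks with more
#'   attractors than this.
#' @param max_pairs at most this many ordered pairs analysed per network
#'   (taken in lexicographic order; truncation is flagged).
#' @param max_depc_subset cap on the DEPC subset size searched per pair.
#' @param max_circuits per-network circuit cap.
#' @param step_cap simulation step cap.
#' @return an `insilico_study` object: list with `pairs` (one row per
#'   ordered attractor pair), `networks` (one row per network) and
#'   `summary` (one row).
#' @export
run_insilico_study <- function(n_networks = 50, size_range = c(20, 40),
                               source = NULL, seed = NULL,
                               max_attractors = 16, max_pairs = 30,
                               max_depc_subset = 4, max_circuits = 20000,
                               step_cap = 1000) {
  with_local_seed(seed, {
    net_seeds <- sample.int(2^31 - 1, n_networks)
    src_seeds <- sample.int(2^31 - 1, n_networks)
    pair_rows <- list()
    net_rows <- list()
    sizes <- seq(size_range[1], size_range[2])
    for (i in seq_len(n_networks)) {
      size <- sizes[sample.int(length(sizes), 1)]
      src_i <- if (is.null(source)) {
        sample_source_network(seed = src_seeds[i])
      } else {
        source
      }
      res <- tryCatch(
        study_one_network(i, src_i, size, net_seeds[i], max_attractors,
                          max_pairs, max_depc_subset, max_circuits,
                          step_cap),
        error = function(e) {
          list(pairs = tibble::tibble(
                 network = i, n_genes = size, initial = NA_integer_,
                 final = NA_integer_, n_depcs = NA_integer_,
                 depc_exists = NA, rd_success = NA,
                 rd_size = NA_integer_, status = "error"),
               network = tibble::tibble(
                 network = i, n_genes = size, n_edges = NA_integer_,
                 n_attractors = NA_integer_, n_pairs = 0L,
                 rd_fraction = NA_real_, status = "error"))
        }
      )
      pair_rows[[i]] <- res$pairs
      net_rows[[i]] <- res$network
    }
    pairs <- dplyr::bind_rows(pair_rows)
    networks <- dplyr::bind_rows(net_rows)
    analysed <- pairs[!is.na(pairs$depc_exists), , drop = FALSE]
    with_depc <- analysed[analysed$depc_exists, , drop = FALSE]
    summary <- tibble::tibble(
      n_networks = n_networks,
      n_multistable = sum(networks$n_attractors >= 2, na.rm = TRUE),
      n_pairs_analysed = nrow(analysed),
      depc_exists_fraction = if (nrow(analysed) > 0)
        mean(analysed$depc_exists) else NA_real_,
      rd_success_fraction = if (nrow(with_depc) > 0)
        mean(with_depc$rd_success) else NA_real_,
      mean_rd_fraction = mean(networks$rd_fraction, na.rm = TRUE),
      mean_max_rd_size = mean(
        tapply(analysed$rd_size, analysed$network, max, na.rm = TRUE),
        na.rm = TRUE),
      mean_min_rd_size = mean(
        tapply(analysed$rd_size, analysed$network, min, na.rm = TRUE),
        na.rm = TRUE)
    )
    structure(list(pairs = pairs, networks = networks, summary = summary),
              class = "insilico_study")
  })
}

study_one_network <- function(i, source, size, net_seed, max_attractors,
                              max_pairs, max_depc_subset, max_circuits,
                              step_cap) {
  # analysis operates on the regulated core: unregulated genes (and the
  # cascade they leave behind) carry no stability constraint.  The RD
  # fraction stays relative to the whole extracted network.
  raw <- extract_subnetwork(source, size, seed = net_seed)
  net <- prune_unregulated(raw)
  if (net$n < 2) {
    return(list(
      pairs = tibble::tibble(network = i, n_genes = raw$n,
                             initial = NA_integer_, final = NA_integer_,
                             n_depcs = NA_integer_, depc_exists = NA,
                             rd_success = NA, rd_size = NA_integer_,
                             status = "empty_core"),
      network = tibble::tibble(network = i, n_genes = raw$n,
                               n_core = net$n,
                               n_edges = nrow(net$edges),
                               n_attractors = NA_integer_, n_pairs = 0L,
                               rd_fraction = NA_real_,
                               status = "empty_core")))
  }
  att <- attractors(net, mode = "backtracking")
  base_pair <- function(status, initial = NA_integer_, final = NA_integer_,
                        n_depcs = NA_integer_, depc_exists = NA,
                        rd_success = NA, rd_size = NA_integer_) {
    tibble::tibble(network = i, n_genes = net$n, initial = initial,
                   final = final, n_depcs = n_depcs,
                   depc_exists = depc_exists, rd_success = rd_success,
                   rd_size = rd_size, status = status)
  }
  net_row <- function(status, n_pairs, rd_fraction = NA_real_) {
    tibble::tibble(network = i, n_genes = raw$n, n_core = net$n,
                   n_edges = nrow(net$edges),
                   n_attractors = nrow(att), n_pairs = n_pairs,
                   rd_fraction = rd_fraction, status = status)
  }
  if (nrow(att) < 2) {
    return(list(pairs = base_pair("no_pair"),
                network = net_row("no_pair", 0L)))
  }
  if (nrow(att) > max_attractors) {
    return(list(pairs = base_pair("too_many_attractors"),
                network = net_row("too_many_attractors", 0L)))
  }
  circ <- tryCatch(circuits(net, max_circuits = max_circuits),
                   error = function(e) NULL)
  if (is.null(circ)) {
    return(list(pairs = base_pair("circuit_cap"),
                network = net_row("circuit_cap", 0L)))
  }
  grid <- expand.grid(initial = att$id, final = att$id)
  grid <- grid[grid$initial != grid$final, , drop = FALSE]
  grid <- grid[order(grid$initial, grid$final), , drop = FALSE]
  truncated <- nrow(grid) > max_pairs
  grid <- utils::head(grid, max_pairs)
  rd_genes <- character(0)
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    si <- as_attractor_arg(net, att[att$id == grid$initial[r], ])
    sf <- as_attractor_arg(net, att[att$id == grid$final[r], ])
    depcs <- detect_depcs(net, si, sf, circ = circ)
    status <- if (truncated) "pair_cap" else "ok"
    if (nrow(depcs) == 0) {
      rows[[r]] <- base_pair("no_depc", grid$initial[r], grid$final[r],
                             0L, FALSE, FALSE)
      next
    }
    rd <- tryCatch(
      rd_for_pair(net, si, sf, depcs, step_cap, max_depc_subset),
      error = function(e) NULL
    )
    if (is.null(rd) || nrow(rd) == 0 || !any(rd$validated)) {
      rows[[r]] <- base_pair("rd_failed", grid$initial[r], grid$final[r],
                             nrow(depcs), TRUE, FALSE)
    } else {
      ok <- rd[rd$validated, , drop = FALSE]
      rd_genes <- union(rd_genes, unlist(ok$genes))
      rows[[r]] <- base_pair(status, grid$initial[r], grid$final[r],
                             nrow(depcs), TRUE, TRUE, min(ok$size))
    }
  }
  pairs <- dplyr::bind_rows(rows)
  list(
    pairs = pairs,
    network = net_row(if (truncated) "pair_cap" else "ok", nrow(grid),
                      rd_fraction = length(rd_genes) / raw$n)
  )
}

# pipeline tail for one attractor pair inside the study (caps applied);
# when no DEPC subset within the size cap works but perturbing every DEPC
# does, fall back to pruning that full gene set — still validated, at the
# cost of exact minimum-cardinality
rd_for_pair <- function(net, si, sf, depcs, step_cap, max_depc_subset) {
  sets <- tryCatch(
    minimal_depc_sets(net, si, sf, depcs, step_cap = step_cap,
                      max_set_size = max_depc_subset),
    error = function(e) NULL
  )
  if (is.null(sets)) {
    all_genes <- sort(unique(unlist(depcs$nodes)))
    cl <- clamps_for(net, all_genes, sf)
    if (!verify_transition(net, si, sf, cl, step_cap = step_cap)) {
      return(tibble::tibble(genes = list(), size = integer(0),
                            validated = logical(0)))
    }
    pruned <- prune_redundant_targets(net, si, sf, all_genes,
                                      step_cap = step_cap)
    return(tibble::tibble(
      genes = list(pruned), size = length(pruned),
      validated = verify_transition(net, si, sf,
                                    clamps_for(net, pruned, sf),
                                    step_cap = step_cap)
    ))
  }
  combos <- minimal_gene_combinations(sets, depcs)
  passes <- function(genes) {
    verify_transition(net, si, sf, clamps_for(net, genes, sf),
                      step_cap = step_cap)
  }
  working <- Filter(passes, combos)
  if (length(working) == 0) {
    working <- lapply(sets, function(S) {
      sort(unique(unlist(depcs$nodes[match(S, depcs$depc_id)])))
    })
  }
  final_sets <- list()
  seen <- character(0)
  for (cc in working) {
    pruned <- prune_redundant_targets(net, si, sf, cc, step_cap = step_cap)
    key <- paste(pruned, collapse = "\r")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      final_sets[[length(final_sets) + 1]] <- pruned
    }
  }
  rows <- lapply(final_sets, function(gene_set) {
    cl <- clamps_for(net, gene_set, sf)
    n_genes <- length(gene_set)
    tibble::tibble(genes = list(gene_set), size = n_genes,
                   validated = verify_transition(net, si, sf, cl,
                                                 step_cap = step_cap))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.insilico_study <- function(x, ...) {
  s <- x$summary
  cat("<insilico_study> ", s$n_networks, " networks (",
      s$n_multistable, " multistable), ", s$n_pairs_analysed,
      " ordered attractor pairs analysed\n", sep = "")
  cat("  DEPC exists for ", round(100 * s$depc_exists_fraction, 1),
      "% of pairs; validated RD for ",
      round(100 * s$rd_success_fraction, 1),
      "% of DEPC-separated pairs\n", sep = "")
  cat("  mean RD gene fraction per network: ",
      round(100 * s$mean_rd_fraction, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname study_tidiers
tidy.insilico_study <- function(x, ...) {
  x$pairs
}

#' Tidiers for in silico study reports
#'
#' `tidy()` returns the per-pair table, `glance()` the one-row summary.
#'
#' @param x an `insilico_study`.
#' @param ... unused.
#' @return a tibble.
#' @export
#' @rdname study_tidiers
glance.insilico_study <- function(x, ...) {
  x$summary
}
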