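#' Verify a reprogramming perturbation by simulation
#'
#' Simulates the network response to clamping a set of genes at their
#' final-attractor values.  Default (transient) semantics mirror a
#' reprogramming cocktail: (1) from the initial attractor, the clamped
#' genes are held fixed and the rest of the network is updated
#' synchronously until the clamped system reaches a fixed point; (2) the
#' clamps are released and the free system is run on to an attractor.  The
#' perturbation succeeds iff the phase-2 terminal state is exactly the
#' target attractor — i.e. the perturbation both destabilized the initial
#' phenotype and the final phenotype is self-sustaining.  A cycle or a hit
#' step cap in either phase counts as failure.  With
#' `permanent_clamp = TRUE` the clamps are never released and success means
#' the clamped system settles exactly on the target attractor.
#'
#' @param network a `grn`.
#' @param initial,final full network states (named 0/1 vectors or one-row
#'   [attractors()] slices); the transition to test is `initial -> final`.
#' @param clamps named 0/1 vector of genes to perturb, normally each gene's
#'   value in the final attractor ("activate" if 1, "repress" if 0).
#' @param step_cap per-phase step limit.
#' @param permanent_clamp keep the clamps applied forever.
#' @param strict_activator_rule see [boolean_update()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' verify_transition(toggle, c(a = 1, b = 0), c(a = 0, b = 1), c(b = 1))
#' @export
verify_transition <- function(network, initial, final, clamps,
                              step_cap = 1000, permanent_clamp = FALSE,
                              strict_activator_rule = FALSE) {
  verify_transition_full(network, initial, final, clamps, step_cap,
                         permanent_clamp, strict_activator_rule)$success
}

verify_transition_full <- function(network, initial, final, clamps,
                                   step_cap = 1000, permanent_clamp = FALSE,
                                   strict = FALSE) {
  si <- as_attractor_arg(network, initial)
  sf <- as_attractor_arg(network, final)
  ph1 <- simulate_to_attractor(network, named_state(network, si),
                               clamp = clamps, step_cap = step_cap,
                               strict_activator_rule = strict)
  reached <- final_state(ph1)
  if (ph1$terminal != "fixed_point") {
    return(list(success = FALSE, reached = reached))
  }
  if (!permanent_clamp) {
    ph2 <- simulate_to_attractor(network, reached, clamp = NULL,
                                 step_cap = step_cap,
                                 strict_activator_rule = strict)
    reached <- final_state(ph2)
    if (ph2$terminal != "fixed_point") {
      return(list(success = FALSE, reached = reached))
    }
  }
  list(success = identical(unname(reached), unname(sf)), reached = reached)
}

# clamp vector for a gene set: each gene held at its final-attractor value
clamps_for <- function(network, genes, final_state_int) {
  stats::setNames(final_state_int[unname(network$index[genes])], genes)
}

#' Minimum DEPC subsets able to effect a transition
#'
#' Searches, in increasing subset size, for all minimum-cardinality subsets
#' of the DEPCs such that simultaneously clamping every gene of every
#' circuit in the subset (to final-attractor values) makes
#' [verify_transition()] succeed.  The search stops at the first size with
#' a success, so all returned subsets have that minimum size.  This
#' exhaustive size-ordered search is exact; the DEPC counts seen in
#' practice (a dozen or fewer) keep it cheap.
#'
#' @inheritParams verify_transition
#' @param depcs a [detect_depcs()] tibble for the same attractor pair.
#' @param max_set_size optional cap on the subset size searched.
#' @return a list of integer vectors of `depc_id`s.
#' @export
minimal_depc_sets <- function(network, initial, final, depcs,
                              step_cap = 1000, permanent_clamp = FALSE,
                              strict_activator_rule = FALSE,
                              max_set_size = Inf) {
  if (nrow(depcs) == 0) stop("no DEPCs supplied", call. = FALSE)
  si <- as_attractor_arg(network, initial)
  sf <- as_attractor_arg(network, final)
  best <- list(frac = -1, reached = NULL, set = NULL)
  for (size in seq_len(min(nrow(depcs), max_set_size))) {
    hits <- list()
    sets <- utils::combn(depcs$depc_id, size, simplify = FALSE)
    for (S in sets) {
      genes <- sort(unique(unlist(depcs$nodes[match(S, depcs$depc_id)])))
      cl <- clamps_for(network, genes, sf)
      res <- verify_transition_full(network, si, sf, cl, step_cap,
                                    permanent_clamp, strict_activator_rule)
      if (res$success) {
        hits[[length(hits) + 1]] <- S
      } else {
        frac <- mean(res$reached == sf)
        if (frac > best$frac) best <- list(frac = frac, reached = res$reached,
                                           set = S)
      }
    }
    if (length(hits) > 0) return(hits)
  }
  stop("no DEPC subset of any size achieves the transition; best attempt ",
       "(DEPCs ", paste(best$set, collapse = ","), ") reached a state ",
       "matching the target on ", round(100 * best$frac, 1), "% of genes",
       call. = FALSE)
}

#' Minimal gene combinations covering a DEPC set
#'
#' Greedy set cover with tie branching: repeatedly pick the gene occurring
#' in the most not-yet-targeted DEPCs of the set; whenever several genes
#' tie, the computation branches into every tied choice, so all alternative
#' greedy covers are produced.  Each returned combination contains at least
#' one gene from every DEPC of the set.
#'
#' @param depc_sets list of DEPC-id vectors (as from [minimal_depc_sets()]).
#' @param depcs the [detect_depcs()] tibble giving each DEPC's genes.
#' @param max_branches guard on the number of alternative covers explored.
#' @return a list of unique sorted character vectors of gene names; each
#'   element carries the originating DEPC set in attribute `"depc_set"`.
#' @export
minimal_gene_combinations <- function(depc_sets, depcs,
                                      max_branches = 10000) {
  out <- list()
  seen <- character(0)
  for (S in depc_sets) {
    members <- depcs$nodes[match(S, depcs$depc_id)]
    covers <- greedy_covers(members, max_branches)
    for (cc in covers) {
      key <- paste(cc, collapse = "\r")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        attr(cc, "depc_set") <- S
        out[[length(out) + 1]] <- cc
      }
    }
  }
  out
}

greedy_covers <- function(members, max_branches) {
  acc <- new.env(parent = emptyenv())
  acc$covers <- list()
  acc$keys <- character(0)
  recurse <- function(uncovered, chosen) {
    if (length(acc$covers) >= max_branches) {
      stop("more than ", max_branches, " alternative gene covers; the tie ",
           "branching exploded", call. = FALSE)
    }
    if (length(uncovered) == 0) {
      key <- paste(sort(chosen), collapse = "\r")
      if (!(key %in% acc$keys)) {
        acc$keys <- c(acc$keys, key)
        acc$covers[[length(acc$covers) + 1]] <- sort(chosen)
      }
      return(invisible(NULL))
    }
    counts <- table(unlist(members[uncovered]))
    top <- sort(names(counts)[counts == max(counts)])
    for (g in top) {
      still <- uncovered[!vapply(members[uncovered],
                                 function(m) g %in% m, TRUE)]
      recurse(still, c(chosen, g))
    }
    invisible(NULL)
  }
  recurse(seq_along(members), character(0))
  acc$covers
}

#' Drop redundant perturbation targets
#'
#' DEPCs regulated by other DEPCs flip on their own once their regulators
#' are perturbed, so their genes need not be clamped directly.  Each gene
#' of a working combination is tried for removal in ascending lexicographic
#' order: the transition is re-simulated with that gene's clamp omitted and
#' the gene is dropped permanently if the transition still succeeds; the
#' scan repeats until no removal succeeds.
#'
#' @inheritParams verify_transition
#' @param genes character vector of clamped genes; the combination must
#'   already pass [verify_transition()].
#' @return the surviving (sorted) character vector of genes.
#' @export
prune_redundant_targets <- function(network, initial, final, genes,
                                    step_cap = 1000, permanent_clamp = FALSE,
                                    strict_activator_rule = FALSE) {
  sf <- as_attractor_arg(network, final)
  genes <- sort(genes)
  repeat {
    dropped <- FALSE
    for (g in genes) {
      rest <- setdiff(genes, g)
      if (length(rest) == 0) next
      cl <- clamps_for(network, rest, sf)
      if (verify_transition(network, initial, final, cl, step_cap,
                            permanent_clamp, strict_activator_rule)) {
        genes <- rest
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  genes
}

# reduce a passing gene set to its minimal passing subsets (exhaustive over
# proper subsets, ascending size); returns the set itself when no proper
# subset passes
minimalize_set <- function(network, initial, final, genes, step_cap,
                           permanent_clamp, strict) {
  sf <- as_attractor_arg(network, final)
  k <- length(genes)
  if (k > 1) {
    for (size in seq_len(k - 1)) {
      hits <- list()
      for (sub in utils::combn(sort(genes), size, simplify = FALSE)) {
        cl <- clamps_for(network, sub, sf)
        if (verify_transition(network, initial, final, cl, step_cap,
                              permanent_clamp, strict)) {
          hits[[length(hits) + 1]] <- sub
        }
      }
      if (length(hits) > 0) return(hits)
    }
  }
  list(sort(genes))
}

#' Find all minimal reprogramming-determinant combinations
#'
#' End-to-end differential stability analysis for one cellular transition:
#' enumerate attractors, pick the initial/final pair (from binarized
#' phenotype profiles or given explicitly), enumerate elementary circuits,
#' detect the DEPCs separating the pair, find the minimum DEPC subsets able
#' to effect the transition, cover them with greedily chosen genes
#' (branching on ties, so alternative recipes are kept), drop redundant
#' targets by re-simulation, and validate every surviving combination.
#'
#' @param network a `grn` (already contextualized / consistent with the
#'   profiles).
#' @param profiles a profiles tibble; the attractor pair is then chosen by
#'   [match_attractors_to_profiles()].  Alternatively supply `initial` and
#'   `final`.
#' @param initial,final attractor ids (into this network's [attractors()]
#'   table) or full named states.
#' @inheritParams verify_transition
#' @param mode attractor enumeration mode, see [attractors()].
#' @param max_circuits see [circuits()].
#' @return a tibble of class `rd_result` with one row per alternative
#'   minimal combination: `rd_id`, `genes` (list), `size`, `perturbation`
#'   (e.g. `"activate SNAI1"`), `clamps` (list of named 0/1 vectors),
#'   `covered_depcs` (list of `depc_id`s the genes belong to), `validated`.
#'   Rows are ordered by size then lexicographically.  Attributes
#'   `attractors`, `match`, `depcs` carry the intermediate results.
#' @examples
#' toggle <- grn(data.frame(from = c("a", "b"), to = c("b", "a"), sign = -1))
#' find_reprogramming_determinants(toggle, initial = 2, final = 1)
#' @export
find_reprogramming_determinants <- function(network, profiles = NULL,
                                            initial = NULL, final = NULL,
                                            step_cap = 1000,
                                            permanent_clamp = FALSE,
                                            strict_activator_rule = FALSE,
                                            mode = "auto",
                                            max_circuits = 100000) {
  att <- attractors(network, mode = mode,
                    strict_activator_rule = strict_activator_rule)
  match_row <- NULL
  if (!is.null(profiles)) {
    match_row <- match_attractors_to_profiles(att, profiles)
    si <- as_attractor_arg(network, att[att$id == match_row$initial_id, ])
    sf <- as_attractor_arg(network, att[att$id == match_row$final_id, ])
  } else {
    if (is.null(initial) || is.null(final)) {
      stop("supply either `profiles` or both `initial` and `final`",
           call. = FALSE)
    }
    si <- resolve_attractor(network, att, initial)
    sf <- resolve_attractor(network, att, final)
  }
  circ <- circuits(network, max_circuits = max_circuits)
  depcs <- detect_depcs(network, si, sf, circ = circ,
                        strict_activator_rule = strict_activator_rule)
  if (nrow(depcs) == 0) {
    stop("no differentially expressed positive circuit separates the two ",
         "attractors", call. = FALSE)
  }
  sets <- minimal_depc_sets(network, si, sf, depcs, step_cap,
                            permanent_clamp, strict_activator_rule)
  combos <- minimal_gene_combinations(sets, depcs)
  # a greedy cover clamps fewer genes than the DEPC set it came from, so it
  # must re-validate; if no cover of any minimal DEPC set passes, fall back
  # to the full (verified) gene sets of the minimal DEPC sets
  passes <- function(genes) {
    verify_transition(network, si, sf, clamps_for(network, genes, sf),
                      step_cap, permanent_clamp, strict_activator_rule)
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
    pruned <- prune_redundant_targets(network, si, sf, cc, step_cap,
                                      permanent_clamp, strict_activator_rule)
    for (ms in minimalize_set(network, si, sf, pruned, step_cap,
                              permanent_clamp, strict_activator_rule)) {
      key <- paste(ms, collapse = "\r")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        final_sets[[length(final_sets) + 1]] <- ms
      }
    }
  }
  rows <- lapply(final_sets, function(gene_set) {
    cl <- clamps_for(network, gene_set, sf)
    covered <- depcs$depc_id[vapply(depcs$nodes,
                                    function(m) any(gene_set %in% m), TRUE)]
    n_genes <- length(gene_set)
    pert <- paste(ifelse(cl == 1L, "activate", "repress"), gene_set,
                  collapse = ", ")
    tibble::tibble(
      genes = list(gene_set),
      size = n_genes,
      perturbation = pert,
      clamps = list(cl),
      covered_depcs = list(covered),
      validated = verify_transition(network, si, sf, cl, step_cap,
                                    permanent_clamp, strict_activator_rule)
    )
  })
  out <- dplyr::bind_rows(rows)
  key <- vapply(out$genes, paste, "", collapse = "\r")
  out <- out[order(out$size, key), , drop = FALSE]
  out <- dplyr::bind_cols(tibble::tibble(rd_id = seq_len(nrow(out))), out)
  attr(out, "attractors") <- att
  attr(out, "match") <- match_row
  attr(out, "depcs") <- depcs
  attr(out, "initial") <- named_state(network, si)
  attr(out, "final") <- named_state(network, sf)
  class(out) <- c("rd_result", class(out))
  out
}

resolve_attractor <- function(network, att, x) {
  if (is.numeric(x) && length(x) == 1) {
    as_attractor_arg(network, att[att$id == x, ])
  } else {
    as_attractor_arg(network, x)
  }
}

#' @export
#' @rdname rd_tidiers
glance.rd_result <- function(x, ...) {
  tibble::tibble(
    n_combinations = nrow(x),
    min_size = if (nrow(x) > 0) min(x$size) else NA_integer_,
    max_size = if (nrow(x) > 0) max(x$size) else NA_integer_,
    n_depcs = nrow(attr(x, "depcs")),
    n_attractors = nrow(attr(x, "attractors")),
    all_validated = all(x$validated)
  )
}

#' Summaries of a reprogramming-determinant search
#'
#' `glance()` condenses an `rd_result` into one row: number of alternative
#' minimal combinations, their size range, how many DEPCs separated the
#' attractor pair, and whether every combination re-validated.
#'
#' @param x an `rd_result` from [find_reprogramming_determinants()].
#' @param ... unused.
#' @return a one-row tibble.
#' @name rd_tidiers
NULL
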