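#' Agreement between network attractors and phenotype profiles
#'
#' Enumerates the attractors of the network and scores the best ordered
#' attractor pair against the initial/final profiles (see
#' [match_attractors_to_profiles()]): the fraction of measured gene states
#' that the dynamical model explains, averaged over the two phenotypes.
#' Networks with fewer than two attractors (or none of the measured genes)
#' cannot represent both phenotypes and score 0.
#'
#' @param network a `grn`.
#' @param profiles a profiles tibble.
#' @param mode attractor enumeration mode, see [attractors()].
#' @param strict_activator_rule see [boolean_update()].
#' @return a fraction in `[0, 1]`.
#' @export
contextualization_score <- function(network, profiles, mode = "auto",
                                    strict_activator_rule = FALSE) {
  if (network$n == 0) return(0)
  att <- attractors(network, mode = mode,
                    strict_activator_rule = strict_activator_rule)
  if (nrow(att) < 2) return(0)
  m <- tryCatch(match_attractors_to_profiles(att, profiles),
                error = function(e) NULL)
  if (is.null(m)) 0 else m$score
}

#' Contextualize a literature-derived network to expression profiles
#'
#' Literature-assembled networks mix regulations observed across many cell
#' types, so their attractors rarely match the phenotypes under study.
#' Contextualization prunes inconsistent interactions with an
#' estimation-of-distribution evolutionary algorithm (EDA): each candidate
#' is an edge-removal mask; candidates are sampled from per-edge removal
#' probabilities coupled with per-positive-circuit retention probabilities
#' (a circuit kept intact protects all of its edges), scored by
#' [contextualization_score()] after re-pruning any node the removals left
#' unregulated, and the distribution is pulled toward the elite fraction of
#' each generation.  The best candidate ever seen is kept (elitism), so the
#' reported score never decreases, and the loop stops early on a perfect
#' score.  The unpruned network itself is always evaluated, so an
#' already-consistent network is returned unchanged.
#'
#' Probabilities are clipped away from 0 and 1 (`p_min`) to keep
#' exploration alive.  Only pruning is performed — edges are never added —
#' and interactions not participating in any circuit cannot be assessed by
#' a stability criterion; they are removed only when their removal does not
#' hurt the score.
#'
#' @inheritParams contextualization_score
#' @param population candidates sampled per generation.
#' @param elite_fraction fraction of the population used to update the
#'   distribution.
#' @param learning_rate pull of each update toward the elite frequencies.
#' @param p_min probability clip.
#' @param generations maximum number of generations.
#' @param seed integer seed; identical seeds give identical results.  The
#'   caller's RNG state is preserved.
#' @param max_circuits see [circuits()].
#' @return an object of class `grn_contextualization`: list with `network`
#'   (best pruned network), `score`, `removed_edges` (tibble), `history`
#'   (per-generation best/mean score), `converged`, `config`.
#' @examples
#' toggle_bad <- grn(data.frame(from = c("a", "b", "a"),
#'                              to = c("b", "a", "a"),
#'                              sign = c(-1, -1, 1)))
#' prof <- as_profiles(data.frame(gene = c("a", "b"),
#'                                initial = c(1, 0), final = c(0, 1)))
#' ctx <- contextualize(toggle_bad, prof, generations = 10, seed = 1)
#' ctx$score
#' @export
contextualize <- function(network, profiles, population = 50,
                          elite_fraction = 0.2, learning_rate = 0.3,
                          p_min = 0.02, generations = 100, seed = NULL,
                          mode = "auto", strict_activator_rule = FALSE,
                          max_circuits = 100000) {
  profiles <- check_profiles(network, profiles)
  circ <- circuits(network, max_circuits = max_circuits)
  if (nrow(circ) == 0) {
    stop("network has no circuit: contextualization operates on stability ",
         "and cannot assess a circuit-free network", call. = FALSE)
  }
  m <- nrow(network$edges)
  edge_key <- paste(network$edges$from, network$edges$to)
  # positive circuits' edge membership couples into the sampling
  pos <- circ[circ$sign == "positive", , drop = FALSE]
  circ_edges <- lapply(seq_len(nrow(pos)), function(r) {
    nds <- pos$nodes[[r]]
    match(paste(nds, c(nds[-1], nds[1])), edge_key)
  })
  edge_circuits <- lapply(seq_len(m), function(e) {
    which(vapply(circ_edges, function(ce) e %in% ce, TRUE))
  })
  score_mask <- local({
    cache <- new.env(parent = emptyenv(), hash = TRUE)
    function(mask) {
      key <- paste0("m", paste(which(mask), collapse = ","))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      net2 <- prune_unregulated(drop_edges(network, which(mask)))
      sc <- contextualization_score(net2, profiles, mode = mode,
                                    strict_activator_rule =
                                      strict_activator_rule)
      assign(key, sc, envir = cache)
      sc
    }
  })
  n_elite <- max(1L, ceiling(elite_fraction * population))
  with_local_seed(seed, {
    p_rm <- rep(0.5, m)
    r_keep <- rep(0.8, length(circ_edges))
    best <- list(mask = rep(FALSE, m), score = score_mask(rep(FALSE, m)))
    history <- vector("list", generations)
    gen <- 0L
    while (gen < generations && best$score < 1) {
      gen <- gen + 1L
      # a positive circuit's retention probability shields its edges:
      # removal of edge e is damped by prod(1 - r_c) over circuits c
      # containing it, so stability elements are broken only when the
      # elite evidence supports it
      prob_rm <- p_rm
      for (e in seq_len(m)) {
        if (length(edge_circuits[[e]]) > 0) {
          prob_rm[e] <- prob_rm[e] * prod(1 - r_keep[edge_circuits[[e]]])
        }
      }
      prob_rm <- pmin(pmax(prob_rm, p_min), 1 - p_min)
      masks <- matrix(stats::runif(m * population) < prob_rm,
                      nrow = m, ncol = population)
      scores <- apply(masks, 2, score_mask)
      n_rm <- colSums(masks)
      ord <- order(-scores, n_rm)
      elite <- masks[, ord[seq_len(n_elite)], drop = FALSE]
      top <- ord[1]
      if (scores[top] > best$score ||
          (scores[top] == best$score && n_rm[top] < sum(best$mask))) {
        best <- list(mask = masks[, top], score = scores[top])
      }
      p_rm <- (1 - learning_rate) * p_rm + learning_rate * rowMeans(elite)
      p_rm <- pmin(pmax(p_rm, p_min), 1 - p_min)
      kept_intact <- vapply(circ_edges, function(ce) {
        mean(colSums(elite[ce, , drop = FALSE]) == 0)
      }, 1)
      r_keep <- (1 - learning_rate) * r_keep + learning_rate * kept_intact
      r_keep <- pmin(pmax(r_keep, p_min), 1 - p_min)
      history[[gen]] <- tibble::tibble(
        generation = gen, best_score = best$score, mean_score = mean(scores)
      )
    }
    structure(
      list(
        network = prune_unregulated(drop_edges(network, which(best$mask))),
        score = best$score,
        removed_edges = network$edges[best$mask, , drop = FALSE],
        history = dplyr::bind_rows(history[seq_len(gen)]),
        converged = best$score == 1,
        config = list(population = population,
                      elite_fraction = elite_fraction,
                      learning_rate = learning_rate, p_min = p_min,
                      generations = generations, seed = seed)
      ),
      class = "grn_contextualization"
    )
  })
}

#' @export
print.grn_contextualization <- function(x, ...) {
  cat("<grn_contextualization> score ", round(x$score, 4), ", removed ",
      nrow(x$removed_edges), " edge(s) in ",
      if (nrow(x$history) > 0) max(x$history$generation) else 0L,
      " generation(s)", if (x$converged) " (converged)", "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname contextualization_tidiers
tidy.grn_contextualization <- function(x, ...) {
  x$history
}

#' Tidiers for contextualization results
#'
#' `tidy()` returns the per-generation best and mean scores; `glance()` a
#' one-row summary.
#'
#' @param x a `grn_contextualization`.
#' @param ... unused.
#' @return a tibble.
#' @export
#' @rdname contextualization_tidiers
glance.grn_contextualization <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    n_removed = nrow(x$removed_edges),
    generations_run = if (nrow(x$history) > 0) max(x$history$generation)
                      else 0L,
    converged = x$converged
  )
}

#' @export
autoplot.grn_contextualization <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"generation",
                              names_to = "series", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$score,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "profile-agreement score",
                  colour = NULL)
}
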