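#' Run the full differential-stability pipeline
#'
#' Orchestrates read -> (optional contextualization) -> attractor
#' enumeration -> circuit enumeration -> DEPC detection -> reprogramming
#' determinant search, writing every stage's output as plain TSV plus a
#' machine-readable JSON summary, so each stage is independently diffable.
#' Errors are re-signalled with the failing stage's name; outputs of the
#' stages already completed are retained.
#'
#' @param network a `grn` or a path readable by [read_grn()].
#' @param profiles a profiles tibble or a path readable by
#'   [read_profiles()]; when given, the attractor pair is selected by
#'   profile matching and the RD stage runs.  Alternatively pass `initial`
#'   and `final` attractor ids.
#' @param out_dir output directory (created if missing).
#' @param initial,final attractor ids, used when `profiles` is `NULL`.
#' @param contextualize logical; run [contextualize()] before analysis
#'   (requires `profiles`).
#' @param ctx_args list of extra arguments for [contextualize()].
#' @param score_threshold when the profile-agreement score of the analysed
#'   network falls below this, a warning is emitted (the predictions are
#'   then only as reliable as the score indicates) and the pipeline
#'   continues.
#' @param dialect network file dialect, see [read_grn()].
#' @inheritParams find_reprogramming_determinants
#' @param seed seed recorded in the summary and passed to contextualization.
#' @return (invisibly) the summary list written to `summary.json`.
#' @export
run_pipeline <- function(network, profiles = NULL, out_dir = ".",
                         initial = NULL, final = NULL,
                         contextualize = FALSE, ctx_args = list(),
                         score_threshold = 0.9, dialect = "sif",
                         step_cap = 1000, permanent_clamp = FALSE,
                         strict_activator_rule = FALSE, mode = "auto",
                         max_circuits = 100000, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  net <- stage("read", {
    if (is.character(network)) read_grn(network, dialect = dialect)
    else network
  })
  prof <- stage("read", {
    if (is.character(profiles)) read_profiles(profiles) else profiles
  })
  summary <- list(
    seed = seed,
    config = list(contextualize = contextualize,
                  score_threshold = score_threshold, step_cap = step_cap,
                  permanent_clamp = permanent_clamp,
                  strict_activator_rule = strict_activator_rule,
                  mode = mode, max_circuits = max_circuits),
    versions = list(reprodet = as.character(utils::packageVersion("reprodet")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    network = as.list(glance(net))
  )
  ctx_score <- NULL
  if (contextualize) {
    if (is.null(prof)) {
      stop("stage 'contextualize' failed: profiles are required",
           call. = FALSE)
    }
    ctx <- stage("contextualize", {
      # string lookup: the local `contextualize` flag shadows the function
      do.call("contextualize", c(list(network = net, profiles = prof,
                                      seed = seed), ctx_args))
    })
    net <- ctx$network
    ctx_score <- ctx$score
    write_grn(net, file.path(out_dir, "contextualized_network.sif"))
    utils::write.table(ctx$history,
                       file.path(out_dir, "contextualization_history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$contextualization <- list(score = ctx$score,
                                      removed = nrow(ctx$removed_edges))
  }
  att <- stage("attractors", {
    attractors(net, mode = mode,
               strict_activator_rule = strict_activator_rule)
  })
  utils::write.table(att, file.path(out_dir, "attractors.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary$n_attractors <- nrow(att)
  circ <- stage("circuits", circuits(net, max_circuits = max_circuits))
  circ_flat <- dplyr::mutate(
    circ,
    members = vapply(.data$nodes, paste, "", collapse = ","),
    edge_signs = vapply(.data$signs, paste, "", collapse = ","),
    nodes = NULL, signs = NULL
  )
  utils::write.table(circ_flat, file.path(out_dir, "circuits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary$n_circuits <- nrow(circ)
  summary$n_positive_circuits <- sum(circ$sign == "positive")
  summary$n_negative_circuits <- sum(circ$sign == "negative")
  run_rd <- !is.null(prof) || (!is.null(initial) && !is.null(final))
  if (run_rd) {
    if (!is.null(prof)) {
      mt <- stage("depcs", match_attractors_to_profiles(att, prof))
      if (!is.null(ctx_score)) mt$score <- ctx_score
      if (mt$score < score_threshold) {
        warning("profile-agreement score ", round(mt$score, 3),
                " is below ", score_threshold,
                "; predictions on this network are correspondingly less ",
                "reliable", call. = FALSE)
      }
      summary$match <- as.list(mt)
      initial <- mt$initial_id
      final <- mt$final_id
    }
    si <- att[att$id == initial, ]
    sf <- att[att$id == final, ]
    depcs <- stage("depcs", detect_depcs(net, si, sf, circ = circ,
                                         strict_activator_rule =
                                           strict_activator_rule))
    depc_flat <- dplyr::mutate(
      depcs,
      members = vapply(.data$nodes, paste, "", collapse = ","),
      initial_state = vapply(.data$state_initial, paste, "", collapse = ","),
      final_state = vapply(.data$state_final, paste, "", collapse = ","),
      nodes = NULL, signs = NULL, state_initial = NULL, state_final = NULL
    )
    utils::write.table(depc_flat, file.path(out_dir, "depcs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$n_depcs <- nrow(depcs)
    rd <- stage("rds", find_reprogramming_determinants(
      net, initial = initial, final = final, step_cap = step_cap,
      permanent_clamp = permanent_clamp,
      strict_activator_rule = strict_activator_rule, mode = mode,
      max_circuits = max_circuits
    ))
    rd_flat <- tibble::tibble(
      rd_id = rd$rd_id,
      genes = vapply(rd$genes, paste, "", collapse = ","),
      size = rd$size,
      perturbation = rd$perturbation,
      covered_depcs = vapply(rd$covered_depcs, paste, "", collapse = ","),
      validated = rd$validated
    )
    utils::write.table(rd_flat, file.path(out_dir, "rds.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    summary$transition <- list(initial = initial, final = final)
    summary$n_rd_combinations <- nrow(rd)
    summary$rd_combinations <- rd_flat$genes
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
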