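# two cross-coupled toggles: toggle-1 (a, b) drives toggle-2 (c, d) via
# a -> c and b -> d; flipping toggle-1 drags toggle-2 along
coupled_toggles <- function() {
  grn(data.frame(
    from = c("a", "b", "c", "d", "a", "b"),
    to = c("b", "a", "d", "c", "c", "d"),
    sign = c(-1, -1, -1, -1, 1, 1)
  ))
}

test_that("transient clamp verification matches hand simulation", {
  toggle <- toggle_grn()
  expect_true(verify_transition(toggle, c(a = 1, b = 0), c(a = 0, b = 1),
                                c(b = 1)))
  expect_false(verify_transition(toggle, c(a = 1, b = 0), c(a = 0, b = 1),
                                 stats::setNames(integer(0), character(0))))
  # permanent clamp: same toggle case also succeeds
  expect_true(verify_transition(toggle, c(a = 1, b = 0), c(a = 0, b = 1),
                                c(b = 1), permanent_clamp = TRUE))
})

test_that("insufficient clamps fail in both phases and both semantics", {
  # two independent toggles: flipping both requires touching both
  two <- grn(data.frame(from = c("a", "b", "c", "d"),
                        to = c("b", "a", "d", "c"), sign = -1))
  ini <- c(a = 1, b = 0, c = 1, d = 0)
  fin <- c(a = 0, b = 1, c = 0, d = 1)
  expect_false(verify_transition(two, ini, fin, c(b = 1)))
  expect_false(verify_transition(two, ini, fin, c(b = 1),
                                 permanent_clamp = TRUE))
  expect_true(verify_transition(two, ini, fin, c(b = 1, d = 1)))
})

test_that("minimal DEPC subsets are found in increasing size", {
  toggle <- toggle_grn()
  att <- attractors(toggle)
  d <- detect_depcs(toggle, att[2, ], att[1, ])
  sets <- minimal_depc_sets(toggle, att[2, ], att[1, ], d)
  expect_equal(sets, list(1L))
  # two independent toggles, transition flipping both: both DEPCs needed
  two <- grn(data.frame(from = c("a", "b", "c", "d"),
                        to = c("b", "a", "d", "c"), sign = -1))
  att2 <- attractors(two)
  ini <- att2[att2$a == 1 & att2$c == 1, ]
  fin <- att2[att2$a == 0 & att2$c == 0, ]
  d2 <- detect_depcs(two, ini, fin)
  expect_equal(nrow(d2), 2)
  sets2 <- minimal_depc_sets(two, ini, fin, d2)
  expect_equal(sets2, list(c(1L, 2L)))
})

test_that("a driven circuit needs no direct perturbation", {
  net <- coupled_toggles()
  att <- attractors(net)
  expect_equal(nrow(att), 2)
  ini <- att[att$a == 0, ]
  fin <- att[att$a == 1, ]
  d <- detect_depcs(net, ini, fin)
  expect_equal(nrow(d), 2)
  # only the driving toggle is a sufficient minimal DEPC set
  sets <- minimal_depc_sets(net, ini, fin, d)
  drive <- d$depc_id[vapply(d$nodes, function(m) "a" %in% m, TRUE)]
  expect_equal(sets, list(drive))
  # pruning drops the driven toggle's gene from a mixed combination
  pruned <- prune_redundant_targets(net, ini, fin, c("a", "c"))
  expect_equal(pruned, "a")
})

test_that("greedy gene cover branches on ties", {
  depcs <- tibble::tibble(depc_id = 1:2,
                          nodes = list(c("x", "p"), c("x", "q")))
  # x covers both circuits: single branch
  shared <- minimal_gene_combinations(list(c(1L, 2L)), depcs)
  expect_equal(vapply(shared, paste, "", collapse = "+"), "x")
  # one DEPC of three genes: three alternative singleton covers
  d1 <- tibble::tibble(depc_id = 1L, nodes = list(c("a", "b", "c")))
  covers <- minimal_gene_combinations(list(1L), d1)
  expect_setequal(vapply(covers, paste, "", collapse = ""),
                  c("a", "b", "c"))
  # two disjoint two-gene DEPCs: four alternative pairs
  d2 <- tibble::tibble(depc_id = 1:2,
                       nodes = list(c("a", "b"), c("c", "d")))
  covers2 <- minimal_gene_combinations(list(c(1L, 2L)), d2)
  expect_setequal(vapply(covers2, paste, "", collapse = "+"),
                  c("a+c", "a+d", "b+c", "b+d"))
})

test_that("redundancy pruning is idempotent on a minimal combination", {
  toggle <- toggle_grn()
  att <- attractors(toggle)
  expect_equal(
    prune_redundant_targets(toggle, att[2, ], att[1, ], "b"),
    "b"
  )
})

test_that("the full pipeline returns all validated minimal alternatives", {
  toggle <- toggle_grn()
  rd <- find_reprogramming_determinants(toggle, initial = 2, final = 1)
  expect_equal(nrow(rd), 2)
  expect_true(all(rd$validated))
  expect_setequal(unlist(rd$genes), c("a", "b"))
  expect_true(all(rd$size == 1))
  # clamp directions are the final-attractor values
  expect_equal(sort(rd$perturbation), c("activate b", "repress a"))
  g <- glance(rd)
  expect_equal(g$n_combinations, 2)
  expect_true(g$all_validated)
})

test_that("driving-circuit genes are the only emitted targets (Fig-3c motif)", {
  net <- coupled_toggles()
  att <- attractors(net)
  rd <- find_reprogramming_determinants(net, initial = att$id[att$a == 0],
                                        final = att$id[att$a == 1])
  expect_true(all(rd$validated))
  expect_true(all(unlist(rd$genes) %in% c("a", "b")))
  expect_true(all(rd$size == 1))
})

test_that("profile-driven and id-driven invocations agree", {
  toggle <- toggle_grn()
  prof <- as_profiles(data.frame(gene = c("a", "b"), initial = c(1, 0),
                                 final = c(0, 1)))
  rd1 <- find_reprogramming_determinants(toggle, profiles = prof)
  rd2 <- find_reprogramming_determinants(toggle, initial = 2, final = 1)
  expect_equal(rd1$genes, rd2$genes)
  expect_equal(attr(rd1, "match")$score, 1)
  expect_error(find_reprogramming_determinants(toggle), "supply")
})

test_that("no combination smaller than the exhaustive optimum is missed", {
  set.seed(51)
  tested <- 0
  for (rep in 1:12) {
    net <- random_signed_network(sample(4:6, 1), sample(6:10, 1),
                                 inhibition_fraction = 0.5,
                                 n_self_loops = 1,
                                 seed = 5000 + rep, max_tries = 200)
    att <- attractors(net)
    ini <- unlist(att[1, -1])
    fin <- unlist(att[2, -1])
    rd <- tryCatch(
      find_reprogramming_determinants(net, initial = 1, final = 2),
      error = function(e) NULL
    )
    if (is.null(rd) || nrow(rd) == 0) next
    depc_genes <- sort(unique(unlist(attr(rd, "depcs")$nodes)))
    opt <- oracle_min_clamp_size(net, ini, fin, depc_genes)
    expect_equal(min(rd$size), opt, info = paste("rep", rep))
    tested <- tested + 1
  }
  expect_gt(tested, 3)
})
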