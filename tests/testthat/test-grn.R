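test_that("inhibitor-dominant update follows the rule table", {
  toggle <- toggle_grn()
  # an active inhibitor always wins
  expect_equal(boolean_update(toggle, c(a = 1, b = 0), "b"), 0L)
  expect_equal(boolean_update(toggle, c(a = 0, b = 1), "b"), 1L)
  # default-ON: all-inhibitor node with every inhibitor inactive turns on
  expect_equal(boolean_update(toggle, c(a = 0, b = 0), "a"), 1L)
  # mixed regulation: at least one activator AND no inhibitor
  mix <- grn(data.frame(from = c("a", "b"), to = c("c", "c"),
                        sign = c(1, -1)))
  expect_equal(boolean_update(mix, c(a = 1, b = 1, c = 0), "c"), 0L)
  expect_equal(boolean_update(mix, c(a = 1, b = 0, c = 0), "c"), 1L)
  expect_equal(boolean_update(mix, c(a = 0, b = 0, c = 1), "c"), 0L)
})

test_that("strict activator rule disables the default-ON convention", {
  toggle <- toggle_grn()
  expect_equal(
    boolean_update(toggle, c(a = 0, b = 0), "a", strict_activator_rule = TRUE),
    0L
  )
  # unregulated node under the strict rule is an unpruned input: error
  chain <- grn(data.frame(from = "a", to = "b", sign = 1))
  expect_error(
    boolean_update(chain, c(a = 0, b = 0), "a", strict_activator_rule = TRUE),
    "prune"
  )
})

test_that("synchronous step updates all nodes from the same input state", {
  toggle <- toggle_grn()
  expect_equal(synchronous_step(toggle, c(a = 0, b = 0)), c(a = 1, b = 1))
  expect_equal(synchronous_step(toggle, c(a = 1, b = 0)), c(a = 1, b = 0))
  selfa <- grn(data.frame(from = "a", to = "a", sign = 1))
  expect_equal(synchronous_step(selfa, c(a = 1)), c(a = 1))
  expect_equal(synchronous_step(selfa, c(a = 0)), c(a = 0))
})

test_that("synchronous step agrees with the brute-force rule oracle", {
  set.seed(11)
  for (rep in 1:20) {
    e <- random_edges(sample(3:7, 1), sample(4:12, 1))
    net <- grn(e)
    nodes <- net$nodes$name
    s <- stats::setNames(sample(0:1, length(nodes), replace = TRUE), nodes)
    expect_equal(synchronous_step(net, s), oracle_step(e, s),
                 info = paste("rep", rep))
  }
})

test_that("a node's update depends only on its in-neighbours", {
  set.seed(12)
  net <- grn(data.frame(from = c("a", "b", "c", "d"),
                        to = c("e", "e", "d", "c"),
                        sign = c(1, -1, 1, 1)))
  base <- c(a = 1, b = 0, c = 0, d = 1, e = 0)
  v <- boolean_update(net, base, "e")
  for (rep in 1:10) {
    scrambled <- base
    scrambled[c("c", "d", "e")] <- sample(0:1, 3, replace = TRUE)
    expect_equal(boolean_update(net, scrambled, "e"), v)
  }
})

test_that("unregulated nodes are pruned iteratively to a fixed point", {
  chain <- grn(data.frame(from = c("a", "b"), to = c("b", "c"), sign = 1))
  expect_equal(prune_unregulated(chain)$n, 0)
  toggle <- toggle_grn()
  expect_equal(prune_unregulated(toggle)$edges, toggle$edges)
  plus_input <- grn(rbind(toggle_edges(),
                          data.frame(from = "i", to = "a", sign = 1)))
  pruned <- prune_unregulated(plus_input)
  expect_setequal(pruned$nodes$name, c("a", "b"))
  # idempotence on random networks
  set.seed(13)
  for (rep in 1:10) {
    net <- grn(random_edges(6, 9))
    once <- prune_unregulated(net)
    twice <- prune_unregulated(once)
    expect_equal(once$edges, twice$edges)
  }
})

test_that("constructor rejects contradictory duplicate edges", {
  expect_error(
    grn(data.frame(from = c("x", "x"), to = c("y", "y"), sign = c(1, -1))),
    "x -> y"
  )
  # exact duplicates collapse to a single edge
  net <- grn(data.frame(from = c("x", "x"), to = c("y", "y"),
                        sign = c(-1, -1)))
  expect_equal(nrow(net$edges), 1)
  expect_error(grn(data.frame(from = "x", to = "y", sign = "maybe")),
               "sign")
})

test_that("network files round-trip in both dialects", {
  net <- grn(data.frame(from = c("SNAI1", "TP53", "ZEB1"),
                        to = c("MIR203", "MIR-107", "SNAI1"),
                        sign = c(-1, 1, -1)))
  for (dialect in c("sif", "tsv")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_grn(net, path, dialect = dialect)
    back <- read_grn(path, dialect = dialect)
    expect_equal(back$edges, net$edges)
    expect_equal(back$nodes, net$nodes)
  }
})

test_that("sif arrow tokens and miRNA kinds parse as printed", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("SNAI1\t-|\tMIR203", "TP53\t->\tMIR-107"), path)
  net <- read_grn(path, dialect = "sif")
  e <- net$edges
  expect_equal(e$sign[e$from == "SNAI1" & e$to == "MIR203"], -1L)
  expect_equal(e$sign[e$from == "TP53" & e$to == "MIR-107"], 1L)
  expect_equal(net$nodes$kind[net$nodes$name == "MIR203"], "mirna")
  expect_equal(net$nodes$kind[net$nodes$name == "TP53"], "gene")
})

test_that("malformed rows are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("a\t->\tb", "broken row here extra"), path)
  expect_error(read_grn(path), "line 2")
  expect_error(read_grn("no/such/file.sif"), "no/such/file.sif")
})

test_that("name normalization uppercases and strips the hsa- prefix", {
  expect_equal(normalize_gene_names(c("hsa-miR-203", "Snai1")),
               c("MIR-203", "SNAI1"))
})

test_that("tidy and glance summarise a network", {
  net <- emt_network()
  g <- glance(net)
  expect_equal(g$interactions, nrow(tidy(net)))
  expect_equal(g$activations + g$inhibitions, g$interactions)
  expect_setequal(unique(tidy(net)$interaction),
                  c("activation", "inhibition"))
})
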