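test_that("greedy extraction returns an induced subgraph", {
  set.seed(71)
  src <- grn(random_edges(12, 30))
  sub <- extract_subnetwork(src, 6, seed = 3)
  expect_equal(sub$n, 6)
  keep <- sub$nodes$name
  expected <- src$edges[src$edges$from %in% keep & src$edges$to %in% keep, ]
  expect_equal(sub$edges, tibble::as_tibble(expected))
  # whole-network extraction is the identity
  whole <- extract_subnetwork(src, src$n, seed = 1)
  expect_equal(whole$edges, src$edges)
})

test_that("extraction is reproducible and respects connectivity", {
  star <- grn(data.frame(from = "hub", to = paste0("leaf", 1:4), sign = 1))
  two <- extract_subnetwork(star, 2, seed = 5)
  expect_true("hub" %in% two$nodes$name)
  expect_equal(nrow(two$edges), 1)
  set.seed(72)
  src <- grn(random_edges(10, 25))
  s1 <- extract_subnetwork(src, 5, seed = 11)
  s2 <- extract_subnetwork(src, 5, seed = 11)
  expect_equal(s1$nodes, s2$nodes)
  expect_error(extract_subnetwork(src, 99, seed = 1), "between 1 and")
  # disconnected source cannot grow past its component
  disc <- grn(data.frame(from = c("a", "c"), to = c("b", "d"), sign = 1))
  expect_error(extract_subnetwork(disc, 3, seed = 2), "disconnected")
})

test_that("the two-gene all-inhibition draw is forced to the toggle", {
  net <- random_signed_network(2, 2, inhibition_fraction = 1,
                               n_self_loops = 0, seed = 8)
  expect_equal(sort(paste(net$edges$from, net$edges$to)),
               c("g01 g02", "g02 g01"))
  expect_true(all(net$edges$sign == -1L))
  expect_equal(nrow(attractors(net)), 2)
})

test_that("requested edge counts and signs are exact", {
  net <- random_signed_network(6, 12, inhibition_fraction = 0,
                               n_self_loops = 2, seed = 9)
  expect_equal(nrow(net$edges), 12)
  expect_equal(sum(net$edges$sign == -1L), 0)
  expect_equal(sum(net$edges$from == net$edges$to), 2)
  same <- random_signed_network(6, 12, inhibition_fraction = 0,
                                n_self_loops = 2, seed = 9)
  expect_equal(net$edges, same$edges)
  # a single inhibition edge can never build a positive circuit
  expect_error(
    random_signed_network(2, 1, inhibition_fraction = 1, n_self_loops = 0,
                          seed = 1, max_tries = 10),
    "multistable"
  )
})

test_that("generated networks always admit the full pipeline", {
  for (rep in 1:5) {
    net <- random_signed_network(5, 9, inhibition_fraction = 0.5,
                                 n_self_loops = 1, seed = 900 + rep)
    expect_gte(nrow(attractors(net)), 2)
    expect_gte(sum(circuits(net)$sign == "positive"), 1)
  }
})

test_that("the synthetic source network has the advertised gross topology", {
  src <- sample_source_network(n_nodes = 200, seed = 77)
  expect_equal(src$n, 200)
  self <- src$edges$from == src$edges$to
  expect_gt(sum(self), 20)                      # autoregulation present
  expect_gt(mean(src$edges$sign[self] == 1L), 0.5)
  out_deg <- table(src$edges$from[!self])
  expect_gt(max(out_deg), 10)                   # hub regulators
  src2 <- sample_source_network(n_nodes = 200, seed = 77)
  expect_equal(src$edges, src2$edges)
})

test_that("regulator tables parse with ambiguous-effect handling", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("araC\taraB\t+", "fnr\tnarG\t+-", "crp\tmalT\t+",
               "lexA\trecA\t-", "h-ns\tproV\t?"), path)
  net <- read_grn_table <- read_regulon_table(path)
  expect_equal(nrow(net$edges), 3)
  asact <- read_regulon_table(path, ambiguous = "activation")
  expect_equal(nrow(asact$edges), 5)
  expect_equal(asact$edges$sign[asact$edges$from == "fnr"], 1L)
})

test_that("a toggle ensemble yields RD fraction one on every transition", {
  toggle_src <- grn(data.frame(from = c("a", "b"), to = c("b", "a"),
                               sign = -1))
  st <- run_insilico_study(n_networks = 3, size_range = c(2, 2),
                           source = toggle_src, seed = 5)
  expect_equal(nrow(st$pairs), 6)               # 2 ordered pairs x 3 nets
  expect_true(all(st$pairs$depc_exists))
  expect_true(all(st$pairs$rd_success))
  expect_true(all(st$pairs$rd_size == 1))
  expect_equal(st$networks$rd_fraction, rep(1, 3))
  expect_equal(st$summary$depc_exists_fraction, 1)
  expect_equal(st$summary$rd_success_fraction, 1)
  expect_equal(st$summary$mean_rd_fraction, 1)
})

test_that("monostable networks are recorded as pair-free, not fatal", {
  neg_src <- grn(data.frame(from = c("a", "b"), to = c("b", "a"),
                            sign = c(1, -1)))
  st <- run_insilico_study(n_networks = 2, size_range = c(2, 2),
                           source = neg_src, seed = 6)
  expect_equal(st$pairs$status, rep("no_pair", 2))
  expect_equal(st$summary$n_pairs_analysed, 0)
  expect_true(is.na(st$summary$rd_success_fraction))
})

test_that("study runs are reproducible with the same seed", {
  s1 <- run_insilico_study(n_networks = 4, size_range = c(8, 12), seed = 77)
  s2 <- run_insilico_study(n_networks = 4, size_range = c(8, 12), seed = 77)
  expect_equal(s1$pairs, s2$pairs)
  expect_equal(glance(s1), s1$summary)
  expect_equal(tidy(s1), s1$pairs)
})
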