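test_that("small canonical networks have the expected fixed points", {
  att <- attractors(toggle_grn())
  expect_equal(att$a, c(0L, 1L))
  expect_equal(att$b, c(1L, 0L))
  # negative two-ring: no fixed point
  neg <- grn(data.frame(from = c("a", "b"), to = c("b", "a"),
                        sign = c(1, -1)))
  expect_equal(nrow(attractors(neg)), 0)
  # positive three-ring (two inhibitions): exactly two fixed points
  ring3 <- grn(ring_edges(c(-1, -1, 1)))
  expect_equal(nrow(attractors(ring3)), 2)
})

test_that("every reported attractor is a fixed point of the step map", {
  set.seed(21)
  for (rep in 1:15) {
    net <- grn(random_edges(sample(3:8, 1), sample(4:14, 1)))
    att <- attractors(net)
    for (i in seq_len(nrow(att))) {
      s <- unlist(att[i, -1])
      expect_equal(synchronous_step(net, s), s)
    }
  }
})

test_that("exhaustive and feedback-vertex-set modes agree with the oracle", {
  set.seed(22)
  for (rep in 1:20) {
    e <- random_edges(sample(3:9, 1), sample(5:18, 1))
    net <- grn(e)
    a1 <- attractors(net, mode = "exhaustive")
    a2 <- attractors(net, mode = "backtracking")
    expect_equal(a1, a2, info = paste("rep", rep))
    fps <- oracle_fixed_points(e)
    expect_equal(nrow(a1), nrow(fps), info = paste("rep", rep))
    if (nrow(fps) > 0) {
      expect_equal(unname(as.matrix(a1[, -1])), unname(fps),
                   info = paste("rep", rep))
    }
  }
})

test_that("attractor ids are lexicographic and independent of mode", {
  net <- grn(ring_edges(c(-1, -1, 1, 1)))
  a <- attractors(net)
  expect_equal(a$id, seq_len(nrow(a)))
  m <- as.matrix(a[, -1])
  expect_true(all(diff(m %*% 2^(rev(seq_len(ncol(m))) - 1)) > 0))
})

test_that("oversized networks are refused with actionable advice", {
  big <- grn(data.frame(from = paste0("g", 1:30),
                        to = paste0("g", c(2:30, 1)), sign = 1))
  expect_error(attractors(big, mode = "exhaustive"), "backtracking")
  expect_error(attractors(big, max_nodes = 10), "cap")
})

test_that("clamped simulation reaches the forced attractor", {
  toggle <- toggle_grn()
  tr <- simulate_to_attractor(toggle, c(a = 0, b = 1), clamp = c(a = 1))
  expect_equal(tr$terminal, "fixed_point")
  expect_equal(tr$states[nrow(tr$states), ], c(a = 1, b = 0))
  # start at an attractor, no clamp: zero steps
  tr0 <- simulate_to_attractor(toggle, c(a = 1, b = 0))
  expect_equal(tr0$terminal, "fixed_point")
  expect_equal(tr0$steps, 0L)
  # negative ring cycles from any start
  neg <- grn(data.frame(from = c("a", "b"), to = c("b", "a"),
                        sign = c(1, -1)))
  expect_equal(simulate_to_attractor(neg, c(a = 0, b = 0))$terminal, "cycle")
  expect_error(simulate_to_attractor(toggle, c(a = 0, b = 0),
                                     clamp = c(zz = 1)), "zz")
})

test_that("free simulation terminates on a state the enumerator knows", {
  set.seed(23)
  for (rep in 1:15) {
    net <- grn(random_edges(sample(3:7, 1), sample(4:12, 1)))
    att <- attractors(net)
    s <- stats::setNames(sample(0:1, net$n, replace = TRUE),
                         net$nodes$name)
    tr <- simulate_to_attractor(net, s, step_cap = 200)
    expect_true(tr$terminal %in% c("fixed_point", "cycle"))
    if (tr$terminal == "fixed_point") {
      final <- tr$states[nrow(tr$states), ]
      hit <- apply(as.matrix(att[, -1]), 1, function(row) {
        all(row == final)
      })
      expect_true(any(hit))
    }
  }
})

test_that("trajectory tidier returns one row per step and node", {
  tr <- simulate_to_attractor(toggle_grn(), c(a = 0, b = 0))
  td <- tidy(tr)
  expect_setequal(names(td), c("step", "node", "state"))
  expect_equal(nrow(td), nrow(tr$states) * 2)
})

test_that("attractor-profile matching maximises explained gene states", {
  att <- attractors(toggle_grn())
  perfect <- as_profiles(data.frame(gene = c("a", "b"),
                                    initial = c(1, 0), final = c(0, 1)))
  m <- match_attractors_to_profiles(att, perfect)
  expect_equal(m$score, 1)
  expect_equal(att[att$id == m$initial_id, ]$a, 1)
  expect_equal(att[att$id == m$final_id, ]$a, 0)
  # one of four gene-states wrong: best pair unchanged, score 0.75
  off <- as_profiles(data.frame(gene = c("a", "b"),
                                initial = c(1, 0), final = c(0, 0)))
  m2 <- match_attractors_to_profiles(att, off)
  expect_equal(m2$initial_id, m$initial_id)
  expect_equal(m2$final_id, m$final_id)
  expect_equal(m2$score, 0.75)
  # fewer than two attractors cannot represent two phenotypes
  mono <- grn(data.frame(from = "a", to = "b", sign = 1))
  expect_equal(nrow(attractors(mono)), 1)
  expect_error(match_attractors_to_profiles(attractors(mono), perfect),
               "phenotypes")
})
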