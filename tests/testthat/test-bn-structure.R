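test_that("bn_dag validates nodes, duplicates, and rejects cycles", {
  g <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_s3_class(g, "bn_dag")
  expect_error(bn_dag(c("a", "a"), NULL), "duplicate")
  expect_error(bn_dag(c("a", "b"), rbind(c("a", "z"))), "declared nodes")
  expect_error(bn_dag(c("a", "b"), rbind(c("a", "b"), c("b", "a"))), "cycl")
  expect_error(bn_dag("a", rbind(c("a", "a"))))
})

test_that("parents, children, and the adjacency matrix are consistent", {
  g <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(sort(dag_parents(g, "c")), c("a", "b"))
  expect_equal(sort(dag_children(g, "a")), c("b", "c"))
  A <- amat(g)
  expect_equal(sum(A), 3)
  expect_true(A["a", "b"] && A["a", "c"] && A["b", "c"])
})

test_that("topological sort respects every arc (igraph oracle)", {
  withr::with_seed(2, {
    for (rep in 1:10) {
      p <- sample(4:8, 1)
      nodes <- letters[1:p]
      arcs <- NULL
      for (i in 1:(p - 1)) for (j in (i + 1):p)
        if (runif(1) < 0.4) arcs <- rbind(arcs, c(nodes[i], nodes[j]))
      g <- bn_dag(nodes, arcs)
      ts <- topo_sort(g)
      pos <- match(nodes, ts)
      if (!is.null(arcs))
        expect_true(all(pos[match(arcs[, 1], nodes)] < pos[match(arcs[, 2], nodes)]))
      ig <- igraph::graph_from_edgelist(if (is.null(arcs)) matrix(character(), 0, 2) else arcs)
      expect_true(igraph::is_dag(igraph::add_vertices(
        ig, sum(!(nodes %in% igraph::V(ig)$name)))))
    }
  })
})

test_that("d-separation matches known textbook structures", {
  # chain a -> b -> c: a _||_ c | b, not marginally
  chain <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_false(d_separated(chain, "a", "c", character(0)))
  expect_true(d_separated(chain, "a", "c", "b"))
  # fork a <- b -> c: same pattern
  fork <- bn_dag(c("a", "b", "c"), rbind(c("b", "a"), c("b", "c")))
  expect_false(d_separated(fork, "a", "c", character(0)))
  expect_true(d_separated(fork, "a", "c", "b"))
  # collider a -> b <- c: marginally independent, dependent given b or its child
  coll <- bn_dag(c("a", "b", "c", "d"),
                 rbind(c("a", "b"), c("c", "b"), c("b", "d")))
  expect_true(d_separated(coll, "a", "c", character(0)))
  expect_false(d_separated(coll, "a", "c", "b"))
  expect_false(d_separated(coll, "a", "c", "d"))
})

test_that("the Markov blanket is parents, children, and co-parents", {
  g <- bn_dag(c("a", "b", "c", "d", "e"),
              rbind(c("a", "c"), c("b", "c"), c("c", "d"), c("e", "d")))
  expect_equal(sort(markov_blanket(g, "c")), c("a", "b", "d", "e"))
  expect_equal(sort(markov_blanket(g, "a")), c("b", "c"))
  expect_equal(markov_blanket(g, "e"), c("c", "d"))
})

test_that("skeleton SHD counts undirected edge differences only", {
  g1 <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  g2 <- bn_dag(c("a", "b", "c"), rbind(c("b", "a"), c("b", "c")))  # reversal
  g3 <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("a", "c")))
  expect_equal(shd_skeleton(g1, g2), 0)
  expect_equal(shd_skeleton(g1, g3), 2)
  expect_equal(shd_skeleton(g1, g1), 0)
})

test_that("the local log-likelihood matches the frozen closed form", {
  d <- data.frame(a = c("y", "y", "y", "n"))
  expect_equal(local_score(d, "a", character(), kind = "loglik"),
               3 * log(0.75) + log(0.25), tolerance = 1e-12)
  # AIC subtracts (r - 1) q free parameters
  expect_equal(local_score(d, "a", character(), kind = "aic"),
               3 * log(0.75) + log(0.25) - 1, tolerance = 1e-12)
})

test_that("declared-but-unobserved levels still count toward the AIC penalty", {
  d <- data.frame(a = c("y", "y", "n", "n"), b = c("u", "v", "u", "v"))
  s2 <- local_score(d, "a", "b", kind = "aic")
  s3 <- local_score(d, "a", "b", kind = "aic",
                    levels = list(a = c("y", "n"), b = c("u", "v", "w")))
  # same observed likelihood, one extra parent configuration penalized
  expect_equal(s2 - s3, 1, tolerance = 1e-12)
})

test_that("the network score is decomposable", {
  d <- toy_data(300, seed = 4)
  g <- bn_dag(c("a", "b", "c"), rbind(c("a", "b")))
  total <- network_score(g, d)
  parts <- local_score(d, "a", character()) +
    local_score(d, "b", "a") + local_score(d, "c", character())
  expect_equal(total, parts, tolerance = 1e-12)
})

test_that("hill-climbing finds the planted dependence and is deterministic", {
  d <- toy_data(400, seed = 1)
  g1 <- hill_climb(d)
  g2 <- hill_climb(d)
  expect_identical(g1$arcs, g2$arcs)
  expect_equal(attr(g1, "score"), attr(g2, "score"))
  sk <- skeleton(g1)
  expect_true(any((sk[, 1] == "a" & sk[, 2] == "b") |
                  (sk[, 1] == "b" & sk[, 2] == "a")))
  expect_true(attr(g1, "converged"))
  # the score trace is strictly increasing
  expect_true(all(diff(attr(g1, "trace")) > 0))
})

test_that("whitelist arcs are kept and blacklist arcs never added", {
  d <- toy_data(400, seed = 3)
  gw <- hill_climb(d, whitelist = rbind(c("c", "a")))
  expect_true(any(gw$arcs[, 1] == "c" & gw$arcs[, 2] == "a"))
  gb <- hill_climb(d, blacklist = rbind(c("a", "b"), c("b", "a")))
  expect_false(any((gb$arcs[, 1] == "a" & gb$arcs[, 2] == "b") |
                   (gb$arcs[, 1] == "b" & gb$arcs[, 2] == "a")))
})

test_that("exhaustive search enumerates the known DAG counts", {
  d2 <- toy_data(60, seed = 5)[, c("a", "b")]
  expect_equal(attr(exhaustive_search(d2), "n_dags"), 3)
  d3 <- toy_data(60, seed = 5)
  expect_equal(attr(exhaustive_search(d3), "n_dags"), 25)
  d4 <- d3
  d4$d <- rep(c("x", "y"), 30)
  expect_equal(attr(exhaustive_search(d4), "n_dags"), 543)
})

test_that("exhaustive search scores at least as high as hill-climbing", {
  for (s in 1:5) {
    d <- toy_data(120, seed = 10 + s)
    hc <- hill_climb(d)
    ex <- exhaustive_search(d)
    expect_gte(attr(ex, "score"), attr(hc, "score") - 1e-9)
  }
})

test_that("bootstrap strengths are reproducible, bounded, and direction-consistent", {
  d <- toy_data(200, seed = 6)
  s1 <- bootstrap_arc_strength(d, B = 25, seed = 9)
  s2 <- bootstrap_arc_strength(d, B = 25, seed = 9)
  expect_identical(tidy(s1), tidy(s2))
  expect_true(all(s1$strength >= 0 & s1$strength <= 1))
  expect_true(all(s1$direction <= s1$strength + 1e-12))
  expect_true(all(s1$from < s1$to))
  # the planted a - b dependence must dominate
  ab <- s1$strength[s1$from == "a" & s1$to == "b"]
  expect_gte(ab, 0.9)
})

test_that("bootstrap excludes design columns from the node set", {
  d <- toy_data(150, seed = 7)
  d$weight <- 1; d$stratum <- 1L; d$psu <- seq_len(nrow(d)); d$id <- seq_len(nrow(d))
  st <- bootstrap_arc_strength(d, B = 5, seed = 1)
  expect_false(any(c("weight", "stratum", "psu", "id") %in%
                   c(st$from, st$to)))
})

test_that("model averaging keeps strong arcs, majority orientation, threshold respected", {
  st <- tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"),
                       strength = c(0.9, 0.5, 0.8),
                       direction = c(0.7, 0.5, 0.2))
  class(st) <- c("arc_strength", class(st))
  g <- model_average(st, threshold = 0.75, nodes = c("a", "b", "c"))
  expect_equal(nrow(g$arcs), 2)
  expect_true(any(g$arcs[, 1] == "a" & g$arcs[, 2] == "b"))  # majority forward
  expect_true(any(g$arcs[, 1] == "c" & g$arcs[, 2] == "b"))  # majority backward
})

test_that("model averaging repairs cycles by dropping the weakest arc", {
  st <- tibble::tibble(from = c("a", "b", "a"), to = c("b", "c", "c"),
                       strength = c(0.95, 0.9, 0.8),
                       direction = c(0.95, 0.9, 0.1))  # a->b, b->c, c->a: cycle
  class(st) <- c("arc_strength", class(st))
  g <- model_average(st, threshold = 0.75, nodes = c("a", "b", "c"))
  expect_s3_class(g, "bn_dag")
  expect_equal(attr(g, "dropped"), "c->a")
  expect_equal(nrow(g$arcs), 2)
})

test_that("tidy and glance summarize DAGs and strength tables", {
  g <- bn_dag(c("a", "b"), rbind(c("a", "b")))
  expect_equal(names(tidy(g)), c("from", "to"))
  gl <- glance(g)
  expect_equal(gl$n_nodes, 2)
  expect_equal(gl$n_arcs, 1)
})
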