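test_that("build_graph caps weights, drops self-edges, applies cutoff", {
  edges <- data.frame(a = c("x", "x", "y", "z"),
                      b = c("y", "x", "z", "w"),
                      e = c(1e-250, 1e-5, 0.1, 0.5))
  expect_warning(g <- build_graph(edges), "self-edge")
  w <- stats::setNames(g$edges$weight, paste(g$edges$a, g$edges$b))
  expect_equal(unname(w["x y"]), 200)       # capped at 200
  expect_equal(unname(w["y z"]), 1.0)       # -log10(0.1)
  expect_false("z w" %in% names(w))         # above the cutoff
  expect_error(build_graph(data.frame(a = "a", b = "b", e = 0)), "> 0")
})

test_that("degree capping removes exactly the lightest non-mutual edges", {
  # star: hub connected to 300 spokes with increasing weights, cap 280
  n <- 300
  edges <- data.frame(a = "hub", b = sprintf("s%03d", seq_len(n)),
                      e = 10^-(1 + seq_len(n) / 10))
  suppressWarnings(g <- build_graph(edges, degree_cap = 280L))
  deg_hub <- sum(g$edges$a == "hub" | g$edges$b == "hub")
  expect_equal(deg_hub, 280L)
  expect_true(deg_hub >= 280L && nrow(g$edges) <= n)
  # the 20 lightest spokes lost their only edge
  kept <- unique(c(g$edges$a, g$edges$b))
  expect_false(any(sprintf("s%03d", 1:20) %in% kept))
  expect_true(all(sprintf("s%03d", 21:300) %in% kept))
})

test_that("MCL separates planted cliques and stays column-stochastic", {
  # clique weight 200 vs bridge weight 2: a 100:1 contrast
  edges <- rbind(clique_edges(paste0("x", 1:5), 1e-200),
                 clique_edges(paste0("y", 1:5), 1e-200),
                 data.frame(a = "x1", b = "y1", e = 1e-2))
  g <- build_graph(edges)
  cl <- mcl(g, 2.0)
  expect_true(cl$converged)
  expect_length(cl$clusters, 2L)
  expect_setequal(cl$clusters[[which(vapply(cl$clusters, function(x) "x1" %in% x, TRUE))]],
                  paste0("x", 1:5))
  expect_lt(max(cl$stochastic_dev), 1e-12)

  # single node
  single <- structure(list(edges = data.frame(a = character(0), b = character(0),
                                              weight = numeric(0)),
                           nodes = "solo", connected = TRUE),
                      class = "similarity_graph")
  expect_length(mcl(single, 2.0)$clusters, 1L)
  expect_error(mcl(g, 1.0), "> 1")
})

test_that("low inflation clusters no finer than high inflation", {
  edges <- rbind(clique_edges(paste0("x", 1:5), 1e-40),
                 clique_edges(paste0("y", 1:5), 1e-40),
                 clique_edges(paste0("z", 1:5), 1e-40),
                 data.frame(a = c("x1", "y1"), b = c("y2", "z2"), e = 1e-2))
  g <- build_graph(edges)
  lo <- suppressWarnings(mcl(g, 1.01))   # near-1 inflation converges slowly
  hi <- mcl(g, 3.0)
  expect_lte(length(lo$clusters), length(hi$clusters))
})

test_that("MCL is equivariant under node relabeling", {
  edges <- rbind(clique_edges(paste0("x", 1:4), 1e-30),
                 clique_edges(paste0("y", 1:4), 1e-30),
                 data.frame(a = "x1", b = "y1", e = 0.01))
  g <- build_graph(edges)
  cl <- mcl(g, 2.0)
  perm <- c(x1 = "q9", x2 = "q8", x3 = "q7", x4 = "q6",
            y1 = "b1", y2 = "b2", y3 = "b3", y4 = "b4")
  edges2 <- data.frame(a = unname(perm[edges$a]), b = unname(perm[edges$b]),
                       e = edges$e)
  cl2 <- mcl(build_graph(edges2), 2.0)
  part1 <- lapply(cl$clusters, function(x) sort(unname(perm[x])))
  part2 <- lapply(cl2$clusters, sort)
  expect_setequal(vapply(part1, paste, "", collapse = ","),
                  vapply(part2, paste, "", collapse = ","))
})

test_that("select_clustering maximizes annotated concentration with tie rule", {
  mk <- function(clusters, inflation) {
    structure(list(clusters = clusters, inflation = inflation,
                   membership = stats::setNames(
                     rep(seq_along(clusters), lengths(clusters)),
                     unlist(clusters))),
              class = "clustering")
  }
  ann <- paste0("a", 1:6)
  A <- mk(list(ann, c("b1", "b2")), 2.0)                  # all 6 together
  B <- mk(list(ann[1:3], c(ann[4:6], "b1"), "b2"), 1.2)   # split 3/3
  expect_equal(select_clustering(list(A, B), ann)$inflation, 2.0)
  # identical scores: lowest inflation wins
  C <- mk(list(ann, c("b1", "b2")), 1.2)
  expect_equal(select_clustering(list(A, C), ann)$inflation, 1.2)
  expect_error(select_clustering(list(A), character(0)), "non-empty")
  D <- mk(list(c("b1", "b2")), 1.5)
  expect_error(select_clustering(list(D), ann), "no clustering")
})

test_that("the inflation sweep keeps an annotated clique intact", {
  edges <- rbind(clique_edges(paste0("x", 1:5), 1e-40),
                 clique_edges(paste0("y", 1:5), 1e-40),
                 data.frame(a = "x1", b = "y1", e = 1e-2))
  g <- build_graph(edges)
  sweep <- suppressWarnings(lapply(c(1.05, 1.2, 2.0, 3.0), function(r) mcl(g, r)))
  best <- select_clustering(sweep, paste0("x", 1:5))
  incl <- vapply(best$clusters, function(cl) all(paste0("x", 1:5) %in% cl), TRUE)
  expect_true(any(incl))
})
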