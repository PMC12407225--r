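# Mutual-information grading, fragment extraction, role classification,
# and fragment comparison.

test_that("mutual information estimates are symmetric and hit closed forms", {
  set.seed(61)
  n <- 1000
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, 0, 0.8)
  a <- mi_jackknife(x, y); b <- mi_jackknife(y, x)
  expect_equal(a$mi, b$mi, tolerance = 1e-12)

  f <- factor(sample(c("u", "v"), n, TRUE))
  perfect <- mi_jackknife(f, f)
  # entropy of the two observed margins, approx ln 2 at equal margins
  p <- mean(f == "u")
  expect_equal(perfect$plugin, -p * log(p) - (1 - p) * log(1 - p),
               tolerance = 1e-9)
  expect_lt(abs(perfect$mi - log(2)), 0.05)

  const <- mi_jackknife(rep(1.0, 50), rnorm(50))
  expect_equal(const$mi, 0)
  expect_equal(const$flag, "constant")

  expect_error(mi_jackknife(rnorm(5), rnorm(5)), "at least 10")
  # complete cases only
  xm <- x; xm[1:100] <- NA
  expect_equal(mi_jackknife(xm, y)$n, n - 100)
})

test_that("edges are graded into terciles and thickness groups", {
  set.seed(62)
  n <- 800
  nodes <- c(paste0("a", 1:9), paste0("b", 1:9))
  rec <- list()
  rho <- seq(0.15, 0.95, length.out = 9)
  for (i in 1:9) {
    rec[[paste0("a", i)]] <- rnorm(n)
    rec[[paste0("b", i)]] <- rho[i] * rec[[paste0("a", i)]] +
      rnorm(n, 0, sqrt(1 - rho[i]^2))
  }
  sp <- variable_spec(nodes, rep("T1", 18), rep("continuous", 18),
                      rep("determinant", 18))
  d <- panel_dataset(as.data.frame(rec, check.names = FALSE), sp)
  net <- averaged_from_arcs(nodes, cbind(paste0("a", 1:9), paste0("b", 1:9)))
  ann <- grade_edges(net, d)
  expect_equal(as.integer(table(ann$tercile)), c(3L, 3L, 3L))
  # MI ordering follows the generating correlation
  expect_equal(order(ann$mi), order(rho[match(ann$from, paste0("a", 1:9))]))
  expect_true(all(ann$thickness_group == 4L))  # presence confidence 1.0

  # thickness cutpoints at 0.7 / 0.8 / 0.9
  strs <- c(replicate(36, dag_structure(c("A", "B"), rbind(c("A", "B"))),
                      simplify = FALSE),
            replicate(14, dag_structure(c("A", "B")), simplify = FALSE))
  net2 <- average_network(strs, 0.6)   # presence 36/50 = 0.72
  sp2 <- variable_spec(c("A", "B"), c("T1", "T1"),
                       rep("continuous", 2), rep("determinant", 2))
  d2 <- panel_dataset(data.frame(A = rnorm(100), B = rnorm(100)), sp2)
  ann2 <- grade_edges(net2, d2)
  expect_equal(ann2$thickness_group, 2L)
})

test_that("fragment extraction keeps exactly the on-path arcs", {
  nodes <- c("intervention", "A", "B", "C", "pa")
  # diamond: all five arcs lie on a path
  diamond <- averaged_from_arcs(nodes, rbind(
    c("intervention", "A"), c("A", "C"), c("intervention", "B"),
    c("B", "C"), c("C", "pa")))
  frag <- extract_fragment(diamond, "intervention", "pa")
  expect_equal(nrow(frag$edges), 5)

  # chain plus a disconnected feeder into the outcome
  chain <- averaged_from_arcs(nodes, rbind(
    c("intervention", "A"), c("A", "pa"), c("B", "pa")))
  frag2 <- extract_fragment(chain, "intervention", "pa")
  expect_setequal(paste(frag2$edges$from, frag2$edges$to),
                  c("intervention A", "A pa"))

  # no route at all: empty fragment with a warning
  isolated <- averaged_from_arcs(nodes, rbind(c("A", "B")))
  expect_warning(frag3 <- extract_fragment(isolated, "intervention", "pa"),
                 "no path")
  expect_equal(nrow(frag3$edges), 0)

  expect_error(extract_fragment(diamond, "nope", "pa"), "not in network")
})

test_that("extraction agrees with brute-force path enumeration on random DAGs", {
  set.seed(63)
  for (i in 1:100) {
    g <- rand_dag(sample(4:10, 1), prob = 0.35)
    net <- averaged_from_arcs(g$nodes, g$arcs)
    src <- sample(g$nodes, 1)
    tgt <- sample(setdiff(g$nodes, src), sample(1:2, 1))
    oracle <- brute_force_path_edges(g$arcs, src, tgt)
    got <- tryCatch({
      f <- suppressWarnings(extract_fragment(net, src, tgt))
      paste(f$edges$from, f$edges$to, sep = ">")
    }, error = function(e) character())
    expect_setequal(got, oracle)
  }
})

test_that("undirected edges are traversable unless excluded", {
  strs <- c(replicate(5, dag_structure(c("I", "M", "pa"),
                                       rbind(c("I", "M"), c("M", "pa"))),
                      simplify = FALSE),
            replicate(5, dag_structure(c("I", "M", "pa"),
                                       rbind(c("I", "M"), c("pa", "M"))),
                      simplify = FALSE))
  net <- average_network(strs, 0.6)  # M~pa is an exact direction tie
  expect_equal(nrow(net$undirected), 1)
  frag <- extract_fragment(net, "I", "pa")
  expect_equal(nrow(frag$edges), 2)
  expect_warning(frag_dir <- extract_fragment(net, "I", "pa",
                                              traversal = "exclude"),
                 "no path")
  expect_equal(nrow(frag_dir$edges), 0)
})

test_that("roles are classified and compared consistently", {
  nodes <- c("intervention", "habit", "intention", "pa")
  a <- extract_fragment(averaged_from_arcs(nodes, rbind(
    c("intervention", "habit"), c("habit", "pa"),
    c("habit", "intention"), c("intention", "pa"))), "intervention", "pa")
  b <- extract_fragment(averaged_from_arcs(nodes, rbind(
    c("intervention", "habit"), c("habit", "intention"),
    c("intention", "pa"))), "intervention", "pa")

  expect_equal(classify_role(a, "habit", "pa"), "direct")
  expect_equal(classify_role(b, "habit", "pa"), "indirect")
  expect_equal(classify_role(a, "nonexistent", "pa"), "absent")
  expect_error(classify_role(a, "habit", "intention"), "not a fragment target")

  same <- compare_fragments(a, a)
  expect_equal(nrow(same$only_a) + nrow(same$only_b), 0)
  expect_equal(nrow(same$role_transitions), 0)

  diff <- compare_fragments(a, b)
  expect_equal(paste(diff$only_a$from, diff$only_a$to), "habit pa")
  expect_equal(nrow(diff$only_b), 0)
  tr <- diff$role_transitions
  expect_true(any(tr$node == "habit" & tr$role_a == "direct" &
                    tr$role_b == "indirect"))
  # membership consistency: a direct node is never absent
  for (v in a$nodes)
    expect_true(classify_role(a, v, "pa") %in% c("direct", "indirect"))
})

test_that("DOT output encodes thickness and terciles", {
  nodes <- c("I", "M", "pa")
  net <- averaged_from_arcs(nodes, rbind(c("I", "M"), c("M", "pa")))
  sp <- variable_spec(nodes, c("T0", "T1", "T2"),
                      c("continuous", "continuous", "continuous"),
                      c("determinant", "determinant", "outcome"))
  set.seed(64)
  d <- panel_dataset(data.frame(I = rnorm(100), M = rnorm(100),
                                pa = rnorm(100), check.names = FALSE), sp)
  frag <- extract_fragment(net, "I", "pa", dataset = d)
  dot <- to_dot(frag)
  expect_match(dot, "digraph")
  expect_match(dot, "penwidth=4")  # presence confidence 1.0
})
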