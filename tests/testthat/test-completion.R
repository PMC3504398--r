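test_that("sigma entries match brute-force enumeration and fit_node", {
  inst <- small_instance(101)
  for (v in inst$net$nodes) {
    tab <- sigma_table(inst$data, inst$net, v, H = 2, K = 2)
    regs <- regulators(inst$net, v)
    cand <- sort(setdiff(inst$net$nodes, c(v, regs)))
    # (0,0) equals the unmodified fit
    expect_equal(tab$sse[1, 1], fit_node(inst$data, v, regs)$sse,
                 tolerance = 1e-9)
    # every finite cell equals an independent exhaustive minimum
    for (hj in 0:2) for (kj in 0:2) {
      if (hj > length(regs) || kj > length(cand) ||
          length(regs) - hj + kj >= length(inst$net$nodes)) {
        expect_identical(tab$sse[hj + 1, kj + 1], Inf)
        next
      }
      best <- Inf
      dels <- if (hj == 0) list(character()) else
        utils::combn(regs, hj, simplify = FALSE)
      adds <- if (kj == 0) list(character()) else
        utils::combn(cand, kj, simplify = FALSE)
      for (d in dels) for (a in adds) {
        best <- min(best,
                    oracle_sse(inst$data, v, sort(c(setdiff(regs, d), a))))
      }
      expect_equal(tab$sse[hj + 1, kj + 1], best,
                   tolerance = 1e-8 * (1 + best))
      # recorded argmin sets have the declared sizes and are disjoint
      ds <- tab$deleted[[hj + 1, kj + 1]]
      as_ <- tab$added[[hj + 1, kj + 1]]
      expect_equal(length(ds), hj)
      expect_equal(length(as_), kj)
      expect_length(intersect(ds, as_), 0)
    }
  }
})

test_that("sigma sentinels appear exactly where entries are infeasible", {
  inst <- small_instance(103)
  v <- inst$net$nodes[1]
  deg <- unname(indegree(inst$net)[v])
  # k_j beyond the cap
  expect_identical(sigma_entry(inst$data, inst$net, v, k_j = 3, K = 2)$sse,
                   Inf)
  # k_j pushing indegree to n or beyond
  expect_identical(
    sigma_add(inst$data, inst$net, v,
              k_j = length(inst$net$nodes) - deg, K = 5)$sse, Inf)
  # h_j beyond the current indegree
  expect_identical(
    sigma_del(inst$data, inst$net, v, h_j = deg + 1, H = 5)$sse, Inf)
  # deletion to the empty set equals the intercept-only fit
  full <- sigma_del(inst$data, inst$net, v, h_j = deg, H = 5)
  expect_equal(full$sse, fit_node(inst$data, v)$sse, tolerance = 1e-9)
})

test_that("the dynamic program equals global exhaustive search", {
  # randomized small instances, all budgets up to 2
  set.seed(202)
  seeds <- sample.int(1e6, 50)
  budgets <- expand.grid(h = 0:2, k = 0:2)
  for (i in seq_along(seeds)) {
    inst <- small_instance(seeds[i])
    b <- budgets[(i - 1) %% nrow(budgets) + 1, ]
    res <- complete_network(inst$data, inst$net, h = b$h, k = b$k,
                            H = 2, K = 2)
    oracle <- oracle_complete(inst$data, inst$net, b$h, b$k,
                              H = 2, K = 2)
    if (!is.finite(oracle)) {
      expect_false(res$feasible)
      next
    }
    expect_equal(res$total_sse, oracle,
                 tolerance = 1e-9 * (1 + oracle))
    # budget conservation and SSE recomputation from the traceback
    expect_equal(sum(res$edits$action == "delete"), b$h)
    expect_equal(sum(res$edits$action == "add"), b$k)
    resse <- sum(vapply(res$completed$nodes, function(v)
      fit_node(inst$data, v, regulators(res$completed, v))$sse, 0))
    expect_equal(res$total_sse, resse,
                 tolerance = 1e-9 * (1 + resse))
    expect_false(any(res$completed$edges$from == res$completed$edges$to))
  }
})

test_that("zero budgets leave the network unchanged", {
  inst <- small_instance(301)
  res <- complete_network(inst$data, inst$net, h = 0, k = 0)
  expect_true(same_edges(res$completed, inst$net))
  expect_equal(nrow(res$edits), 0)
  base <- sum(vapply(inst$net$nodes, function(v)
    fit_node(inst$data, v, regulators(inst$net, v))$sse, 0))
  expect_equal(res$total_sse, base, tolerance = 1e-9)
  expect_true(same_edges(complete_by_addition(inst$data, inst$net,
                                              k = 0)$completed,
                         inst$net))
})

test_that("addition-only and deletion-only agree with the combined DP", {
  for (seed in c(401, 402, 403)) {
    inst <- small_instance(seed)
    for (k in 0:2) {
      a <- complete_by_addition(inst$data, inst$net, k = k, K = 2)
      c_ <- complete_network(inst$data, inst$net, h = 0, k = k,
                             H = 3, K = 2)
      expect_equal(a$total_sse, c_$total_sse,
                   tolerance = 1e-9 * (1 + abs(c_$total_sse)))
      expect_true(same_edges(a$completed, c_$completed))
    }
    for (h in 0:2) {
      d <- complete_by_deletion(inst$data, inst$net, h = h, H = 2)
      c_ <- complete_network(inst$data, inst$net, h = h, k = 0,
                             H = 2, K = 3)
      expect_equal(d$total_sse, c_$total_sse,
                   tolerance = 1e-9 * (1 + abs(c_$total_sse)))
    }
  }
})

test_that("optimal total SSE is invariant under node reordering", {
  inst <- small_instance(501)
  res <- complete_network(inst$data, inst$net, h = 1, k = 1, H = 2,
                          K = 2)
  for (rep in 1:3) {
    perm <- sample(inst$net$nodes)
    net2 <- grn(inst$net$edges, nodes = perm)
    res2 <- complete_network(inst$data, net2, h = 1, k = 1, H = 2,
                             K = 2)
    expect_equal(res2$total_sse, res$total_sse,
                 tolerance = 1e-9 * (1 + res$total_sse))
  }
})

test_that("relaxing the addition budget never hurts", {
  inst <- small_instance(601)
  prev <- Inf
  for (k in 0:3) {
    cur <- complete_by_addition(inst$data, inst$net, k = k,
                                K = 3)$total_sse
    expect_lte(cur, prev + 1e-9 * (1 + abs(cur)))
    prev <- cur
  }
})

test_that("deleting every edge yields the intercept-only total", {
  inst <- small_instance(701)
  ne <- nrow(inst$net$edges)
  res <- complete_by_deletion(inst$data, inst$net, h = ne,
                              H = max(indegree(inst$net)))
  expect_equal(nrow(res$completed$edges), 0)
  base <- sum(vapply(inst$net$nodes, function(v)
    fit_node(inst$data, v)$sse, 0))
  expect_equal(res$total_sse, base, tolerance = 1e-9 * (1 + base))
})

test_that("infeasible budgets return an explicit infeasible result", {
  inst <- small_instance(801)
  ne <- nrow(inst$net$edges)
  res <- complete_by_deletion(inst$data, inst$net, h = ne + 1,
                              H = max(indegree(inst$net)) + 1)
  expect_false(res$feasible)
  expect_identical(res$total_sse, Inf)
  expect_null(res$completed)
})

test_that("inference recovers a small network exactly from clean data", {
  withr::with_seed(42, {
    net <- grn(tibble::tibble(
      from = c("B", "C", "A", "D", "A", "B"),
      to = c("A", "A", "B", "B", "C", "D")))
    models <- sample_parameters(net)
    data <- noise_free_data(models, net$nodes, n_series = 6,
                            n_steps = 9)
  })
  res <- infer_network(data, k = nrow(net$edges), K = 2)
  expect_true(same_edges(res$completed, net))
  expect_equal(inference_accuracy(net, res$completed), 1)
  # zero budget: empty network stays empty
  res0 <- infer_network(data, k = 0)
  expect_equal(nrow(res0$completed$edges), 0)
})
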