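test_that("initial importance maps fold changes onto the node universe", {
  net <- gene_network(data.frame(from = c("g1", "g2"), to = c("g2", "g3")))
  degs <- deg_table(data.frame(record_id = c("r1", "r2"),
                               symbol = c("g1", "offnet"),
                               log2fc = c(-2, 1)))

  init <- build_initial_importance(degs, net, generank_config())
  expect_equal(init$ex[init$symbol == "g1"], 2) # |-2|
  expect_equal(init$ex[init$symbol == "g2"], 0) # no DEG record
  expect_true("offnet" %in% init$symbol) # DEG symbol off the network kept

  signed <- build_initial_importance(
    degs, net, generank_config(init_mode = "signed"))
  expect_equal(signed$ex[signed$symbol == "g1"], -2)

  norm <- build_initial_importance(
    deg_table(data.frame(record_id = c("r1", "r2"),
                         symbol = c("g1", "g2"), log2fc = c(3, 1))),
    net, generank_config(normalize_init = TRUE))
  expect_equal(sort(norm$ex, decreasing = TRUE)[1:2], c(0.75, 0.25))

  # duplicate symbols aggregate by maximum magnitude
  dup <- build_initial_importance(
    deg_table(data.frame(record_id = c("r1", "r2"),
                         symbol = c("g1", "g1"), log2fc = c(1, -3))),
    net, generank_config())
  expect_equal(dup$ex[dup$symbol == "g1"], 3)

  expect_warning(
    build_initial_importance(
      deg_table(data.frame(record_id = "r1", symbol = "g1", log2fc = 0)),
      net, generank_config()),
    "zero"
  )
})

test_that("d = 0 returns the initial importance exactly", {
  net <- base_er_network(25, 0.2, seed = 3)
  init <- random_init(net, seed = 4)
  fit <- generank(net, init, generank_config(d = 0))
  expect_identical(unname(fit$scores), init$ex)
  expect_equal(fit$iterations, 1L)
  direct <- generank_direct(net, init, generank_config(d = 0))
  expect_equal(unname(direct$scores), init$ex, tolerance = 1e-12)
})

test_that("the two-node system converges to the hand-solved fixed point", {
  cfg <- generank_config(d = 0.5)
  fit <- generank(two_node_network(), two_node_init(cfg), cfg)
  expect_equal(unname(fit$scores[c("g1", "g2")]), c(2 / 3, 1 / 3),
               tolerance = 1e-9)
  expect_lt(fit$fp_residual, 10 * cfg$tol)
  expect_equal(rank_genes(fit), c("g1", "g2"))
  expect_equal(select_top_k(rank_genes(fit), 1), "g1")
})

test_that("isolated genes keep only their damped initial importance", {
  net <- gene_network(data.frame(from = "g1", to = "g2"),
                      nodes = c("g1", "g2", "iso"))
  degs <- deg_table(data.frame(record_id = "r1", symbol = "iso",
                               log2fc = 4))
  init <- build_initial_importance(degs, net, generank_config())
  fit <- generank(net, init, generank_config(d = 0.5))
  expect_equal(fit$scores[["iso"]], 0.5 * 4)
})

test_that("the iterative solver matches an independent dense solve", {
  # 5-node graph solved with base::solve on a dense system built by hand
  edges <- data.frame(from = c("a", "a", "b", "c", "d"),
                      to   = c("b", "c", "c", "d", "e"))
  net <- gene_network(edges)
  syms <- net$nodes
  n <- length(syms)
  W <- matrix(0, n, n, dimnames = list(syms, syms))
  for (k in seq_len(nrow(edges))) {
    W[edges$from[k], edges$to[k]] <- 1
    W[edges$to[k], edges$from[k]] <- 1
  }
  deg <- rowSums(W)
  set.seed(11)
  ex <- stats::setNames(abs(stats::rnorm(n)), syms)
  for (d in c(0.3, 0.5, 0.9)) {
    expected <- solve(diag(n) - d * W %*% diag(1 / deg), (1 - d) * ex)
    degs <- deg_table(data.frame(record_id = paste0("r", 1:n),
                                 symbol = syms, log2fc = unname(ex)))
    init <- build_initial_importance(degs, net, generank_config())
    fit <- generank(net, init, generank_config(d = d))
    expect_equal(unname(fit$scores[syms]), as.numeric(expected),
                 tolerance = 1e-8)
  }
})

test_that("iterative and direct solvers agree on random graphs", {
  cfg_grid <- expand.grid(seed = 1:6, d = c(0, 0.3, 0.5, 0.9))
  for (k in seq_len(nrow(cfg_grid))) {
    net <- base_er_network(40, 0.1, seed = cfg_grid$seed[k])
    init <- random_init(net, seed = 100 + cfg_grid$seed[k])
    cfg <- generank_config(d = cfg_grid$d[k])
    gap <- max(abs(generank(net, init, cfg)$scores -
                     generank_direct(net, init, cfg)$scores))
    expect_lt(gap, 1e-6)
  }
})

test_that("scores are conserved, linear in ex, and non-negative", {
  for (seed in 1:5) {
    net <- base_er_network(40, 0.25, seed = seed) # dense enough: no isolates
    if (any(net$degree == 0L)) next
    init <- random_init(net, seed = seed + 50)
    fit <- generank(net, init, generank_config(d = 0.5))
    # conservation on graphs without isolated nodes
    expect_equal(sum(fit$scores), sum(init$ex), tolerance = 1e-8)
    # non-negativity under absolute-mode initialization
    expect_true(all(fit$scores >= 0))
    # linearity: scaling ex scales r
    scaled <- init
    scaled$ex <- scaled$ex * 7.5
    fit2 <- generank(net, scaled, generank_config(d = 0.5))
    expect_equal(unname(fit2$scores), unname(fit$scores) * 7.5,
                 tolerance = 1e-9)
  }

  # with isolated nodes the total can only shrink
  net <- gene_network(data.frame(from = "g1", to = "g2"),
                      nodes = c("g1", "g2", "iso"))
  degs <- deg_table(data.frame(record_id = 1:3,
                               symbol = c("g1", "g2", "iso"),
                               log2fc = c(1, 1, 1)))
  init <- build_initial_importance(degs, net, generank_config())
  fit <- generank(net, init, generank_config(d = 0.5))
  expect_lt(sum(fit$scores), sum(init$ex))
})

test_that("cycle symmetry gives equal scores under uniform ex", {
  n <- 12
  syms <- sprintf("c%02d", 1:n)
  net <- gene_network(data.frame(from = syms, to = syms[c(2:n, 1)]))
  degs <- deg_table(data.frame(record_id = paste0("r", 1:n), symbol = syms,
                               log2fc = 1))
  init <- build_initial_importance(degs, net, generank_config())
  fit <- generank(net, init, generank_config(d = 0.7))
  expect_lt(diff(range(fit$scores)), 1e-10)
})

test_that("convergence is geometric with rate at most d", {
  for (seed in 1:4) {
    net <- base_er_network(50, 0.2, seed = seed)
    if (any(net$degree == 0L)) next
    init <- random_init(net, seed = seed + 10)
    d <- 0.5
    cfg <- generank_config(d = d, tol = 1e-9)
    fit <- generank(net, init, cfg)
    # one explicit step to size the first increment
    pt_ex <- stats::setNames(init$ex, init$symbol)
    r1 <- (1 - d) * init$ex +
      d * vapply(init$symbol, function(j) {
        nb <- c(net$edges$to[net$edges$from == j],
                net$edges$from[net$edges$to == j])
        sum(pt_ex[nb] / net$degree[nb])
      }, numeric(1))
    step1 <- sum(abs(r1 - init$ex))
    bound <- ceiling(log(cfg$tol / step1) / log(d)) + 1
    expect_lte(fit$iterations, bound)
  }
})

test_that("non-convergence raises an explicit error carrying the residual", {
  net <- base_er_network(30, 0.2, seed = 2)
  init <- random_init(net, seed = 2)
  err <- tryCatch(
    generank(net, init, generank_config(d = 0.9, tol = 1e-12, max_iter = 3)),
    condition = identity
  )
  expect_s3_class(err, "herbrank_nonconvergence")
  expect_true(is.finite(err$residual))
})

test_that("ranking is descending with deterministic symbol tie-break", {
  expect_equal(rank_genes(c(a = 0.2, b = 0.5)), c("b", "a"))
  expect_equal(rank_genes(c(b = 0.3, a = 0.3)), c("a", "b"))
  expect_equal(select_top_k(letters[1:5], 3), c("a", "b", "c"))
  expect_equal(select_top_k(letters[1:5], 300), letters[1:5])
})

test_that("tidy/glance expose the fit as tables", {
  cfg <- generank_config(d = 0.5)
  fit <- generank(two_node_network(), two_node_init(cfg), cfg)
  td <- tidy(fit)
  expect_equal(td$symbol, c("g1", "g2"))
  expect_equal(td$score, c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(td$ex, c(1, 0))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 2L)
  expect_lt(gl$final_residual, cfg$tol)
  expect_s3_class(autoplot(fit), "ggplot")
})
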