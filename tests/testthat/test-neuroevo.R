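# A hand-constructed single-hidden-unit AND network: the hidden unit fires
# only when both inputs are on, and the output follows the hidden unit.
hand_and_net <- function() {
  net <- structure(list(w_in = matrix(0, 2, 1), b_hid = 0, w_out = 0,
                        b_out = 0, steepness = 1, n_hidden = 1L),
                   class = "layered_network")
  net$w_in <- matrix(c(10, 10), 2, 1)
  net$b_hid <- -15          # fires iff x1 + x2 == 2
  net$w_out <- 10
  net$b_out <- -5           # output on iff hidden fires
  net
}

test_that("forward pass is a bounded sigmoid feedforward", {
  set.seed(1)
  net <- layered_network(5)
  zero <- unflatten_network(rep(0, 21), net)
  expect_equal(forward(zero, c(0, 0)), 0.5)
  expect_equal(forward(zero, c(1, 1)), 0.5)
  outs <- forward(net, gate_truth_tables()$and$inputs)
  expect_length(outs, 4L)
  expect_true(all(outs > 0 & outs < 1))
})

test_that("the analytic AND construction implements AND and only AND", {
  tasks <- gate_truth_tables()
  net <- hand_and_net()
  expect_identical(forward(net, tasks$and$inputs) >= 0.5,
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_true(implements_gate(net, tasks$and))
  expect_false(implements_gate(net, tasks$xor))
  # exactness is invariant under a rescaling that preserves every margin
  scaled <- unflatten_network(flatten_network(net) * 1.7, net)
  expect_true(implements_gate(scaled, tasks$and))
  # the all-zero network binarizes to constant 1: exact for neither gate
  zero <- unflatten_network(rep(0, 4 * net$n_hidden + 1), net)
  expect_false(implements_gate(zero, tasks$and))
  expect_false(implements_gate(zero, tasks$xor))
})

test_that("training reduces the loss, keeps pruned weights at zero, and can be skipped", {
  tasks <- gate_truth_tables()
  set.seed(2)
  net <- layered_network(8)
  net$w_in[1, 3] <- 0                      # prune one connection by hand
  same <- train_network(net, tasks$and, epochs = 0)
  expect_identical(same, net)
  mse <- function(nn, task) mean((forward(nn, task$inputs) - task$targets)^2)
  # loss is non-increasing epoch by epoch for a small enough rate
  losses <- numeric(30)
  cur <- net
  for (k in 1:30) {
    cur <- train_network(cur, tasks$and, epochs = 1, rate = 0.05)
    losses[k] <- mse(cur, tasks$and)
  }
  expect_true(all(diff(losses) <= 1e-12))
  expect_identical(cur$w_in[1, 3], 0)      # architecture fixed during learning
})

test_that("a full-width network learns XOR from most initialisations", {
  task <- gate_truth_tables()$xor
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    net <- train_network(layered_network(30), task, epochs = 400, rate = 2)
    if (implements_gate(net, task)) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("Q, sigma and F follow their closed forms", {
  tasks <- gate_truth_tables()
  set.seed(3)
  net <- layered_network(6)
  zero <- unflatten_network(rep(0, 25), net)
  # constant-0.5 output on a balanced gate: MSE 0.25, Q 0.75
  expect_equal(task_fitness_Q(zero, tasks$xor), 0.75)
  expect_equal(task_fitness_Q(zero, tasks$and), 0.75)
  # Q matches an independent MSE computation on a random net
  expect_equal(task_fitness_Q(net, tasks$and),
               1 - mean((forward(net, tasks$and$inputs) -
                           tasks$and$targets)^2))
  expect_identical(size_cost_sigma(net), 1)      # freshly drawn: no zeros
  expect_identical(size_cost_sigma(zero), 0)
  pruned <- net
  pruned$w_out[2] <- 0
  expect_lt(size_cost_sigma(pruned), 1)
  expect_equal(fitness_F(net, tasks$and, 0), task_fitness_Q(net, tasks$and))
  expect_equal(fitness_F(zero, tasks$and, 1), 0.75)
  # F decreases in sigma at fixed Q and lambda > 0
  expect_gt(fitness_F(pruned, tasks$and, 0.5) -
              task_fitness_Q(pruned, tasks$and),
            fitness_F(net, tasks$and, 0.5) - task_fitness_Q(net, tasks$and))
})

test_that("network crossover swaps genome tails and conserves weights", {
  set.seed(4)
  p1 <- layered_network(4)
  p2 <- layered_network(4)
  expect_error(crossover_networks(p1, layered_network(5)), "architectures")
  for (i in 1:50) {
    kids <- crossover_networks(p1, p2)
    g <- c(flatten_network(kids[[1]]), flatten_network(kids[[2]]))
    expect_identical(sort(g),
                     sort(c(flatten_network(p1), flatten_network(p2))))
  }
  # self-crossover yields two copies of the parent
  kids <- crossover_networks(p1, p1)
  expect_identical(flatten_network(kids[[1]]), flatten_network(p1))
  expect_identical(flatten_network(kids[[2]]), flatten_network(p1))
  # flatten/unflatten round-trip
  expect_identical(flatten_network(unflatten_network(flatten_network(p1), p1)),
                   flatten_network(p1))
})

test_that("mutation and pruning behave as specified", {
  set.seed(5)
  net <- layered_network(4)
  # no mutation, no sub-threshold weights: unchanged
  expect_identical(flatten_network(mutate_and_prune(net, p_mut = 0,
                                                    prune_threshold = 0)),
                   flatten_network(net))
  # a weight below threshold is exactly zeroed even without mutation
  small <- net
  small$w_out[1] <- 0.01
  out <- mutate_and_prune(small, p_mut = 0, prune_threshold = 0.05)
  expect_identical(out$w_out[1], 0)
  # pruning never increases sigma; pruned weights are never revived
  for (i in 1:20) {
    before <- mutate_and_prune(net, p_mut = 1, scale = 0.5)
    after <- mutate_and_prune(before, p_mut = 0)
    expect_lte(size_cost_sigma(after), size_cost_sigma(before))
    expect_true(all(flatten_network(after)[flatten_network(before) == 0] == 0))
  }
})

test_that("active hidden units are counted from output connections", {
  net <- hand_and_net()
  expect_identical(active_hidden_units(net), 1L)
  net$w_out <- 0
  expect_identical(active_hidden_units(net), 0L)
})

test_that("network evolution is seed-reproducible and flags exactness honestly", {
  task <- gate_truth_tables()$and
  cfg <- evo_config(generations = 3, epochs = 30, seed = 7)
  ra <- evolve_networks(cfg, task)
  rb <- evolve_networks(cfg, task)
  expect_identical(flatten_network(ra$champion), flatten_network(rb$champion))
  expect_identical(ra$history, rb$history)
  # the champion's exact flag re-verifies post hoc
  expect_identical(ra$exact, implements_gate(ra$champion, task))
  expect_identical(ra$sigma, size_cost_sigma(ra$champion))
})

test_that("champion sparsity trends downward across the lambda grid, for both gates", {
  grid <- c(0, 0.05, 0.1, 0.2)
  for (gate in c("and", "xor")) {
    runs <- expand.grid(lambda = grid, seed = 1:10)
    runs$sigma <- mapply(function(l, s) run_nn(gate, l, s)$sigma,
                         runs$lambda, runs$seed)
    # statistical trend: sparsity decreases with lambda
    ct <- suppressWarnings(stats::cor.test(runs$lambda, runs$sigma,
                                           method = "spearman",
                                           alternative = "less"))
    expect_lt(ct$p.value, 0.05)
    med <- tapply(runs$sigma, runs$lambda, median)
    expect_lt(med[["0.2"]], med[["0"]])
  }
})

test_that("under size pressure AND champions are usually no larger than XOR champions", {
  # AND is linearly separable, XOR is not; once lambda makes size count,
  # the ordering shows up in the nonzero-connection counts seed by seed
  nz <- function(r) sum(flatten_network(r$champion) != 0)
  wins <- sum(vapply(1:10, function(s)
    nz(run_nn("and", 0.1, s)) <= nz(run_nn("xor", 0.1, s)), logical(1)))
  expect_gte(wins, 6L)
})
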