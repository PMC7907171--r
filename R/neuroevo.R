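## Size-penalized neuroevolution of one-hidden-layer networks toward
## minimal AND/XOR implementations.  Each generation every member is
## trained by batch gradient descent with its architecture held fixed
## (pruned connections stay zero), rated by F = Q - lambda * sigma, and the
## next generation is built by wheel-of-fortune parental choice, one-point
## crossover on the flattened weight vector, Gaussian mutation, and
## small-weight pruning.

#' Construct a layered network
#'
#' Two inputs, one hidden layer of `n_hidden` units, one output unit.
#' Neurons have zero intrinsic firing threshold; thresholds are realised
#' only through bias connections (inputs clamped to 1), which count as
#' connections for the size measure.  A connection with weight exactly zero
#' is pruned: training never moves it.
#'
#' @param n_hidden Hidden-layer width (default 30).
#' @param init_sd Standard deviation of the random initial weights.
#' @param steepness Slope of the sigmoid activation.
#' @return A `layered_network`: list with `w_in` (2 x H), `b_hid` (H),
#'   `w_out` (H), `b_out` (scalar), `steepness`, `n_hidden`.
#' @export
layered_network <- function(n_hidden = 30L, init_sd = 1, steepness = 1) {
  stopifnot(n_hidden >= 1L, init_sd >= 0, steepness > 0)
  structure(list(w_in = matrix(stats::rnorm(2L * n_hidden, sd = init_sd),
                               2L, n_hidden),
                 b_hid = stats::rnorm(n_hidden, sd = init_sd),
                 w_out = stats::rnorm(n_hidden, sd = init_sd),
                 b_out = stats::rnorm(1L, sd = init_sd),
                 steepness = steepness, n_hidden = as.integer(n_hidden)),
            class = "layered_network")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Feedforward pass
#'
#' @param net A `layered_network`.
#' @param inputs Numeric matrix with one row per pattern and two columns
#'   (a single pattern may be given as a length-2 vector).
#' @return Numeric vector of outputs in `(0, 1)`, one per pattern.  The
#'   binarised prediction is `output >= 0.5`.
#' @export
forward <- function(net, inputs) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L)
  h <- sigmoid(net$steepness *
                 (inputs %*% net$w_in +
                    rep(net$b_hid, each = nrow(inputs))))
  as.vector(sigmoid(net$steepness * (h %*% net$w_out + net$b_out)))
}

#' Train a network on a gate task
#'
#' Batch gradient descent on the mean squared error over the four
#' truth-table patterns, with the architecture held fixed: gradients of
#' pruned (exactly zero) connections are masked, so pruned connections stay
#' exactly zero.
#'
#' @param net A `layered_network`.
#' @param task A `gate_task` from [gate_truth_tables()].
#' @param epochs Number of full-batch updates.
#' @param rate Learning rate.
#' @return The trained `layered_network`.
#' @export
train_network <- function(net, task, epochs = 100L, rate = 2) {
  x <- unname(task$inputs)      # 4 x 2
  y <- task$targets             # length 4
  k <- net$steepness
  m_in <- net$w_in != 0
  m_bh <- net$b_hid != 0
  m_out <- net$w_out != 0
  m_bo <- net$b_out != 0
  if (epochs > 0) for (e in seq_len(epochs)) {
    zh <- x %*% net$w_in + rep(net$b_hid, each = 4L)
    h <- sigmoid(k * zh)                          # 4 x H
    zo <- as.vector(h %*% net$w_out + net$b_out)
    o <- sigmoid(k * zo)                          # length 4
    if (!all(is.finite(o))) stop("non-finite activations: learning diverged")
    # d(MSE)/d(o) with MSE = mean((o - y)^2)
    do <- 2 * (o - y) / 4
    dzo <- do * o * (1 - o) * k                   # length 4
    g_wout <- as.vector(crossprod(h, dzo))        # length H
    g_bout <- sum(dzo)
    dh <- outer(dzo, net$w_out)                   # 4 x H
    dzh <- dh * h * (1 - h) * k
    g_win <- crossprod(x, dzh)                    # 2 x H
    g_bhid <- colSums(dzh)
    net$w_in <- net$w_in - rate * g_win * m_in
    net$b_hid <- net$b_hid - rate * g_bhid * m_bh
    net$w_out <- net$w_out - rate * g_wout * m_out
    net$b_out <- net$b_out - rate * g_bout * m_bo
  }
  net
}

#' Task fitness Q
#'
#' `Q = 1 - MSE` over the four truth-table patterns: 1 for a saturated
#' perfect implementation, 0.75 for a constant-0.5 network on a balanced
#' gate.  Continuous, so the selection wheel stays informative before any
#' member is exact.
#'
#' @param net A `layered_network`.
#' @param task A `gate_task`.
#' @return Numeric in `[0, 1]`.
#' @export
task_fitness_Q <- function(net, task) {
  1 - mean((forward(net, task$inputs) - task$targets)^2)
}

#' Network size cost sigma
#'
#' The fraction of the full architecture's connections (biases included)
#' that are unpruned: `sigma = nonzero / (4 * H + 1)`.  1 for a fully
#' connected network, 0 if everything is pruned.
#'
#' @param net A `layered_network`.
#' @return Numeric in `[0, 1]`.
#' @export
size_cost_sigma <- function(net) {
  nz <- sum(net$w_in != 0) + sum(net$b_hid != 0) +
    sum(net$w_out != 0) + sum(net$b_out != 0)
  nz / (4 * net$n_hidden + 1)
}

#' Size-penalized fitness
#'
#' `F = Q - lambda * sigma`: at `lambda = 0` selection sees only task
#' performance and tolerates full connectivity; increasing `lambda` biases
#' the population toward the sparsest networks that still solve the task.
#'
#' @param net A `layered_network`.
#' @param task A `gate_task`.
#' @param lambda Size-penalty weight in `[0, 1]`.
#' @return Numeric fitness (may be negative for large `lambda`).
#' @export
fitness_F <- function(net, task, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  task_fitness_Q(net, task) - lambda * size_cost_sigma(net)
}

#' Exact gate implementation test
#'
#' @param net A `layered_network`.
#' @param task A `gate_task`.
#' @return `TRUE` iff the binarised outputs (`>= 0.5`) match the task
#'   targets on all four rows.
#' @export
implements_gate <- function(net, task) {
  all((forward(net, task$inputs) >= 0.5) == (task$targets == 1))
}

#' Number of active hidden units
#'
#' A hidden unit is active when its output connection is unpruned.
#'
#' @param net A `layered_network`.
#' @return Integer count.
#' @export
active_hidden_units <- function(net) sum(net$w_out != 0)

## ---- genome flattening and variation ---------------------------------------

#' Flatten / restore network weights
#'
#' Fixed genome order (required for reproducible crossover): input-to-hidden
#' weights column-major by hidden unit, then hidden biases, then
#' hidden-to-output weights, then the output bias.
#'
#' @param net A `layered_network`.
#' @param genome Numeric vector of length `4 * n_hidden + 1`.
#' @return `flatten_network()`: the genome vector; `unflatten_network()`:
#'   a `layered_network`.
#' @export
flatten_network <- function(net) {
  c(as.vector(net$w_in), net$b_hid, net$w_out, net$b_out)
}

#' @rdname flatten_network
#' @export
unflatten_network <- function(genome, net) {
  h <- net$n_hidden
  stopifnot(length(genome) == 4L * h + 1L)
  net$w_in <- matrix(genome[seq_len(2L * h)], 2L, h)
  net$b_hid <- genome[2L * h + seq_len(h)]
  net$w_out <- genome[3L * h + seq_len(h)]
  net$b_out <- genome[4L * h + 1L]
  net
}

#' One-point crossover of two networks
#'
#' Parents are cut into two parts each at a single uniformly chosen point
#' of the flattened genome and recomposed crosswise; a cut at position 0
#' simply swaps the parents.  The multiset of weights is conserved.
#'
#' @param p1,p2 `layered_network`s of identical architecture.
#' @return List of two offspring `layered_network`s.
#' @export
crossover_networks <- function(p1, p2) {
  if (p1$n_hidden != p2$n_hidden)
    stop("parents have different architectures")
  g1 <- flatten_network(p1)
  g2 <- flatten_network(p2)
  n <- length(g1)
  cut <- sample(0:(n - 1L), 1L)
  head1 <- seq_len(cut)
  o1 <- c(g1[head1], g2[setdiff(seq_len(n), head1)])
  o2 <- c(g2[head1], g1[setdiff(seq_len(n), head1)])
  list(unflatten_network(o1, p1), unflatten_network(o2, p2))
}

#' Mutate and prune a network
#'
#' Each unpruned weight is perturbed with probability `p_mut` by Gaussian
#' noise of standard deviation `scale`; afterwards every weight with
#' magnitude below `prune_threshold` is set to exactly zero.  Pruning can
#' only decrease `sigma`; pruned connections are never revived.
#'
#' @param net A `layered_network`.
#' @param p_mut Per-weight mutation probability.
#' @param scale Mutation standard deviation.
#' @param prune_threshold Magnitude below which weights are zeroed.
#' @return The mutated, pruned `layered_network`.
#' @export
mutate_and_prune <- function(net, p_mut = 0.2, scale = 0.3,
                             prune_threshold = 0.05) {
  g <- flatten_network(net)
  live <- g != 0
  hit <- live & (stats::runif(length(g)) < p_mut)
  g[hit] <- g[hit] + stats::rnorm(sum(hit), sd = scale)
  g[abs(g) < prune_threshold] <- 0
  unflatten_network(g, net)
}

#' Export a network's weights
#'
#' `write_network()` writes a long-format TSV (`layer`, `from`, `to`,
#' `weight`) of the unpruned connections; `network_dot()` renders the same
#' adjacency as a GraphViz DOT diagram (inputs at the bottom, output on
#' top, bias connections drawn from clamped `bias` nodes), which is the
#' conventional way to display the minimal evolved topologies.
#'
#' @param net A `layered_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path) {
  rows <- list()
  add <- function(layer, from, to, w) {
    if (w != 0)
      rows[[length(rows) + 1L]] <<- data.frame(layer = layer, from = from,
                                               to = to, weight = w)
  }
  for (h in seq_len(net$n_hidden)) {
    for (i in 1:2) add("input_hidden", paste0("x", i), paste0("h", h),
                       net$w_in[i, h])
    add("bias_hidden", "bias", paste0("h", h), net$b_hid[h])
    add("hidden_output", paste0("h", h), "out", net$w_out[h])
  }
  add("bias_output", "bias", "out", net$b_out)
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
network_dot <- function(net, path) {
  lines <- c("digraph network {", "  rankdir=BT;",
             "  node [shape=circle];")
  edge <- function(from, to, w)
    sprintf("  %s -> %s [label=\"%.2f\"];", from, to, w)
  for (h in seq_len(net$n_hidden)) {
    live <- net$w_out[h] != 0 || any(net$w_in[, h] != 0)
    if (!live) next
    for (i in 1:2) if (net$w_in[i, h] != 0)
      lines <- c(lines, edge(paste0("x", i), paste0("h", h), net$w_in[i, h]))
    if (net$b_hid[h] != 0)
      lines <- c(lines, edge(paste0("bias_h", h), paste0("h", h),
                             net$b_hid[h]))
    if (net$w_out[h] != 0)
      lines <- c(lines, edge(paste0("h", h), "out", net$w_out[h]))
  }
  if (net$b_out != 0) lines <- c(lines, edge("bias_out", "out", net$b_out))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

## ---- evolutionary loop -----------------------------------------------------

#' Neuroevolution configuration
#'
#' @param pop_size Population size (default 20).
#' @param n_hidden Hidden-layer width (default 30).
#' @param lambda Size-penalty weight in `[0, 1]`.
#' @param generations Generation cap.
#' @param epochs,rate Gradient-descent epochs and learning rate per
#'   generation (training is cumulative: offspring inherit trained
#'   weights).
#' @param p_mut,mut_scale,prune_threshold See [mutate_and_prune()].
#' @param init_sd,steepness See [layered_network()].
#' @param elitism Copy the best member unchanged each generation.
#' @param seed Integer seed for the run.
#' @return An `evo_config` list.
#' @export
evo_config <- function(pop_size = 20L, n_hidden = 30L, lambda = 0,
                       generations = 25L, epochs = 60L, rate = 2,
                       p_mut = 0.3, mut_scale = 0.4, prune_threshold = 0.1,
                       init_sd = 1, steepness = 1, elitism = TRUE,
                       seed = 1L) {
  stopifnot(pop_size >= 2L, n_hidden >= 1L, lambda >= 0, lambda <= 1,
            generations >= 0L, epochs >= 0L, rate > 0)
  structure(as.list(environment()), class = "evo_config")
}

#' Evolve networks toward a minimal gate implementation
#'
#' Generational loop under the size-penalized fitness: every member is
#' trained with its architecture fixed, rated by `F = Q - lambda * sigma`,
#' and parents are chosen by a wheel of fortune on `F` shifted to be
#' non-negative (`F - min(F) + eps`, since `F` can be negative for
#' `lambda > 0`).  Offspring arise by one-point genome crossover, then
#' Gaussian mutation and small-weight pruning.  The champion is the
#' highest-`F` member seen in any generation that exactly implements the
#' gate; if none is found within the cap the best non-exact member is
#' returned flagged `exact = FALSE`.
#'
#' @param config An [evo_config()].
#' @param task A `gate_task`.
#' @return List: `champion` (`layered_network`), `exact` (logical), `F`,
#'   `Q`, `sigma` of the champion, `history` (per-generation best F, Q of
#'   the best-F member, its sigma, and whether any member is exact),
#'   `config`.
#' @export
evolve_networks <- function(config, task) {
  set.seed(config$seed)
  pop <- replicate(config$pop_size,
                   layered_network(config$n_hidden, config$init_sd,
                                   config$steepness),
                   simplify = FALSE)
  best_exact <- NULL
  best_any <- NULL
  history <- NULL

  for (gen in 0:config$generations) {
    pop <- lapply(pop, train_network, task = task,
                  epochs = config$epochs, rate = config$rate)
    fF <- vapply(pop, fitness_F, numeric(1), task = task,
                 lambda = config$lambda)
    exact <- vapply(pop, implements_gate, logical(1), task = task)
    ib <- which.max(fF)
    if (is.null(best_any) || fF[ib] > best_any$F)
      best_any <- list(net = pop[[ib]], F = fF[ib])
    if (any(exact)) {
      ie <- which(exact)[which.max(fF[exact])]
      if (is.null(best_exact) || fF[ie] > best_exact$F)
        best_exact <- list(net = pop[[ie]], F = fF[ie])
    }
    history <- rbind(history,
                     data.frame(generation = gen, best_F = fF[ib],
                                Q = task_fitness_Q(pop[[ib]], task),
                                sigma = size_cost_sigma(pop[[ib]]),
                                any_exact = any(exact)))
    if (gen == config$generations) break

    shifted <- fF - min(fF) + 1e-6
    nxt <- vector("list", config$pop_size)
    slot <- 1L
    if (config$elitism) {
      nxt[[1L]] <- pop[[ib]]
      slot <- 2L
    }
    while (slot <= config$pop_size) {
      a <- pop[[roulette_select(shifted)]]
      b <- pop[[roulette_select(shifted)]]
      kids <- crossover_networks(a, b)
      for (k in 1:2) {
        if (slot > config$pop_size) break
        nxt[[slot]] <- mutate_and_prune(kids[[k]], config$p_mut,
                                        config$mut_scale,
                                        config$prune_threshold)
        slot <- slot + 1L
      }
    }
    pop <- nxt
  }

  champ <- if (!is.null(best_exact)) best_exact else best_any
  list(champion = champ$net, exact = !is.null(best_exact), F = champ$F,
       Q = task_fitness_Q(champ$net, task),
       sigma = size_cost_sigma(champ$net), history = history,
       config = config)
}
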