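## Tree-based genetic programming over boolean control programs for the
## wall-following task: biased random program generation,
## fitness-proportionate (wheel of fortune) selection, subtree crossover and
## mutation, with elitism and a node-count cap against bloat.

#' GP run configuration
#'
#' @param pop_size Population size (>= 2).
#' @param generations Generation cap.
#' @param p_crossover Probability that a selected parent pair is recombined
#'   by subtree exchange (otherwise copied).
#' @param p_mutation Per-offspring probability of subtree-replacement
#'   mutation.  The default is deliberately generous: with
#'   fitness-proportionate selection the population's fitness spread
#'   flattens late in a run, and mutation is then the main source of
#'   further progress.
#' @param bias Positive weights for drawing internal node kinds during
#'   random program growth, named `if`, `and`, `or`, `not`, `terminal`.
#'   Function symbols are deliberately favoured over terminals so random
#'   programs have computational depth.
#' @param max_depth Depth bound for random program growth.
#' @param journey_length Steps per fitness journey.  The default comfortably
#'   exceeds the free-cell count of the reference labyrinths, so a journey
#'   realises the controller's full reachable coverage.
#' @param n_starts Number of random free starting cells per fitness
#'   evaluation; frozen once per run for variance reduction.
#' @param size_cap Maximum node count of any individual (bloat control);
#'   offspring exceeding it revert to their first parent.  The default of
#'   120 nodes is roughly three times the size of the packaged reference
#'   wall-follower, which keeps the search space expressive while
#'   preventing the runaway bloat that stalls tree-GP runs.
#' @param elitism Copy the best individual unchanged into the next
#'   generation (makes best-so-far fitness non-decreasing).
#' @param seed Integer seed making the whole run reproducible.
#' @return A `gp_config` list.
#' @export
gp_config <- function(pop_size = 200L, generations = 500L,
                      p_crossover = 0.9, p_mutation = 0.25,
                      bias = c("if" = 4, "and" = 4, "or" = 4, "not" = 2,
                               terminal = 2),
                      max_depth = 6L, journey_length = 150L, n_starts = 10L,
                      size_cap = 120L, elitism = TRUE, seed = 1L) {
  stopifnot(pop_size >= 2L, generations >= 0L,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            all(bias > 0), length(bias) == 5L,
            max_depth >= 0L, journey_length >= 1L, n_starts >= 1L,
            size_cap >= 1L)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 bias = bias, max_depth = as.integer(max_depth),
                 journey_length = as.integer(journey_length),
                 n_starts = as.integer(n_starts),
                 size_cap = as.integer(size_cap),
                 elitism = isTRUE(elitism), seed = as.integer(seed)),
            class = "gp_config")
}

#' Grow a random program
#'
#' Recursive "grow" initialisation: at each node below the depth bound an
#' internal kind or a terminal is drawn with the configured bias weights; at
#' the bound a terminal is forced.  Terminals are uniform over the 12
#' variables plus `True`/`False`.
#'
#' @param config A [gp_config()].
#' @param depth Depth budget (defaults to the configured bound).
#' @return A `bool_expr`.
#' @export
random_program <- function(config, depth = config$max_depth) {
  cum <- cumsum(config$bias) / sum(config$bias)   # if, and, or, not, terminal
  vocab <- bool_vocab()
  terminal <- function() {
    pick <- sample.int(14L, 1L)
    if (pick <= 12L) new_bx("var", name = vocab[pick])
    else new_bx("const", value = pick == 13L)
  }
  grow <- function(depth) {
    if (depth <= 0L) return(terminal())
    kind <- findInterval(stats::runif(1), cum, left.open = TRUE) + 1L
    switch(kind,
      new_bx("if", list(grow(depth - 1L), grow(depth - 1L),
                        grow(depth - 1L))),
      new_bx("and", list(grow(depth - 1L), grow(depth - 1L))),
      new_bx("or", list(grow(depth - 1L), grow(depth - 1L))),
      new_bx("not", list(grow(depth - 1L))),
      terminal())
  }
  grow(depth)
}

## ---- subtree indexing ------------------------------------------------------

# Subtrees are addressed by preorder index (1 = root).
subtree_at <- function(expr, index) {
  k <- 0L
  found <- NULL
  walk <- function(e) {
    k <<- k + 1L
    if (k == index) {
      found <<- e
      return(TRUE)
    }
    for (a in e$args) if (walk(a)) return(TRUE)
    FALSE
  }
  walk(expr)
  if (is.null(found)) stop("subtree index out of range: ", index)
  found
}

replace_subtree <- function(expr, index, replacement) {
  k <- 0L
  walk <- function(e) {
    k <<- k + 1L
    if (k == index) return(replacement)
    if (length(e$args)) {
      for (j in seq_along(e$args)) {
        if (k >= index) break
        e$args[[j]] <- walk(e$args[[j]])
      }
    }
    e
  }
  walk(expr)
}

#' Subtree crossover
#'
#' Exchanges a uniformly chosen subtree of each parent, producing two
#' offspring.  The multiset of leaf tokens over the two offspring equals
#' that over the two parents.
#'
#' @param p1,p2 Parent `bool_expr`s.
#' @return List of two `bool_expr` offspring.
#' @export
crossover_programs <- function(p1, p2) {
  i1 <- sample.int(expr_size(p1), 1L)
  i2 <- sample.int(expr_size(p2), 1L)
  s1 <- subtree_at(p1, i1)
  s2 <- subtree_at(p2, i2)
  list(replace_subtree(p1, i1, s2), replace_subtree(p2, i2, s1))
}

#' Subtree mutation
#'
#' With probability `config$p_mutation`, replaces a uniformly chosen node's
#' subtree with a freshly grown random program (depth budget half the
#' configured bound, at least 1); otherwise the program is returned
#' unchanged.
#'
#' @param program A `bool_expr`.
#' @param config A [gp_config()].
#' @return A `bool_expr`.
#' @export
mutate_program <- function(program, config) {
  if (stats::runif(1) >= config$p_mutation) return(program)
  i <- sample.int(expr_size(program), 1L)
  replace_subtree(program, i,
                  random_program(config, max(1L, config$max_depth %/% 2L)))
}

#' Wheel-of-fortune selection
#'
#' Selects an index with probability proportional to fitness.  When every
#' fitness is zero (or the total does not allow a proportional draw) the
#' fallback is uniform selection.
#'
#' @param fitness Numeric vector of non-negative fitnesses.
#' @return A single index in `seq_along(fitness)`.
#' @export
roulette_select <- function(fitness) {
  if (length(fitness) == 0L) stop("empty population")
  if (any(fitness < 0)) stop("negative fitness")
  total <- sum(fitness)
  if (total <= 0) return(sample.int(length(fitness), 1L))
  sample.int(length(fitness), 1L, prob = fitness / total)
}

#' Rate a program's wall-coverage fitness
#'
#' Fitness is the mean number of distinct wall cells covered over journeys
#' of fixed length from each of the supplied starting cells — how many
#' different parts of the wall the robot visits.  Uses the
#' fast table-driven simulator; equivalence with the step-by-step simulator
#' is tested.
#'
#' @param program A `bool_expr`.
#' @param tables A [world_tables()] (or a `grid_world`).
#' @param starts Integer vector of free-cell ordinals (into
#'   `tables$free_lin`) used as journey starts.
#' @param journey_length Steps per journey.
#' @return List: `program`, `fitness` (mean coverage), `per_start` coverage
#'   counts, `max_possible` (reachable wall-cell count).
#' @export
rate_fitness <- function(program, tables, starts, journey_length = 150L) {
  if (inherits(tables, "grid_world")) tables <- world_tables(tables)
  succ <- successor_map(tables, compile_move_table(program))
  cov <- as.numeric(coverage_all_starts(tables, succ, journey_length)[starts])
  list(program = program, fitness = mean(cov), per_start = cov,
       max_possible = tables$n_reachable_wall)
}

#' Evolve a wall-following program
#'
#' The generational loop: rate every program, then build the next
#' generation by wheel-of-fortune parental choice, subtree crossover,
#' subtree mutation, and (by default) elitism.  The run stops at the first
#' program whose journeys achieve full coverage from all evaluation starts
#' *and* which verifies as a perfect wall-follower from every free start
#' ([is_perfect()]), or at the generation cap.  Fully reproducible from
#' `config$seed`: the evaluation starts are drawn once and frozen for the
#' whole run.
#'
#' @param config A [gp_config()].
#' @param world A `grid_world`.
#' @return List: `champion` (`bool_expr`), `perfect` (logical), `fitness`
#'   of the champion, `generation` at which the run stopped, `history`
#'   (data frame of per-generation best/mean fitness), `starts`, `config`.
#' @export
evolve_gp <- function(config, world) {
  set.seed(config$seed)
  tables <- world_tables(world)
  starts <- sample.int(tables$nfree, config$n_starts, replace = TRUE)
  max_cov <- tables$n_reachable_wall

  memo <- new.env(parent = emptyenv())
  rate <- function(program) {
    key <- rlang::hash(program)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    r <- rate_fitness(program, tables, starts, config$journey_length)
    memo[[key]] <- r
    r
  }

  # ramped initialisation: depth budgets cycle over 2..max_depth so the
  # initial population mixes shallow and deep trees
  depths <- rep_len(seq.int(2L, max(2L, config$max_depth)), config$pop_size)
  pop <- lapply(depths, function(d) random_program(config, d))
  history <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0))
  best_overall <- NULL

  for (gen in 0:config$generations) {
    rated <- lapply(pop, rate)
    fit <- vapply(rated, `[[`, numeric(1), "fitness")
    ib <- which.max(fit)
    if (is.null(best_overall) || fit[ib] > best_overall$fitness)
      best_overall <- rated[[ib]]
    history <- rbind(history, data.frame(generation = gen, best = max(fit),
                                         mean = mean(fit)))

    # full coverage from every evaluation start => candidate for perfection
    if (fit[ib] == max_cov && all(rated[[ib]]$per_start == max_cov) &&
        is_perfect(tables, pop[[ib]])) {
      return(list(champion = pop[[ib]], perfect = TRUE, fitness = fit[ib],
                  generation = gen, history = history, starts = starts,
                  config = config))
    }
    if (gen == config$generations) break

    nxt <- vector("list", config$pop_size)
    slot <- 1L
    if (config$elitism) {
      nxt[[1L]] <- pop[[ib]]
      slot <- 2L
    }
    while (slot <= config$pop_size) {
      a <- pop[[roulette_select(fit)]]
      b <- pop[[roulette_select(fit)]]
      kids <- if (stats::runif(1) < config$p_crossover)
        crossover_programs(a, b) else list(a, b)
      for (k in 1:2) {
        if (slot > config$pop_size) break
        kid <- mutate_program(kids[[k]], config)
        if (expr_size(kid) > config$size_cap) kid <- if (k == 1L) a else b
        nxt[[slot]] <- kid
        slot <- slot + 1L
      }
    }
    pop <- nxt
  }

  champ <- best_overall$program
  list(champion = champ,
       perfect = best_overall$fitness == max_cov && is_perfect(tables, champ),
       fitness = best_overall$fitness, generation = config$generations,
       history = history, starts = starts, config = config)
}
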