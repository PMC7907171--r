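## Grid world: the robot's physical environment.
##
## Coordinates are (row, column), 1-based; north decreases the row, east
## increases the column.  The robot occupies free cells only.  Moving into a
## wall cell or off the grid is a no-op (the step counter still advances).
## Cells outside the grid are sensed as free but cannot be entered.

DIR8 <- c("n", "ne", "e", "se", "s", "sw", "w", "nw")
DIR8_OFF <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L,
                     0L, -1L, -1L, -1L),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(DIR8, c("dr", "dc")))
DIR4 <- c("north", "east", "south", "west")
DIR4_OFF <- matrix(c(-1L, 0L, 0L, 1L, 1L, 0L, 0L, -1L),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(DIR4, c("dr", "dc")))

#' Construct a grid world
#'
#' A grid world is a rectangular occupancy grid of wall and free cells.  Its
#' topology is `"closed"` when every boundary cell is wall (the robot is
#' confined) and `"open"` otherwise (the robot can roam the free margin —
#' the regime in which a controller meets states never seen during
#' evolution).  Open maps are usually padded with a free apron (`pad`) so
#' there is genuine space "outside the labyrinth".
#'
#' @param lines Character vector, one string per row, `'#'` = wall,
#'   `'.'` = free; all rows must have equal length.  Alternatively a logical
#'   matrix (`TRUE` = wall).
#' @param pad Number of rings of free cells to add around the map.
#' @return A `grid_world` object: list with `wall` (logical matrix),
#'   `nrow`, `ncol`, `topology`.
#' @export
grid_world <- function(lines, pad = 0L) {
  if (is.matrix(lines)) {
    wall <- lines
    storage.mode(wall) <- "logical"
  } else {
    if (length(unique(nchar(lines))) != 1L)
      stop("map rows have unequal lengths")
    chars <- do.call(rbind, strsplit(lines, ""))
    if (!all(chars %in% c("#", ".")))
      stop("map may contain only '#' (wall) and '.' (free)")
    wall <- chars == "#"
  }
  if (pad > 0L) {
    w2 <- matrix(FALSE, nrow(wall) + 2L * pad, ncol(wall) + 2L * pad)
    w2[pad + seq_len(nrow(wall)), pad + seq_len(ncol(wall))] <- wall
    wall <- w2
  }
  if (!any(wall) || all(wall))
    stop("a grid world needs at least one wall cell and one free cell")
  boundary_wall <- all(wall[1, ]) && all(wall[nrow(wall), ]) &&
    all(wall[, 1]) && all(wall[, ncol(wall)])
  structure(list(wall = wall, nrow = nrow(wall), ncol = ncol(wall),
                 topology = if (boundary_wall) "closed" else "open"),
            class = "grid_world")
}

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf("<grid_world %dx%d, %s, %d wall cells>\n",
              x$nrow, x$ncol, x$topology, sum(x$wall)))
  cat(paste(apply(ifelse(x$wall, "#", "."), 1, paste, collapse = ""),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write an ASCII map file
#'
#' `'#'` marks wall cells and `'.'` free cells, one row per line.  The reader
#' validates rectangularity; write then read round-trips.
#'
#' @param path File path.
#' @param world A `grid_world`.
#' @param pad Passed to [grid_world()].
#' @return `read_map()`: a `grid_world`; `write_map()`: `path`, invisibly.
#' @export
read_map <- function(path, pad = 0L) {
  lines <- readLines(path, warn = FALSE)
  grid_world(lines[nzchar(lines) & !startsWith(lines, "#!")], pad = pad)
}

#' @rdname read_map
#' @export
write_map <- function(world, path) {
  writeLines(apply(ifelse(world$wall, "#", "."), 1, paste, collapse = ""),
             path)
  invisible(path)
}

is_free <- function(world, pos) {
  pos[1] >= 1L && pos[1] <= world$nrow && pos[2] >= 1L &&
    pos[2] <= world$ncol && !world$wall[pos[1], pos[2]]
}

#' Read the eight wall sensors
#'
#' The robot senses, for each of the eight space-fixed compass directions,
#' whether the adjacent cell is occupied by wall.  Cells outside the grid
#' read as free.
#'
#' @param world A `grid_world`.
#' @param pos Integer `c(row, col)`, a free cell.
#' @return Named logical vector over `n, ne, e, se, s, sw, w, nw`.
#' @export
sense <- function(world, pos) {
  if (!is_free(world, pos)) stop("robot position is not a free cell")
  r <- pos[1] + DIR8_OFF[, "dr"]
  c <- pos[2] + DIR8_OFF[, "dc"]
  inside <- r >= 1L & r <= world$nrow & c >= 1L & c <= world$ncol
  out <- rep(FALSE, 8L)
  out[inside] <- world$wall[cbind(r[inside], c[inside])]
  names(out) <- DIR8
  out
}

# Wall cells 8-adjacent to a position, as linear indices into world$wall.
adjacent_walls <- function(world, pos) {
  r <- as.integer(pos[1]) + DIR8_OFF[, "dr"]
  c <- as.integer(pos[2]) + DIR8_OFF[, "dc"]
  inside <- r >= 1L & r <= world$nrow & c >= 1L & c <= world$ncol
  idx <- (c[inside] - 1L) * world$nrow + r[inside]
  unname(idx[world$wall[idx]])
}

#' Robot state
#'
#' @param world A `grid_world`.
#' @param pos Integer `c(row, col)`, a free cell.
#' @return A `robot_state`: list with `pos`, `credited` (linear indices of
#'   wall cells the robot has stood next to so far), `steps`.  The initial
#'   state already credits the walls adjacent to the start.
#' @export
robot_state <- function(world, pos) {
  if (!is_free(world, pos)) stop("start position is not a free cell")
  structure(list(pos = as.integer(pos),
                 credited = adjacent_walls(world, pos),
                 steps = 0L),
            class = "robot_state")
}

#' Advance the robot by one move
#'
#' Moves one cell in the given compass direction if that cell is free;
#' blocked or off-grid moves (and `move = "stay"`) leave the position
#' unchanged.  The step counter always advances, and wall cells 8-adjacent
#' to the (possibly unchanged) position are credited.
#'
#' @param world A `grid_world`.
#' @param state A `robot_state`.
#' @param move One of `"north"`, `"east"`, `"south"`, `"west"`, `"stay"`.
#' @return The updated `robot_state`.
#' @export
step_robot <- function(world, state, move) {
  pos <- state$pos
  if (move != "stay") {
    if (!(move %in% DIR4)) stop("unknown move: ", move)
    cand <- pos + DIR4_OFF[move, ]
    if (is_free(world, cand)) pos <- as.integer(cand)
  }
  structure(list(pos = pos,
                 credited = union(state$credited, adjacent_walls(world, pos)),
                 steps = state$steps + 1L),
            class = "robot_state")
}

#' Run a journey under a controller
#'
#' A controller is a function taking a sensor reading (the named logical
#' vector of [sense()]) and returning the next move: `"north"`, `"east"`,
#' `"south"`, `"west"`, or `"stay"`.  The journey applies the controller for
#' a fixed number of steps; it is deterministic given world, controller and
#' start.
#'
#' @param world A `grid_world`.
#' @param controller Function `reading -> move`; see also
#'   [program_controller()].
#' @param start Integer `c(row, col)`, a free cell.
#' @param journey_length Number of steps (>= 0).
#' @return List of `journey_length + 1` `robot_state`s, the trajectory.
#' @export
run_journey <- function(world, controller, start, journey_length) {
  stopifnot(journey_length >= 0)
  st <- robot_state(world, start)
  traj <- vector("list", journey_length + 1L)
  traj[[1]] <- st
  if (journey_length > 0) for (k in seq_len(journey_length)) {
    st <- step_robot(world, st, controller(sense(world, st$pos)))
    traj[[k + 1L]] <- st
  }
  traj
}

#' Wall coverage achieved by a trajectory
#'
#' The robot "visits" a part of the wall by standing next to it: the fitness
#' of a journey is the number of distinct wall cells 8-adjacent to any
#' position on the trajectory.  Bounded above by the world's wall-cell
#' count, and non-decreasing in the journey prefix.
#'
#' @param world A `grid_world`.
#' @param trajectory List of `robot_state`s from [run_journey()].
#' @return Integer count of distinct wall cells covered.
#' @export
wall_coverage_fitness <- function(world, trajectory) {
  covered <- unique(unlist(lapply(trajectory, function(s)
    adjacent_walls(world, s$pos))))
  length(covered)
}

#' Export a trajectory as a table
#'
#' @param world A `grid_world`.
#' @param trajectory List of `robot_state`s.
#' @return Data frame with columns `step`, `row`, `col`, `new_walls`
#'   (wall cells first credited at that step).
#' @export
trajectory_table <- function(world, trajectory) {
  prev <- integer(0)
  rows <- lapply(seq_along(trajectory), function(k) {
    s <- trajectory[[k]]
    fresh <- setdiff(s$credited, prev)
    prev <<- s$credited
    data.frame(step = k - 1L, row = s$pos[1], col = s$pos[2],
               new_walls = length(fresh))
  })
  do.call(rbind, rows)
}

## ---- controller semantics for boolean programs ------------------------------

#' Candidate-move interrogation controller
#'
#' Turns a boolean program over the 12 variables into a movement controller.
#' For each direction `d` in the fixed priority order north, east, south,
#' west, the program is evaluated on the assignment formed by the 8 sensor
#' bits together with a one-hot indicator on the direction variable `d`; the
#' first direction for which the program answers true is taken, and if none
#' does the robot stays.  This is how a single boolean-valued program (the
#' object the exhaustive equivalence test enumerates over all 2^12 states)
#' selects among the four moves.
#'
#' @param expr A `bool_expr`.
#' @return A controller function usable with [run_journey()].
#' @export
program_controller <- function(expr) {
  force(expr)
  function(reading) {
    a <- c(as.list(reading),
           list(north = FALSE, east = FALSE, south = FALSE, west = FALSE))
    for (d in DIR4) {
      a[[d]] <- TRUE
      if (eval_program(expr, unlist(a))) return(d)
      a[[d]] <- FALSE
    }
    "stay"
  }
}

## ---- fast simulation tables -------------------------------------------------

#' Precompute simulation tables for a world
#'
#' The world is static, so each free cell's sensor reading, its four move
#' targets, and its adjacent wall cells can be tabulated once.  A memoryless
#' controller then induces a deterministic successor map on free cells, and
#' journeys become table lookups.  Used by the GP engine's fitness
#' evaluation; consistency with the step-by-step simulator is part of the
#' test suite.
#'
#' @param world A `grid_world`.
#' @return A `world_tables` object (free-cell index, per-cell sensor state
#'   index in `0:255`, neighbour table, adjacent-wall lists).
#' @export
world_tables <- function(world) {
  free_lin <- which(!world$wall)              # linear indices of free cells
  nfree <- length(free_lin)
  ord <- integer(world$nrow * world$ncol)     # linear index -> free ordinal
  ord[free_lin] <- seq_len(nfree)
  rr <- ((free_lin - 1L) %% world$nrow) + 1L
  cc <- ((free_lin - 1L) %/% world$nrow) + 1L

  # sensor state index: bits (n, ne, e, se, s, sw, w, nw), n most significant
  sens <- integer(nfree)
  for (k in seq_len(8L)) {
    r <- rr + DIR8_OFF[k, "dr"]
    c <- cc + DIR8_OFF[k, "dc"]
    inside <- r >= 1L & r <= world$nrow & c <= world$ncol & c >= 1L
    bit <- logical(nfree)
    bit[inside] <- world$wall[cbind(r[inside], c[inside])]
    sens <- sens + as.integer(bit) * 2L^(8L - k)
  }

  # neighbour ordinal per move (self if blocked or off-grid)
  nbr <- matrix(seq_len(nfree), nfree, 4L, dimnames = list(NULL, DIR4))
  for (k in seq_len(4L)) {
    r <- rr + DIR4_OFF[k, "dr"]
    c <- cc + DIR4_OFF[k, "dc"]
    ok <- r >= 1L & r <= world$nrow & c >= 1L & c <= world$ncol
    ok[ok] <- !world$wall[cbind(r[ok], c[ok])]
    nbr[ok, k] <- ord[(c[ok] - 1L) * world$nrow + r[ok]]
  }

  wall_lin <- which(world$wall)
  wall_ord <- integer(world$nrow * world$ncol)
  wall_ord[wall_lin] <- seq_along(wall_lin)
  adj <- lapply(seq_len(nfree), function(i)
    wall_ord[adjacent_walls(world, c(rr[i], cc[i]))])
  reachable <- sort(unique(unlist(adj)))

  # per-cell adjacent-wall sets packed 31 bits per integer word (the sign
  # bit stays clear), for the pointer-doubling coverage path
  nwords <- max(1L, (length(wall_lin) + 30L) %/% 31L)
  ww <- matrix(0L, nfree, nwords)
  for (i in seq_len(nfree)) for (j in adj[[i]])
    ww[i, (j - 1L) %/% 31L + 1L] <-
      bitwOr(ww[i, (j - 1L) %/% 31L + 1L],
             bitwShiftL(1L, (j - 1L) %% 31L))

  structure(list(world = world, nfree = nfree, free_lin = free_lin,
                 row = rr, col = cc, sens = sens, nbr = nbr,
                 wall_adj = adj, wall_words = ww,
                 n_wall = length(wall_lin),
                 n_reachable_wall = length(reachable)),
            class = "world_tables")
}

# 16-bit popcount lookup, built lazily once per session.
popcount_env <- new.env(parent = emptyenv())
popcount <- function(x) {
  pc <- popcount_env$pc16
  if (is.null(pc)) {
    pc <- integer(65536L)
    for (i in 1:65535) pc[i + 1L] <- pc[bitwShiftR(i, 1L) + 1L] + (i %% 2L)
    popcount_env$pc16 <- pc
  }
  pc[bitwAnd(x, 65535L) + 1L] + pc[bitwAnd(bitwShiftR(x, 16L), 65535L) + 1L]
}

# Distinct-wall-cell coverage, for every free start simultaneously, of the
# deterministic journey of `budget` steps induced by a successor map:
# binary decomposition of the node count with pointer doubling, unioning
# packed wall sets.  Exact for any budget.
coverage_all_starts <- function(tables, succ, budget) {
  nfree <- tables$nfree
  nwords <- ncol(tables$wall_words)
  ck <- tables$wall_words        # coverage of a 1-node path from each cell
  sk <- succ
  pos <- seq_len(nfree)
  acc <- matrix(0L, nfree, nwords)
  n_nodes <- budget + 1L
  repeat {
    if (n_nodes %% 2L == 1L) {
      acc <- matrix(bitwOr(acc, ck[pos, , drop = FALSE]), nfree)
      pos <- sk[pos]
    }
    n_nodes <- n_nodes %/% 2L
    if (n_nodes == 0L) break
    ck <- matrix(bitwOr(ck, ck[sk, , drop = FALSE]), nfree)
    sk <- sk[sk]
  }
  counts <- popcount(acc[, 1L])
  if (nwords > 1L) for (w in 2:nwords) counts <- counts + popcount(acc[, w])
  counts
}

#' Compile a program to a move table
#'
#' Evaluates the program on all 256 sensor states x 4 one-hot direction
#' indicators in a single vectorized pass and reduces the result under the
#' north/east/south/west priority of [program_controller()].  The 1,024
#' evaluation rows are bit-packed into 32-bit words, so each AST node costs
#' one vectorized bitwise operation on 32 integers; this is the hot path of
#' GP fitness evaluation.
#'
#' @param expr A `bool_expr`.
#' @return Integer vector of length 256: entry `s + 1` is the move chosen in
#'   sensor state `s` (0 = stay, 1..4 = north, east, south, west).
#' @export
compile_move_table <- function(expr) {
  wcols <- move_table_words()
  ev <- function(e) {
    switch(e$kind,
      var = wcols[[e$name]],
      const = if (e$value) rep(-1L, 32L) else integer(32L),
      "not" = bitwNot(ev(e$args[[1]])),
      "and" = bitwAnd(ev(e$args[[1]]), ev(e$args[[2]])),
      "or"  = bitwOr(ev(e$args[[1]]), ev(e$args[[2]])),
      "if"  = {
        c0 <- ev(e$args[[1]])
        bitwOr(bitwAnd(c0, ev(e$args[[2]])),
               bitwAnd(bitwNot(c0), ev(e$args[[3]])))
      })
  }
  out <- as.logical(intToBits(ev(expr)))          # 1024 row results
  ans <- matrix(out, 256L, 4L)       # column d = program's answer for move d
  mv <- integer(256L)
  for (d in 4:1) mv[ans[, d]] <- d   # first true in priority order wins
  mv
}

# Packed evaluation columns for compile_move_table(): 1024 rows (4 one-hot
# direction blocks of the 256 sensor states) packed 32 rows per 32-bit word,
# row r in bit r %% 32 of word r %/% 32.  Constant, built once per session.
move_table_env <- new.env(parent = emptyenv())
move_table_words <- function() {
  if (!is.null(move_table_env$wcols)) return(move_table_env$wcols)
  s <- 0:255
  cols <- lapply(seq_len(8L), function(k)
    rep(bitwAnd(bitwShiftR(s, 8L - k), 1L) == 1L, 4L))
  names(cols) <- DIR8
  for (d in seq_len(4L))
    cols[[DIR4[d]]] <- rep(seq_len(4L) == d, each = 256L)
  pack <- function(bits) {
    vapply(seq_len(32L), function(w)
      packBits(bits[(w - 1L) * 32L + seq_len(32L)], type = "integer"),
      integer(1))
  }
  move_table_env$wcols <- lapply(cols, pack)
  move_table_env$wcols
}

# Successor map induced on free cells by a move table.
successor_map <- function(tables, move_table) {
  mv <- move_table[tables$sens + 1L]
  succ <- seq_len(tables$nfree)
  moved <- mv > 0L
  succ[moved] <- tables$nbr[cbind(which(moved), mv[moved])]
  succ
}

#' Is a controller a perfect wall-follower?
#'
#' A program is perfect when, from every free starting cell, its journey
#' covers every wall cell that touches the free region within the step
#' budget — the robot finds the wall from an arbitrary start and then
#' follows it all the way round.
#'
#' @param world A `grid_world` or a precomputed [world_tables()].
#' @param expr A `bool_expr` controller program.
#' @param budget Step budget per start; the default `4 *` wall-cell count is
#'   comfortably more than one full perimeter traversal.
#' @return Logical scalar.
#' @export
is_perfect <- function(world, expr, budget = NULL) {
  tables <- if (inherits(world, "world_tables")) world else world_tables(world)
  if (is.null(budget)) budget <- 4L * tables$n_wall
  succ <- successor_map(tables, compile_move_table(expr))
  cov <- coverage_all_starts(tables, succ, budget)
  all(cov == tables$n_reachable_wall)
}
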