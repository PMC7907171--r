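empty_room <- function(n = 9) {
  grid_world(c(strrep("#", n),
               rep(paste0("#", strrep(".", n - 2), "#"), n - 2),
               strrep("#", n)))
}

test_that("sense reports the 8-neighbourhood wall occupancy", {
  w <- empty_room()
  expect_identical(unname(sense(w, c(5, 5))), rep(FALSE, 8))
  # one cell south of a long east-west wall: n, ne, nw true
  w2 <- grid_world(c("........",
                     "########",
                     "........",
                     "...#...."))
  r <- sense(w2, c(3, 4))
  expect_identical(r, c(n = TRUE, ne = TRUE, e = FALSE, se = FALSE,
                        s = TRUE, sw = FALSE, w = FALSE, nw = TRUE))
  expect_error(sense(w2, c(2, 1)), "not a free cell")
})

test_that("sense equals direct grid indexing on random worlds", {
  set.seed(11)
  offs <- list(n = c(-1, 0), ne = c(-1, 1), e = c(0, 1), se = c(1, 1),
               s = c(1, 0), sw = c(1, -1), w = c(0, -1), nw = c(-1, -1))
  for (rep in 1:5) {
    w <- random_world(8, 0.3)
    free <- which(!w$wall, arr.ind = TRUE)
    for (k in sample(nrow(free), min(6, nrow(free)))) {
      pos <- free[k, ]
      r <- sense(w, pos)
      for (d in names(offs)) {
        q <- pos + offs[[d]]
        inside <- all(q >= 1) && q[1] <= w$nrow && q[2] <= w$ncol
        expect_identical(unname(r[d]),
                         if (inside) w$wall[q[1], q[2]] else FALSE)
      }
    }
  }
})

test_that("sense is translation-consistent", {
  core <- c("....", ".##.", ".#..", "....")
  w1 <- grid_world(c(core, "....", "...."))
  w2 <- grid_world(c("....", "....", core))    # same pattern shifted south
  expect_identical(sense(w1, c(3, 4)), sense(w2, c(5, 4)))
})

test_that("step moves into free cells and no-ops on blocked moves", {
  w <- empty_room()
  st <- robot_state(w, c(5, 5))
  st2 <- step_robot(w, st, "east")
  expect_identical(st2$pos, c(5L, 6L))
  expect_identical(st2$steps, 1L)
  # blocked: cell north of position (2,5) is wall
  stb <- robot_state(w, c(2, 5))
  stb2 <- step_robot(w, stb, "north")
  expect_identical(stb2$pos, stb$pos)
  expect_identical(stb2$steps, 1L)
  expect_error(step_robot(w, st, "up"), "unknown move")
})

test_that("credited wall cells equal an independent per-step neighbourhood scan", {
  w <- reference_labyrinths()$closed
  moves <- c("north", "north", "west", "west", "north", "east", "east",
             "east", "south", "east")
  st <- robot_state(w, c(6, 4))
  seen <- list(st$pos)
  for (m in moves) {
    st <- step_robot(w, st, m)
    seen[[length(seen) + 1L]] <- st$pos
  }
  # brute-force union of 8-neighbourhood wall cells along the trajectory
  expected <- sort(unique(unlist(lapply(seen, function(p) {
    hood <- expand.grid(dr = -1:1, dc = -1:1)
    hood <- hood[!(hood$dr == 0 & hood$dc == 0), ]
    idx <- mapply(function(dr, dc) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= w$nrow && c >= 1 && c <= w$ncol &&
          w$wall[r, c]) (c - 1) * w$nrow + r else NA_integer_
    }, hood$dr, hood$dc)
    idx[!is.na(idx)]
  }))))
  expect_identical(sort(st$credited), as.integer(expected))
})

test_that("run_journey honours the controller, start and budget", {
  w <- empty_room()
  stay <- function(reading) "stay"
  traj <- run_journey(w, stay, c(4, 4), 5)
  expect_length(traj, 6L)
  expect_true(all(vapply(traj, function(s) all(s$pos == c(4, 4)), logical(1))))
  expect_length(run_journey(w, stay, c(4, 4), 0), 1L)
})

test_that("the reference wall-follower hugs the wall once it finds it", {
  w <- reference_labyrinths()$closed
  ctrl <- program_controller(reference_wall_follower())
  traj <- run_journey(w, ctrl, c(7, 8), 60)
  touching <- vapply(traj, function(s) any(sense(w, s$pos)), logical(1))
  first <- which(touching)[1]
  expect_false(is.na(first))
  expect_true(all(touching[first:length(touching)]))
})

test_that("wall coverage is bounded, monotone in the prefix, and complete for the reference follower", {
  w <- reference_labyrinths()$closed
  n_wall <- sum(w$wall)
  ctrl <- program_controller(reference_wall_follower())
  traj <- run_journey(w, ctrl, c(6, 6), 4 * n_wall)
  cov <- vapply(seq_along(traj), function(k)
    wall_coverage_fitness(w, traj[seq_len(k)]), integer(1))
  expect_true(all(diff(cov) >= 0))
  expect_lte(max(cov), n_wall)
  expect_identical(cov[length(cov)], n_wall)   # full perimeter + spur
  # stationary robot far from any wall covers nothing
  stay_traj <- run_journey(w, function(r) "stay", c(7, 8), 10)
  expect_identical(wall_coverage_fitness(w, stay_traj), 0L)
})

test_that("robot never occupies a wall cell under any controller", {
  set.seed(23)
  cfg <- gp_config()
  for (rep in 1:5) {
    w <- random_world(8, 0.3)
    ctrl <- program_controller(random_program(cfg, 4))
    free <- which(!w$wall, arr.ind = TRUE)
    start <- free[sample(nrow(free), 1), ]
    traj <- run_journey(w, ctrl, start, 30)
    expect_true(all(vapply(traj, function(s)
      !w$wall[s$pos[1], s$pos[2]], logical(1))))
  }
})

test_that("fast table-driven simulation matches the step-by-step simulator", {
  set.seed(31)
  cfg <- gp_config()
  for (rep in 1:6) {
    w <- if (rep <= 3) reference_labyrinths()$closed else random_world(9, 0.25)
    wt <- world_tables(w)
    p <- if (rep == 1) reference_wall_follower()
         else random_program(cfg, sample(3:5, 1))
    starts <- sample(wt$nfree, 3)
    fast <- rate_fitness(p, wt, starts, journey_length = 40)
    ctrl <- program_controller(p)
    slow <- vapply(starts, function(s) {
      traj <- run_journey(w, ctrl, c(wt$row[s], wt$col[s]), 40)
      wall_coverage_fitness(w, traj)
    }, integer(1))
    expect_identical(as.integer(fast$per_start), slow)
  }
})

test_that("is_perfect separates the reference follower from degenerate controllers", {
  w <- reference_labyrinths()$closed
  expect_true(is_perfect(w, reference_wall_follower()))
  # always-move-north: If[north, True, False] answers yes only to north
  expect_false(is_perfect(w, parse_program("If[north, True, False]")))
  # constant-stay controller
  expect_false(is_perfect(w, parse_program("False")))
})

test_that("maps round-trip through ASCII files and classify topology", {
  labs <- reference_labyrinths()
  expect_identical(labs$closed$topology, "closed")
  expect_identical(labs$open$topology, "open")
  expect_true(all(labs$closed$wall[1, ], labs$closed$wall[labs$closed$nrow, ],
                  labs$closed$wall[, 1], labs$closed$wall[, labs$closed$ncol]))
  expect_true(any(!labs$open$wall[1, ]))
  f <- withr::local_tempfile(fileext = ".map")
  write_map(labs$closed, f)
  expect_identical(read_map(f)$wall, labs$closed$wall)
  expect_error(grid_world(c("##", "#")), "unequal")
  expect_error(grid_world(c("..", "..")), "wall")
  # padding adds a free apron
  padded <- grid_world(c("##", "##", ".."), pad = 2)
  expect_identical(padded$nrow, 7L)
  expect_identical(padded$topology, "open")
})

test_that("trajectory export records steps, positions and fresh wall credit", {
  w <- reference_labyrinths()$closed
  ctrl <- program_controller(reference_wall_follower())
  traj <- run_journey(w, ctrl, c(6, 6), 10)
  tab <- trajectory_table(w, traj)
  expect_identical(nrow(tab), 11L)
  expect_identical(tab$step, 0:10)
  expect_identical(sum(tab$new_walls),
                   length(traj[[length(traj)]]$credited))
})
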