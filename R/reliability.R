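## Non-equivalence analysis: pairwise truth-table disagreement among
## champion programs, and the orchestration of the full study (GP
## champions on the closed labyrinth, the printed solutions, and the
## lambda-sweep of the neuroevolution experiment).

#' Pairwise disagreement matrix
#'
#' Computes the truth vector of every program and counts, for each pair,
#' the assignments (out of 4,096) on which their outputs differ.  Programs
#' that steer the robot identically inside the labyrinth can still disagree
#' on a large share of the full state space — the reliability gap this
#' analysis quantifies.
#'
#' @param programs List of `bool_expr`s (length >= 2).
#' @param ids Character identifiers (default `names(programs)` or
#'   `prog1..progN`).
#' @param perfect Optional logical vector of in-labyrinth perfection flags.
#' @return A `reliability_report`: list with `ids`, `matrix` (symmetric
#'   integer matrix, zero diagonal), `perfect`.
#' @export
disagreement_matrix <- function(programs, ids = NULL, perfect = NULL) {
  if (length(programs) < 2L) stop("need at least two programs")
  if (is.null(ids))
    ids <- if (!is.null(names(programs)) && all(nzchar(names(programs))))
      names(programs) else paste0("prog", seq_along(programs))
  tv <- lapply(programs, truth_vector)
  n <- length(tv)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- disagreement_count(tv[[i]], tv[[j]])
  structure(list(ids = ids, matrix = m, perfect = perfect),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>", nrow(x$matrix),
      "programs, pairwise disagreements out of 4096 states:\n")
  print(x$matrix)
  if (!is.null(x$perfect))
    cat("perfect in-labyrinth:",
        paste0(x$ids, "=", x$perfect, collapse = ", "), "\n")
  invisible(x)
}

#' Behavioural disagreement between two controllers
#'
#' Supplementary, trajectory-level comparison: the fraction of free cells
#' of a world from which the two programs choose different moves (under the
#' candidate-move interrogation semantics).  Complements the raw
#' truth-table comparison, which enumerates many sensor states a given
#' world never presents.
#'
#' @param world A `grid_world` or [world_tables()].
#' @param e1,e2 `bool_expr` controller programs.
#' @return Fraction in `[0, 1]` of free cells with differing move choice.
#' @export
behavioural_disagreement <- function(world, e1, e2) {
  tables <- if (inherits(world, "world_tables")) world else world_tables(world)
  m1 <- compile_move_table(e1)[tables$sens + 1L]
  m2 <- compile_move_table(e2)[tables$sens + 1L]
  mean(m1 != m2)
}

#' Run the full study pipeline
#'
#' Orchestrates the whole analysis: (1) evolves `n_champions` GP
#' wall-followers on the closed reference labyrinth under distinct seeds
#' and verifies each with [is_perfect()]; (2) computes the pairwise
#' disagreement matrix over the evolved champions together with the three
#' printed solutions; (3) runs the neuroevolution lambda sweep for both
#' gates and collects champion size summaries.  All artefacts (program
#' texts, disagreement matrix TSV, histories, JSON manifest) are written
#' under `out_dir` when given; the same seeds reproduce the same outputs.
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param n_champions Number of GP champions to evolve (0 = compare the
#'   printed solutions only).
#' @param gp_seeds Seeds for the GP runs (default `1:n_champions`).
#' @param gp Base [gp_config()] for the GP runs (the seed field is
#'   overridden per run).
#' @param lambdas Lambda grid for the neuroevolution sweep.
#' @param evo_seeds Seeds for the neuroevolution runs at each lambda.
#' @param evo Base [evo_config()].
#' @return List: `report` (a `reliability_report`), `gp_runs`,
#'   `nn_summary` (data frame over gate x lambda x seed), `manifest`.
#' @export
run_full_pipeline <- function(out_dir = NULL, n_champions = 3L,
                              gp_seeds = seq_len(n_champions),
                              gp = gp_config(),
                              lambdas = c(0, 0.1), evo_seeds = 1:3,
                              evo = evo_config()) {
  world <- reference_labyrinths()$closed
  printed <- printed_solutions()

  gp_runs <- list()
  champs <- list()
  for (s in gp_seeds) {
    cfg <- gp
    cfg$seed <- as.integer(s)
    run <- evolve_gp(cfg, world)
    if (!run$perfect)
      warning("GP run with seed ", s, " ended without a perfect program")
    gp_runs[[paste0("champion_seed", s)]] <- run
    champs[[paste0("champion_seed", s)]] <- run$champion
  }

  programs <- c(printed, champs)
  perfect <- c(vapply(printed, function(p) is_perfect(world, p), logical(1)),
               vapply(gp_runs, `[[`, logical(1), "perfect"))
  report <- disagreement_matrix(programs, names(programs), perfect)

  tasks <- gate_truth_tables()
  nn_rows <- list()
  for (gate in names(tasks)) for (lam in lambdas) for (s in evo_seeds) {
    cfg <- evo
    cfg$lambda <- lam
    cfg$seed <- as.integer(s)
    res <- evolve_networks(cfg, tasks[[gate]])
    nn_rows[[length(nn_rows) + 1L]] <-
      data.frame(gate = gate, lambda = lam, seed = s, exact = res$exact,
                 sigma = res$sigma, Q = res$Q,
                 active_hidden = active_hidden_units(res$champion))
  }
  nn_summary <- do.call(rbind, nn_rows)

  manifest <- list(gp_seeds = as.integer(gp_seeds),
                   gp_config = unclass(gp)[setdiff(names(gp), "seed")],
                   lambdas = lambdas, evo_seeds = as.integer(evo_seeds),
                   programs = vapply(programs, deparse_program, character(1)),
                   perfect = as.list(perfect))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$matrix,
                       file.path(out_dir, "disagreement_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(nn_summary, file.path(out_dir, "nn_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (id in names(champs))
      write_program(champs[[id]], file.path(out_dir, paste0(id, ".txt")))
    for (id in names(gp_runs))
      utils::write.table(gp_runs[[id]]$history,
                         file.path(out_dir, paste0(id, "_history.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(report = report, gp_runs = gp_runs, nn_summary = nn_summary,
       manifest = manifest)
}
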