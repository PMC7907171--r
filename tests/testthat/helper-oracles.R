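# Independent oracles for the engine-level checks.  These deliberately
# re-implement semantics in a different style from the package (explicit
# stack-free recursion over a different representation) so that agreement
# is evidence, not tautology.

# Second, independently coded brute-force interpreter: works directly on
# the node list, with If desugared to (c AND t) OR (NOT c AND f).
oracle_eval <- function(node, env) {
  if (node$kind == "var") return(isTRUE(env[[node$name]]))
  if (node$kind == "const") return(isTRUE(node$value))
  if (node$kind == "not") return(!oracle_eval(node$args[[1]], env))
  a <- oracle_eval(node$args[[1]], env)
  if (node$kind == "and") return(a && oracle_eval(node$args[[2]], env))
  if (node$kind == "or") return(a || oracle_eval(node$args[[2]], env))
  # if: desugared form
  (a && oracle_eval(node$args[[2]], env)) ||
    (!a && oracle_eval(node$args[[3]], env))
}

# Truth vector by per-assignment oracle evaluation, enumerating i = 0..4095
# with n as most significant bit (independent of assignment_table()).
oracle_truth_vector <- function(expr) {
  vocab <- c("n", "ne", "e", "se", "s", "sw", "w", "nw",
             "north", "east", "south", "west")
  vapply(0:4095, function(i) {
    env <- as.list(structure(
      as.logical(bitwAnd(bitwShiftR(i, 11:0), 1L)), names = vocab))
    oracle_eval(expr, env)
  }, logical(1))
}

# Random expression generator for property tests (independent of
# random_program(): no bias machinery, plain uniform choices).
random_expr <- function(depth) {
  vocab <- c("n", "ne", "e", "se", "s", "sw", "w", "nw",
             "north", "east", "south", "west")
  if (depth <= 0 || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.2) return(bx_const(stats::runif(1) < 0.5))
    return(bx_var(sample(vocab, 1)))
  }
  switch(sample(4, 1),
         bx_not(random_expr(depth - 1)),
         bx_and(random_expr(depth - 1), random_expr(depth - 1)),
         bx_or(random_expr(depth - 1), random_expr(depth - 1)),
         bx_if(random_expr(depth - 1), random_expr(depth - 1),
               random_expr(depth - 1)))
}

# One full De Morgan / double-negation rewrite pass over a tree.
demorgan_rewrite <- function(e) {
  e$args <- lapply(e$args, demorgan_rewrite)
  if (e$kind == "not") {
    inner <- e$args[[1]]
    if (inner$kind == "and")
      return(bx_or(demorgan_rewrite(bx_not(inner$args[[1]])),
                   demorgan_rewrite(bx_not(inner$args[[2]]))))
    if (inner$kind == "or")
      return(bx_and(demorgan_rewrite(bx_not(inner$args[[1]])),
                    demorgan_rewrite(bx_not(inner$args[[2]]))))
    if (inner$kind == "not") return(inner$args[[1]])
  }
  e
}

# Multiset of leaf tokens of a tree (for crossover conservation checks).
leaf_tokens <- function(e) {
  if (e$kind == "var") return(e$name)
  if (e$kind == "const") return(if (e$value) "True" else "False")
  sort(unlist(lapply(e$args, leaf_tokens)))
}

expect_same_ast <- function(a, b) expect_identical(unclass(a), unclass(b))
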