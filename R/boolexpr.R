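#' Variable vocabulary of the boolean control programs
#'
#' The twelve named boolean variables a control program may mention: the eight
#' space-fixed wall sensors (`n`, `ne`, `e`, `se`, `s`, `sw`, `w`, `nw`, each
#' reporting whether the neighbouring grid cell in that compass direction is a
#' wall) and the four candidate-move indicators (`north`, `east`, `south`,
#' `west`).  The order returned here is the canonical enumeration order used
#' by [truth_vector()]: assignment `i` (for `i` in `0:4095`) is the 12-bit
#' binary expansion of `i` with `n` as the most significant bit.
#'
#' @return Character vector of the 12 variable names, in canonical order.
#' @export
bool_vocab <- function() {
  c("n", "ne", "e", "se", "s", "sw", "w", "nw",
    "north", "east", "south", "west")
}

## ---- AST constructors -------------------------------------------------------

new_bx <- function(kind, args = list(), name = NULL, value = NULL) {
  structure(list(kind = kind, args = args, name = name, value = value),
            class = "bool_expr")
}

#' Construct boolean expression nodes
#'
#' Constructors for the abstract syntax tree of a control program: variable
#' and constant leaves, negation, binary conjunction/disjunction, and the
#' ternary `If[cond, then, else]`.  Arities are enforced at construction.
#'
#' @param name Variable name; must belong to [bool_vocab()].
#' @param value Logical scalar for a constant leaf.
#' @param x,a,b,cond,yes,no Child expressions (`bool_expr`).
#' @return A `bool_expr` node.
#' @export
bx_var <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% bool_vocab()))
    stop("unknown variable name: ", name)
  new_bx("var", name = name)
}

#' @rdname bx_var
#' @export
bx_const <- function(value) {
  stopifnot(is.logical(value), length(value) == 1L, !is.na(value))
  new_bx("const", value = value)
}

#' @rdname bx_var
#' @export
bx_not <- function(x) new_bx("not", args = list(as_bx(x)))

#' @rdname bx_var
#' @export
bx_and <- function(a, b) new_bx("and", args = list(as_bx(a), as_bx(b)))

#' @rdname bx_var
#' @export
bx_or <- function(a, b) new_bx("or", args = list(as_bx(a), as_bx(b)))

#' @rdname bx_var
#' @export
bx_if <- function(cond, yes, no)
  new_bx("if", args = list(as_bx(cond), as_bx(yes), as_bx(no)))

as_bx <- function(x) {
  if (inherits(x, "bool_expr")) return(x)
  if (is.logical(x) && length(x) == 1L) return(bx_const(x))
  if (is.character(x) && length(x) == 1L) return(bx_var(x))
  stop("cannot coerce to bool_expr: ", class(x)[1])
}

bx_arity <- c(var = 0L, const = 0L, "not" = 1L, "and" = 2L, "or" = 2L, "if" = 3L)

#' Validate a boolean expression tree
#'
#' Checks the structural invariants of a `bool_expr`: each node's child count
#' matches its kind, variable leaves use the 12-name vocabulary, and constant
#' leaves hold a non-missing logical.
#'
#' @param expr A `bool_expr`.
#' @return `expr`, invisibly; errors if an invariant is violated.
#' @export
validate_bool_expr <- function(expr) {
  walk <- function(e) {
    if (!is.list(e) || is.null(e$kind) || !(e$kind %in% names(bx_arity)))
      stop("not a bool_expr node")
    if (length(e$args) != bx_arity[[e$kind]])
      stop("node of kind '", e$kind, "' has ", length(e$args),
           " children, expected ", bx_arity[[e$kind]])
    if (e$kind == "var" && !(e$name %in% bool_vocab()))
      stop("unknown variable name: ", e$name)
    if (e$kind == "const" && (!is.logical(e$value) || is.na(e$value)))
      stop("constant leaf must hold TRUE or FALSE")
    for (a in e$args) walk(a)
  }
  walk(expr)
  invisible(expr)
}

#' Size and depth of an expression tree
#'
#' @param expr A `bool_expr`.
#' @return `expr_size()`: total node count; `expr_depth()`: depth of the tree
#'   (a single leaf has depth 0).
#' @export
expr_size <- function(expr) {
  n <- 1L
  args <- expr$args
  if (length(args)) for (a in args) n <- n + expr_size(a)
  n
}

#' @rdname expr_size
#' @export
expr_depth <- function(expr) {
  if (length(expr$args) == 0L) return(0L)
  d <- 0L
  for (a in expr$args) d <- max(d, expr_depth(a))
  1L + d
}

#' Variables occurring in an expression
#'
#' @param expr A `bool_expr`.
#' @return Character vector (sorted, unique) of the variable names appearing
#'   in the tree; empty for constant expressions.
#' @export
support_variables <- function(expr) {
  acc <- character(0)
  walk <- function(e) {
    if (e$kind == "var") acc[[length(acc) + 1L]] <<- e$name
    for (a in e$args) walk(a)
  }
  walk(expr)
  sort(unique(acc))
}

## ---- parser ----------------------------------------------------------------

# Token pattern for the program dialect.  Asterisks (italic markup around
# single-letter variables in typeset sources) are treated as whitespace.
bx_tokenize <- function(text) {
  text <- gsub("*", " ", text, fixed = TRUE)
  pat <- "[A-Za-z]+|&&|\\|\\||!|\\[|\\]|\\(|\\)|,"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) return(data.frame(tok = character(0), pos = integer(0)))
  toks <- regmatches(text, list(m))[[1]]
  # anything between tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (k in seq_along(m))
    covered[seq(m[k], length.out = attr(m, "match.length")[k])] <- TRUE
  chars <- strsplit(text, "")[[1]]
  bad <- which(!covered & !grepl("^\\s$", chars))
  if (length(bad))
    stop("unexpected character '", chars[bad[1]], "' at position ", bad[1])
  data.frame(tok = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Parse a control program
#'
#' Parses program text in the dialect used throughout this package:
#' `If[cond, then, else]`, `&&` (AND), `||` (OR), `!` (NOT), the constants
#' `True`/`False`, and the twelve variable names of [bool_vocab()].  `!` binds
#' tighter than `&&`, which binds tighter than `||`; `&&` and `||` associate
#' to the left; parentheses group.  Lines starting with `#` are comments.
#'
#' @param text Program source as a single string (or a character vector of
#'   lines, which are joined).
#' @return A `bool_expr` AST.
#' @seealso [deparse_program()] for the inverse, [read_program()] to parse a
#'   file.
#' @examples
#' parse_program("ne && !w")
#' parse_program("If[n, east, If[e, south, north]]")
#' @export
parse_program <- function(text) {
  text <- paste(grep("^\\s*#", text, invert = TRUE, value = TRUE),
                collapse = "\n")
  td <- bx_tokenize(text)
  toks <- td$tok
  pos <- td$pos
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  where <- function() if (i <= length(toks)) pos[i] else nchar(text) + 1L
  advance <- function() {
    t <- peek()
    i <<- i + 1L
    t
  }
  expect <- function(t) {
    got <- peek()
    if (is.na(got) || got != t)
      stop("expected '", t, "' at position ", where(),
           if (!is.na(got)) paste0(" but found '", got, "'")
           else " but input ended")
    advance()
  }
  p_or <- function() {
    l <- p_and()
    while (!is.na(peek()) && peek() == "||") {
      advance()
      l <- bx_or(l, p_and())
    }
    l
  }
  p_and <- function() {
    l <- p_not()
    while (!is.na(peek()) && peek() == "&&") {
      advance()
      l <- bx_and(l, p_not())
    }
    l
  }
  p_not <- function() {
    if (!is.na(peek()) && peek() == "!") {
      advance()
      bx_not(p_not())
    } else p_primary()
  }
  p_primary <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of input at position ", where())
    if (t == "(") {
      advance()
      e <- p_or()
      expect(")")
      return(e)
    }
    if (t == "If") {
      advance()
      expect("[")
      a <- p_or()
      expect(",")
      b <- p_or()
      expect(",")
      c3 <- p_or()
      expect("]")
      return(bx_if(a, b, c3))
    }
    if (t == "True") {
      advance()
      return(bx_const(TRUE))
    }
    if (t == "False") {
      advance()
      return(bx_const(FALSE))
    }
    if (t %in% bool_vocab()) {
      advance()
      return(bx_var(t))
    }
    stop("unknown token '", t, "' at position ", where())
  }
  if (length(toks) == 0L) stop("empty program text")
  e <- p_or()
  if (!is.na(peek()))
    stop("trailing token '", peek(), "' at position ", where())
  e
}

## ---- serializer ------------------------------------------------------------

bx_prec <- c("or" = 1L, "and" = 2L, "not" = 3L,
             "if" = 4L, "var" = 4L, "const" = 4L)

#' Serialize a control program
#'
#' Writes a `bool_expr` back to program text in the same dialect the parser
#' reads.  Parentheses are emitted only where required by precedence and
#' associativity, so `parse_program(deparse_program(e))` reconstructs a tree
#' identical to `e`.
#'
#' @param expr A `bool_expr`.
#' @return A single string.
#' @export
deparse_program <- function(expr) {
  wrap <- function(e, minp) {
    s <- emit(e)
    if (bx_prec[[e$kind]] < minp) paste0("(", s, ")") else s
  }
  emit <- function(e) {
    switch(e$kind,
      var = e$name,
      const = if (e$value) "True" else "False",
      "not" = paste0("!", wrap(e$args[[1]], 3L)),
      # left-associative: right operand needs strictly higher precedence
      "and" = paste0(wrap(e$args[[1]], 2L), "&&", wrap(e$args[[2]], 3L)),
      "or"  = paste0(wrap(e$args[[1]], 1L), "||", wrap(e$args[[2]], 2L)),
      "if"  = paste0("If[", emit(e$args[[1]]), ", ", emit(e$args[[2]]),
                     ", ", emit(e$args[[3]]), "]"))
  }
  emit(expr)
}

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr>", deparse_program(x), "\n")
  invisible(x)
}

#' @export
format.bool_expr <- function(x, ...) deparse_program(x)

#' Read / write a program file
#'
#' Program files hold one expression in the package dialect; lines beginning
#' with `#` are comments and are ignored by the reader.
#'
#' @param path File path.
#' @param expr A `bool_expr`.
#' @param notes Optional character vector of comment lines written above the
#'   expression.
#' @return `read_program()`: a `bool_expr`; `write_program()`: `path`,
#'   invisibly.
#' @export
read_program <- function(path) parse_program(readLines(path, warn = FALSE))

#' @rdname read_program
#' @export
write_program <- function(expr, path, notes = NULL) {
  lines <- c(if (!is.null(notes)) paste0("# ", notes), deparse_program(expr))
  writeLines(lines, path)
  invisible(path)
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a program under one assignment
#'
#' Standard boolean semantics by full recursion: `If[c, t, f]` yields `t`'s
#' value when `c` is true and `f`'s otherwise; `&&`, `||`, `!` are the
#' classical connectives; constants evaluate to themselves.
#'
#' @param expr A `bool_expr`.
#' @param assignment Named logical vector binding every variable in
#'   [bool_vocab()] (extra names are ignored).
#' @return Logical scalar.
#' @export
eval_program <- function(expr, assignment) {
  need <- support_variables(expr)
  miss <- setdiff(need, names(assignment))
  if (length(miss))
    stop("assignment is missing variables: ", paste(miss, collapse = ", "))
  ev <- function(e) {
    switch(e$kind,
      var = as.logical(assignment[[e$name]]),
      const = e$value,
      "not" = !ev(e$args[[1]]),
      "and" = ev(e$args[[1]]) && ev(e$args[[2]]),
      "or"  = ev(e$args[[1]]) || ev(e$args[[2]]),
      "if"  = if (ev(e$args[[1]])) ev(e$args[[2]]) else ev(e$args[[3]]))
  }
  ev(expr)
}

# Vectorized evaluation over a set of assignments given as a named list of
# logical columns (all the same length).  Internal fast path shared by
# truth_vector() and the GP controller compiler.
eval_program_cols <- function(expr, cols) {
  nr <- length(cols[[1]])
  ev <- function(e) {
    switch(e$kind,
      var = cols[[e$name]],
      const = rep(e$value, nr),
      "not" = !ev(e$args[[1]]),
      "and" = ev(e$args[[1]]) & ev(e$args[[2]]),
      "or"  = ev(e$args[[1]]) | ev(e$args[[2]]),
      "if"  = {
        c0 <- ev(e$args[[1]])
        out <- ev(e$args[[3]])
        out[c0] <- ev(e$args[[2]])[c0]
        out
      })
  }
  ev(expr)
}

#' The 4,096-row assignment table
#'
#' All distinct truth assignments of the 12 variables, in canonical order:
#' row `i + 1` is the 12-bit binary expansion of `i` (`i` in `0:4095`) with
#' `n` as the most significant bit and `west` the least.
#'
#' @return Logical matrix of dimension 4096 x 12 with columns named by
#'   [bool_vocab()].
#' @export
assignment_table <- function() {
  v <- bool_vocab()
  i <- 0:4095
  m <- vapply(seq_along(v),
              function(k) bitwAnd(bitwShiftR(i, 12L - k), 1L) == 1L,
              logical(4096))
  colnames(m) <- v
  m
}

#' Exhaustive semantics of a program
#'
#' The truth vector is a program's output on every one of the `2^12 = 4096`
#' assignments of its 12 variables, in the canonical enumeration order of
#' [assignment_table()].  Two programs are semantically equivalent if and
#' only if their truth vectors are identical; this is the exhaustive test
#' used to compare champion programs.
#'
#' @param expr A `bool_expr`.
#' @return Logical vector of length 4096.
#' @export
truth_vector <- function(expr) {
  m <- assignment_table()
  cols <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(cols) <- colnames(m)
  eval_program_cols(expr, cols)
}

#' Count semantic disagreements between two programs
#'
#' @param v1,v2 Truth vectors (logical, length 4096) as returned by
#'   [truth_vector()], under the same enumeration order.
#' @return Integer: the number of assignments on which the two programs
#'   produce different outputs.  Zero exactly when the programs are
#'   semantically equivalent.
#' @export
disagreement_count <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("truth vectors have different lengths (", length(v1), " vs ",
         length(v2), ")")
  sum(v1 != v2)
}

#' Read / write a truth vector file
#'
#' Plain-text export: a header line naming the variable order, then one `0`
#' or `1` per line for each of the 4096 assignments.
#'
#' @param v Logical vector of length 4096.
#' @param path File path.
#' @return `read_truth_vector()`: logical vector of length 4096;
#'   `write_truth_vector()`: `path`, invisibly.
#' @export
write_truth_vector <- function(v, path) {
  stopifnot(length(v) == 4096L)
  writeLines(c(paste("# variable order:", paste(bool_vocab(), collapse = " ")),
               as.character(as.integer(v))), path)
  invisible(path)
}

#' @rdname write_truth_vector
#' @export
read_truth_vector <- function(path) {
  lines <- grep("^#", readLines(path, warn = FALSE), invert = TRUE,
                value = TRUE)
  v <- as.integer(lines)
  if (length(v) != 4096L || anyNA(v) || !all(v %in% 0:1))
    stop("malformed truth vector file: ", path)
  v == 1L
}
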